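test_that("PCA truncation keeps the minimal component set reaching the threshold", {
  set.seed(1)
  ## rank-1 structure plus relatively tiny noise -> one component suffices
  u <- rnorm(60); v <- rnorm(8)
  x <- u %*% t(v) + matrix(rnorm(60 * 8, 0, 1e-3), 60, 8)
  expect_equal(pca_reduce(x, 0.85)$m, 1L)
  ## full retention on full-rank data
  y <- matrix(rnorm(30 * 10), 30, 10)
  expect_equal(pca_reduce(y, 1.0)$m, 10L)
  ## minimality: dropping the last retained PC falls below the threshold
  res <- pca_reduce(y, 0.6)
  cum <- cumsum(res$full_variance_ratio)
  expect_gte(cum[res$m], 0.6)
  if (res$m > 1) expect_lt(cum[res$m - 1], 0.6)
  ## energy conservation over the full spectrum
  expect_lt(abs(sum(res$full_variance_ratio) - 1), 1e-9)
  ## nonincreasing spectrum
  expect_true(all(diff(res$full_variance_ratio) <= 1e-12))
  expect_error(pca_reduce(y, 0), "variance_threshold")
  expect_error(pca_reduce(y, 1.5), "variance_threshold")
})

test_that("isotropic noise needs nearly all components for 85% of the variance", {
  set.seed(2)
  x <- matrix(rnorm(500 * 20), 500, 20)
  expect_gte(pca_reduce(x, 0.85)$m, 15L)
})

test_that("the PCA sign convention is deterministic under sign flips", {
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6)
  a <- pca_reduce(x, 0.9)
  b <- pca_reduce(-x, 0.9)   # mirrored data: same spectrum, canonical signs
  for (j in seq_len(min(a$m, b$m))) {
    v <- a$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("consensus clustering recovers a clean two-cluster structure", {
  sc <- two_blobs(n_per = 25, sep = 10, seed = 4)
  res <- consensus_select_k(sc, k_range = 2:5, n_resamples = 100,
                            subsample_fraction = 0.8, seed = 9)
  expect_equal(res$k, 2L)
  expect_lt(res$pac_scores[["2"]], 0.05)
  cons <- res$consensus[["2"]]
  ## symmetry, unit diagonal, [0,1] range where defined
  expect_equal(cons, t(cons))
  expect_true(all(diag(cons) == 1))
  expect_true(all(cons[!is.na(cons)] >= 0 & cons[!is.na(cons)] <= 1))
})

test_that("a single resample yields binary consensus entries", {
  sc <- two_blobs(n_per = 10, seed = 5)
  res <- suppressWarnings(
    consensus_select_k(sc, k_range = 2:3, n_resamples = 1,
                       subsample_fraction = 0.8, seed = 1))
  vals <- res$consensus[["2"]]
  vals <- vals[!is.na(vals)]
  expect_true(all(vals %in% c(0, 1)))
})

test_that("PAC ties resolve to the smallest k", {
  ## four tight blobs arranged as two well-separated pairs: k = 2 and k = 4
  ## are both perfectly stable (PAC = 0), so the tie must give k = 2
  set.seed(6)
  centers <- c(0, 1, 100, 101)
  sc <- cbind(rep(centers, each = 10) + rnorm(40, 0, 1e-3))
  res <- consensus_select_k(sc, k_range = c(2L, 4L), n_resamples = 50,
                            subsample_fraction = 0.8, seed = 2)
  expect_equal(unname(res$pac_scores[["2"]]), 0)
  expect_equal(unname(res$pac_scores[["4"]]), 0)
  expect_equal(res$k, 2L)
})

test_that("complete-linkage clustering behaves on blobs, duplicates and tiny n", {
  sc <- two_blobs(n_per = 20, sep = 10, seed = 7)
  truth <- rep(1:2, each = 20)
  expect_equal(ari(cluster_phenotype(sc, 2), truth), 1)
  ## n = 2, k = 2: every point its own cluster
  expect_equal(sort(unique(cluster_phenotype(matrix(c(0, 5), 2, 1), 2))), 1:2)
  ## duplicated rows always share a label
  dup <- sc[c(1, 1, 25, 25, 3, 30), ]
  lab <- cluster_phenotype(dup, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_error(cluster_phenotype(sc, 100), "k must not exceed")
})

test_that("cluster labels are permutation-equivariant in the patient order", {
  sc <- two_blobs(n_per = 15, sep = 6, seed = 8)
  set.seed(9)
  perm <- sample(nrow(sc))
  lab <- cluster_phenotype(sc, 2)
  lab_p <- cluster_phenotype(sc[perm, ], 2)
  expect_equal(ari(lab[perm], lab_p), 1)
})

test_that("risk orientation follows event fractions with a median-time tie rule", {
  surv <- data.frame(time = c(5, 6, 7, 40, 50, 60),
                     event = c(1, 1, 1, 0, 0, 1))
  lab <- c(1, 1, 1, 2, 2, 2)   # cluster 1: 3/3 events; cluster 2: 1/3
  r <- orient_risk(lab, surv)
  expect_identical(as.character(r), c("high", "high", "high", "low", "low", "low"))
  ## tie in event fractions -> shorter median observed time is high
  surv2 <- data.frame(time = c(10, 10, 40, 40), event = c(1, 0, 1, 0))
  r2 <- orient_risk(c(1, 1, 2, 2), surv2)
  expect_identical(as.character(r2)[1], "high")
  expect_error(orient_risk(rep(1, 4), surv2), "exactly 2")
})

test_that("derived phenotypes recover the planted cluster structure", {
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(), seed = s)
    harm <- nested_combat(co$features, co$batches)
    ph <- derive_phenotype(harm$final_features, co$survival, k = 2)
    ari(as.integer(ph$labels), co$latent_phenotype)
  }, numeric(1))
  expect_gte(sum(hits >= 0.8), 8)
})

test_that("outcome-blind orientation never consults survival", {
  co <- simulate_cohort(sim_config(), seed = 3)
  harm <- nested_combat(co$features, co$batches)
  ph <- derive_phenotype(harm$final_features, survival = NULL, k = 2,
                         outcome_blind = TRUE)
  expect_true(!is.null(ph$risk_labels))
  expect_setequal(levels(ph$risk_labels), c("low", "high"))
})

test_that("covariate association tests dispatch by type and handle degeneracy", {
  set.seed(10)
  n <- 110
  risk <- factor(rep(c("low", "high"), c(55, 55)), levels = c("low", "high"))
  clinical <- simulate_clinical(n, seed = 11)
  surv <- data.frame(time = runif(n, 1, 50), event = rbinom(n, 1, 0.5))
  rep1 <- suppressWarnings(associate_covariates(risk, clinical, surv))
  expect_setequal(rep1$covariate,
                  c("age", "bmi", "pack_years", "sex", "race", "ecog",
                    "event_of_death"))
  expect_identical(rep1$test[rep1$covariate == "age"], "kruskal-wallis")
  expect_identical(rep1$test[rep1$covariate == "sex"], "chi-squared")

  ## perfectly separated continuous covariate: maximal rank separation
  clinical2 <- clinical
  clinical2$age <- c(seq(40, 50, length.out = 55), seq(70, 80, length.out = 55))
  rep2 <- suppressWarnings(associate_covariates(risk, clinical2, surv))
  expect_lt(rep2$p_value[rep2$covariate == "age"], 1e-10)

  ## degenerate covariate: flagged non-significant with a warning
  clinical3 <- clinical
  clinical3$bmi <- 25
  expect_warning(rep3 <- associate_covariates(risk, clinical3, surv),
                 "degenerate")
  expect_false(rep3$significant[rep3$covariate == "bmi"])

  ## 2x2 death table [[40,15],[16,39]]: uncorrected Pearson statistic from
  ## the closed formula n (ad - bc)^2 / (r1 r2 c1 c2)
  ev <- c(rep(c(1, 0), c(40, 15)), rep(c(1, 0), c(16, 39)))
  surv4 <- data.frame(time = runif(n, 1, 50), event = ev)
  rep4 <- suppressWarnings(associate_covariates(risk, clinical, surv4))
  stat_oracle <- 110 * (40 * 39 - 15 * 16)^2 / (55 * 55 * 56 * 54)
  got <- rep4[rep4$covariate == "event_of_death", ]
  expect_equal(got$statistic, stat_oracle, tolerance = 1e-10)
  expect_lt(got$p_value, 0.001)
})
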