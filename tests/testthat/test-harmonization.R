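test_that("z-scoring centers and scales columns, zeroing constant features", {
  x <- cbind(a = c(1, 2, 3), b = c(0.5, -0.5, 0), c = c(5, 5, 5))
  expect_warning(z <- zscore_features(x), "constant")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(z[, "c"]), c(0, 0, 0))
  expect_identical(attr(z, "constant_features"), "c")
  ## idempotence on an already standardized column
  set.seed(1)
  v <- rnorm(50); v <- (v - mean(v)) / sd(v)
  z2 <- zscore_features(cbind(v = v, w = rnorm(50)))
  expect_lt(max(abs(z2[, "v"] - v)), 1e-12)
})

test_that("a single batch level leaves the data untouched", {
  set.seed(2)
  x <- matrix(rnorm(40 * 5), 40, 5)
  res <- combat_harmonize(x, rep("only", 40))
  expect_lt(max(abs(res$features - x)), 1e-6)
  expect_true(all(res$estimates$gamma_star == 0))
  expect_true(all(res$estimates$delta_star == 1))
})

test_that("a pure location shift between balanced batches is removed", {
  set.seed(3)
  n <- 200
  batch <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[batch == "B", 3] <- x[batch == "B", 3] + 3
  res <- combat_harmonize(x, batch)
  d <- abs(mean(res$features[batch == "A", 3]) - mean(res$features[batch == "B", 3]))
  expect_lt(d, 0.1)
  ## shape, order and names preserved
  expect_identical(dim(res$features), dim(x))
})

test_that("recovered batch locations approach the planted ones as n grows", {
  mae_at <- function(n, seed) {
    set.seed(seed)
    p <- 50
    batch <- rep(c("A", "B"), each = n / 2)
    gam <- rbind(A = rnorm(p, 0, 1), B = rnorm(p, 0, 1))
    x <- matrix(rnorm(n * p), n, p)
    for (b in c("A", "B"))
      x[batch == b, ] <- sweep(x[batch == b, ], 2, gam[b, ], "+")
    est <- combat_harmonize(x, batch)$estimates
    ## comparable scale: centered planted shifts vs de-standardized gamma*
    centered <- sweep(gam, 2, colMeans(gam), "-")
    recov <- est$gamma_star * matrix(sqrt(est$sigma2), 2, p, byrow = TRUE)
    mean(abs(recov - centered))
  }
  maes_small <- vapply(1:5, function(s) mae_at(110, s), numeric(1))
  maes_large <- vapply(1:5, function(s) mae_at(1100, s + 100), numeric(1))
  expect_lt(mean(maes_large), mean(maes_small))
})

test_that("harmonized output matches the reference parametric ComBat implementation", {
  suppressMessages(requireNamespace("sva"))
  set.seed(4)
  n <- 60; p <- 20
  batch <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(.5, .3, .2))
  x <- matrix(rnorm(n * p), n, p)
  for (b in unique(batch)) {
    idx <- batch == b
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, runif(p, .5, 2), "*"),
                      2, rnorm(p), "+")
  }
  mine <- combat_harmonize(x, batch)$features
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(x), batch = batch, mod = NULL, par.prior = TRUE)))
  expect_lt(max(abs(mine - unname(ref))), 1e-4)
})

test_that("the adjustment vanishes as planted effects shrink to zero", {
  adj_at <- function(gsd, dspread) {
    cfg <- sim_config(n_patients = 80, n_features = 30, gamma_sd = gsd,
                      delta_range = c(1 / (1 + dspread), 1 + dspread),
                      phenotype_separation = 0)
    co <- simulate_cohort(cfg, seed = 5)
    z <- zscore_features(co$features)
    res <- nested_combat(co$features, co$batches)
    mean(abs(res$final_features - z))
  }
  adj <- c(adj_at(1, 1), adj_at(0.3, 0.3), adj_at(0, 0))
  expect_true(all(diff(adj) < 0))
  ## residual floor is the EB-shrunk sampling noise of the per-batch
  ## location/scale estimates, not an unremoved effect
  expect_lt(adj[3], 0.1)
})

test_that("undersized batch levels are rejected by name", {
  set.seed(6)
  x <- matrix(rnorm(20 * 4), 20, 4)
  batch <- c(rep("A", 19), "lonely")
  expect_error(combat_harmonize(x, batch), "lonely")
})

test_that("KS flag counting detects planted shifts and respects degenerate inputs", {
  set.seed(7)
  x <- matrix(rnorm(110 * 10), 110, 10)
  batch <- rep(c("A", "B"), each = 55)
  expect_equal(ks_flag_count(x, rep("A", 110))$count, 0L)
  x[batch == "B", 4] <- x[batch == "B", 4] + 3   # 3 pooled-sd shift
  res <- ks_flag_count(x, batch, alpha = 0.05)
  expect_true(res$flags[[4]])
})

test_that("KS false-flag rate on null data matches the test's nominal level", {
  counts <- vapply(1:500, function(s) {
    set.seed(s)
    x <- matrix(rnorm(110 * 107), 110, 107)
    ks_flag_count(x, rep(c("A", "B"), length.out = 110), alpha = 0.05)$count
  }, integer(1))
  expect_lt(abs(mean(counts) - 107 * 0.05), 2)
})

test_that("nested harmonization with one variable reduces to plain ComBat", {
  co <- simulate_cohort(sim_config(batch_spec = list(
    contrast = c("non-contrast" = 0.745, contrast = 0.255))), seed = 8)
  res <- nested_combat(co$features, co$batches)
  expect_identical(res$applied_order, "contrast")
  expect_length(res$per_iteration, 1L)
  z <- zscore_features(co$features)
  direct <- combat_harmonize(z, co$batches$contrast)$features
  expect_lt(max(abs(res$final_features - direct)), 1e-10)
})

test_that("nested harmonization prefers the effect-bearing variable first", {
  cfg <- sim_config(gamma_sd = c(contrast = 1, vendor = 0),
                    delta_range = list(contrast = c(0.5, 2), vendor = c(1, 1)))
  firsts <- vapply(1:15, function(s) {
    co <- simulate_cohort(cfg, seed = s)
    nested_combat(co$features, co$batches)$applied_order[1]
  }, character(1))
  expect_gte(sum(firsts == "contrast"), 13)
})

test_that("tied flag counts resolve to the earliest batch variable, and the loop terminates in V iterations", {
  cfg <- sim_config(gamma_sd = 0, delta_range = c(1, 1))
  co <- simulate_cohort(cfg, seed = 9)
  res <- nested_combat(co$features, co$batches, alpha = 1e-8)  # all counts 0: tie
  expect_identical(res$per_iteration[[1]],
                   c(contrast = 0L, vendor = 0L))
  expect_identical(res$applied_order, c("contrast", "vendor"))
  expect_length(res$per_iteration, 2L)
  ## shape/order preservation through the whole loop
  expect_identical(rownames(res$final_features), rownames(co$features))
  expect_identical(colnames(res$final_features), colnames(co$features))
})
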