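test_that("Cox fits recover a planted hazard ratio and satisfy the score equation", {
  d <- ph_two_group(1000, log(2), seed = 1)
  fit <- cox_fit(cbind(g = d$g), d[c("time", "event")])
  expect_lt(abs(fit$coefficients[["g"]] - log(2)), 0.1)
  expect_equal(fit$hazard_ratios, exp(fit$coefficients), tolerance = 1e-12)
  ## numerical score-equation check at the estimate
  expect_lt(max(abs(cox_numerical_gradient(fit))), 1e-6)
})

test_that("Cox fits are calibrated under the null", {
  ok <- vapply(1:50, function(s) {
    d <- ph_two_group(500, log(2), seed = s)
    set.seed(s + 1000)
    x_perm <- sample(d$g)   # break the association
    fit <- cox_fit(cbind(x = x_perm), d[c("time", "event")])
    wald_p <- 2 * pnorm(-abs(fit$coefficients[1] / sqrt(fit$fit$var[1, 1])))
    abs(fit$coefficients[1]) < 0.2 && wald_p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("degenerate Cox inputs are rejected", {
  d <- data.frame(time = 1:10, event = 0)
  expect_error(cox_fit(cbind(x = rnorm(10)), d), "no events")
  d2 <- data.frame(time = 1:10, event = rep(c(1, 0), 5))
  expect_error(cox_fit(cbind(x = 1:10, y = 2 * (1:10)), d2), "rank deficient")
})

test_that("concordance matches hand-computed and brute-force enumerations", {
  ## perfect ordering, no censoring
  oc <- data.frame(time = c(1, 2, 3, 4), event = 1)
  expect_equal(concordance_index(c(4, 3, 2, 1), oc), 1)
  ## worked example: 6 usable pairs, 4 concordant
  expect_equal(concordance_index(c(0.9, 0.1, 0.8, 0.2),
                                 data.frame(time = c(2, 4, 6, 8), event = 1)),
               4 / 6)
  ## antisymmetry without score ties
  set.seed(2)
  oc2 <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.7))
  s <- rnorm(40)
  expect_equal(concordance_index(-s, oc2), 1 - concordance_index(s, oc2))
  ## brute-force oracle over random instances with ties in times and scores
  for (rep in 1:200) {
    set.seed(rep)
    n <- sample(5:30, 1)
    time <- round(rexp(n, 0.2), sample(c(0, 1, 3), 1))  # induce ties
    time <- pmax(time, 0.1)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1
    sc <- round(rnorm(n), 1)
    got <- tryCatch(concordance_index(sc, data.frame(time = time, event = event)),
                    error = function(e) NA_real_)
    want <- tryCatch(harrell_oracle(sc, time, event),
                     error = function(e) NA_real_)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(concordance_index(c(1, 2), data.frame(time = c(3, 3), event = c(1, 1))),
               "no usable pairs")
})

test_that("bootstrap t-intervals are reproducible and degrade gracefully", {
  x <- rnorm(100)
  stat <- function(idx) mean(x[idx])
  a <- bootstrap_ci(stat, n = 100, n_bootstrap = 500, seed = 3)
  b <- bootstrap_ci(stat, n = 100, n_bootstrap = 500, seed = 3)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$mean && a$mean <= a$ci_high)
  ## constant statistic: zero-width interval
  cst <- bootstrap_ci(function(idx) 0.7, n = 50, n_bootstrap = 100, seed = 1)
  expect_equal(c(cst$ci_low, cst$mean, cst$ci_high), c(0.7, 0.7, 0.7))
  ## excessive replicate failure is an error
  flaky <- function(idx) if (runif(1) < 0.5) stop("boom") else 1
  expect_error(bootstrap_ci(flaky, n = 10, n_bootstrap = 200, seed = 2),
               "replicates failed")
})

test_that("likelihood ratio tests compare nested fits correctly", {
  d <- ph_two_group(200, log(2), seed = 4, event_frac = 0.6)
  X1 <- cbind(g = d$g)
  X2 <- cbind(g = d$g, z = rnorm(200))
  f1 <- cox_fit(X1, d[c("time", "event")])
  f2 <- cox_fit(X2, d[c("time", "event")])
  res <- likelihood_ratio_test(f1, f2)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 1L)
  ## identical models: statistic 0, p = 1
  same <- likelihood_ratio_test(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ## non-nested covariate sets are rejected
  f3 <- cox_fit(cbind(w = rnorm(200)), d[c("time", "event")])
  expect_error(likelihood_ratio_test(f3, f2), "not nested")
})

test_that("adding a truly prognostic covariate is detected at modest n", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 110
    g <- rbinom(n, 1, 0.5)
    z <- rnorm(n)
    t_ev <- rexp(n, 0.05 * exp(log(2) * g + 0.2 * z))
    cens <- rexp(n, 0.05)
    d <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
    f0 <- cox_fit(cbind(z = z), d)
    f1 <- cox_fit(cbind(z = z, g = g), d)
    likelihood_ratio_test(f0, f1)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  ## no censoring
  km <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  ## all censored
  km2 <- km_estimate(data.frame(time = c(2, 5, 9), event = 0))
  expect_true(all(km2$survival == 1))
  ## hand-checked mixed case: S(10) = (5/6) * (3/4) = 0.625
  km3 <- km_estimate(data.frame(time = c(6, 7, 10, 15, 19, 25),
                                event = c(1, 0, 1, 1, 0, 1)))
  expect_equal(km3$survival[km3$time == 10], 0.625)
  ## monotone nonincreasing from 1
  expect_true(all(diff(km3$survival) <= 0))
  ## empty group is skipped with a warning
  expect_warning(km_estimate(data.frame(time = c(1, 2), event = c(1, 1)),
                             groups = c("a", NA)),
                 "empty")
})
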