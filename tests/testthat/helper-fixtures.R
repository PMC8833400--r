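## shared fixture builders and independent oracles

## brute-force Harrell C: literal loop over ordered pairs, independent of
## the vectorized implementation
harrell_oracle <- function(scores, time, event) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ## usable iff i fails first: strictly earlier event, or an
      ## event/censored tie with i the event
      usable <- (event[i] == 1 && time[i] < time[j]) ||
        (event[i] == 1 && event[j] == 0 && time[i] == time[j])
      if (!usable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

## adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## small two-blob score matrix
two_blobs <- function(n_per = 20, sep = 10, m = 3, sd = 1, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * m, 0, sd), n_per, m),
        matrix(rnorm(n_per * m, sep, sd), n_per, m))
}

## cohort with a single prognostic two-group covariate, exponential PH
ph_two_group <- function(n, log_hr, seed, event_frac = 1) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.05 * exp(log_hr * g))
  if (event_frac >= 1) {
    data.frame(time = t_ev, event = 1, g = g)
  } else {
    cens <- rexp(n, rate = 0.05 * (1 - event_frac) / event_frac)
    data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens), g = g)
  }
}

## numerical score-equation check: central-difference gradient of the Cox
## partial log-likelihood at the fitted coefficients
cox_numerical_gradient <- function(fit, h = 1e-4) {
  beta <- fit$coefficients
  vapply(seq_along(beta), function(j) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (cox_loglik_at(fit, bp) - cox_loglik_at(fit, bm)) / (2 * h)
  }, numeric(1))
}
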