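#' Z-score the columns of a feature matrix
#'
#' Centers and scales every feature to sample mean 0 and sample standard
#' deviation 1 (denominator n - 1). Constant features cannot be scaled; they
#' are set to all-zero, kept in place to preserve the column contract, and
#' reported through a warning and the `"constant_features"` attribute.
#'
#' @param features numeric patients x features matrix (or data.frame with a
#'   `patient_id` column).
#' @return the z-scored matrix, with attribute `constant_features` (character
#'   vector, possibly empty).
#' @export
zscore_features <- function(features) {
  x <- as_feature_matrix(features)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv < .Machine$double.eps^0.5
  sdv[const] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, const] <- 0
  if (any(const))
    warning(sprintf("constant feature(s) set to zero: %s",
                    paste(colnames(x)[const], collapse = ", ")))
  attr(z, "constant_features") <- colnames(x)[const]
  z
}

#' ComBat empirical-Bayes batch harmonization
#'
#' Removes additive (location) and multiplicative (scale) batch effects from
#' a feature matrix with the parametric empirical-Bayes location/scale model:
#' each feature is standardized against its pooled grand mean and pooled
#' residual variance, per-batch location and scale estimates are shrunk
#' toward moment-matched normal and inverse-gamma priors by iterated
#' conditional updates, and the shrunken effects are removed before
#' back-transforming. Optional covariate effects are estimated jointly and
#' re-added unchanged (covariate protection).
#'
#' A single observed batch level is a degenerate case with no batch contrast
#' to remove: the input is returned unchanged with `gamma_star = 0`,
#' `delta_star = 1`.
#'
#' @param features patients x features numeric matrix.
#' @param batch per-patient batch level (factor or character).
#' @param covariates optional numeric design matrix of covariates to protect
#'   (no intercept; full rank together with the batch indicators).
#' @param eb_tol relative convergence tolerance of the EB iteration.
#' @param eb_max_iter maximum EB iterations per batch.
#' @param min_batch_size smallest admissible batch level size.
#' @return list with `features` (harmonized matrix, same dimnames) and
#'   `estimates`, an object of class `radphen_combat` holding the grand
#'   intercepts `alpha`, pooled variances `sigma2`, per-batch `gamma_hat`,
#'   `delta_hat`, EB-shrunk `gamma_star`, `delta_star`, and the prior
#'   hyperparameters per batch.
#' @export
combat_harmonize <- function(features, batch, covariates = NULL,
                             eb_tol = 1e-6, eb_max_iter = 1000L,
                             min_batch_size = 2L) {
  x <- as_feature_matrix(features)
  n <- nrow(x); p <- ncol(x)
  batch <- factor(batch)
  if (length(batch) != n) stop_radphen("batch length must equal nrow(features)")
  if (eb_tol <= 0) stop_radphen("eb_tol must be > 0")
  levs <- levels(batch)[table(batch)[levels(batch)] > 0]
  batch <- factor(batch, levels = levs)
  n_i <- as.integer(table(batch))
  small <- n_i < min_batch_size
  if (any(small) && length(levs) > 1L)
    stop_radphen(sprintf("batch level(s) smaller than min_batch_size (%d): %s",
                         min_batch_size, paste(levs[small], collapse = ", ")))
  nb <- length(levs)

  if (nb == 1L) {
    est <- structure(list(
      batch_levels = levs, n_per_batch = n_i,
      alpha = colMeans(x), sigma2 = rep(1, p),
      gamma_hat = matrix(0, 1, p), delta_hat = matrix(1, 1, p),
      gamma_star = matrix(0, 1, p), delta_star = matrix(1, 1, p),
      priors = list(list(gamma_bar = 0, tau2 = 0, a = NA_real_, b = NA_real_)),
      iterations = 0L, degenerate = TRUE), class = "radphen_combat")
    return(list(features = x, estimates = est))
  }

  design <- stats::model.matrix(~ 0 + batch)
  colnames(design) <- levs
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_radphen("covariates must have one row per patient")
    design <- cbind(design, covariates)
  }
  if (qr(design)$rank < ncol(design))
    stop_radphen("batch + covariate design is rank deficient")

  ## pooled least squares: batch means (+ covariate effects) per feature
  B <- solve(crossprod(design), crossprod(design, x))       # (nb+q) x p
  grand <- drop(crossprod(n_i / n, B[seq_len(nb), , drop = FALSE]))  # length p
  resid <- x - design %*% B
  sigma2 <- colSums(resid^2) / n
  if (any(sigma2 <= 0)) stop_radphen("zero pooled variance; drop constant features first")

  stand_mean <- matrix(grand, n, p, byrow = TRUE)
  if (!is.null(covariates))
    stand_mean <- stand_mean + covariates %*% B[-seq_len(nb), , drop = FALSE]
  sdm <- matrix(sqrt(sigma2), n, p, byrow = TRUE)
  s <- (x - stand_mean) / sdm

  gamma_hat <- matrix(NA_real_, nb, p, dimnames = list(levs, colnames(x)))
  delta_hat <- gamma_hat
  for (i in seq_len(nb)) {
    si <- s[batch == levs[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(si)
    delta_hat[i, ] <- apply(si, 2, stats::var)
  }

  gamma_star <- gamma_hat; delta_star <- delta_hat
  priors <- vector("list", nb)
  iters <- integer(nb)
  for (i in seq_len(nb)) {
    g_hat <- gamma_hat[i, ]; d_hat <- delta_hat[i, ]
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_pr <- (2 * s2 + m^2) / s2          # inverse-gamma moment matching
    b_pr <- (m * s2 + m^3) / s2
    priors[[i]] <- list(gamma_bar = g_bar, tau2 = t2, a = a_pr, b = b_pr)
    si <- s[batch == levs[i], , drop = FALSE]
    ni <- nrow(si)
    g_old <- g_hat; d_old <- d_hat
    converged <- FALSE
    for (it in seq_len(eb_max_iter)) {
      g_new <- (t2 * ni * g_hat + d_old * g_bar) / (t2 * ni + d_old)
      sum2 <- colSums((si - matrix(g_new, ni, p, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b_pr) / (ni / 2 + a_pr - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new; d_old <- d_new
      if (is.finite(change) && change < eb_tol) { converged <- TRUE; iters[i] <- it; break }
    }
    if (!converged)
      stop_radphen(sprintf(
        "EB iteration for batch '%s' did not converge in %d iterations (last change %.3g)",
        levs[i], eb_max_iter, change))
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  out <- s
  for (i in seq_len(nb)) {
    idx <- batch == levs[i]
    out[idx, ] <- sweep(sweep(s[idx, , drop = FALSE], 2, gamma_star[i, ], "-"),
                        2, sqrt(delta_star[i, ]), "/")
  }
  out <- out * sdm + stand_mean
  dimnames(out) <- dimnames(x)

  est <- structure(list(batch_levels = levs, n_per_batch = n_i,
                        alpha = grand, sigma2 = sigma2,
                        gamma_hat = gamma_hat, delta_hat = delta_hat,
                        gamma_star = gamma_star, delta_star = delta_star,
                        priors = priors, iterations = iters,
                        degenerate = FALSE),
                   class = "radphen_combat")
  list(features = out, estimates = est)
}

#' @export
print.radphen_combat <- function(x, ...) {
  cat(sprintf("ComBat estimates: %d batch level(s) [%s], %d features\n",
              length(x$batch_levels), paste(x$batch_levels, collapse = ", "),
              length(x$alpha)))
  invisible(x)
}

#' Count features whose distributions differ across batch levels
#'
#' Runs the two-sample Kolmogorov-Smirnov test on every unordered pair of
#' batch levels, per feature; a feature is flagged when any pairwise
#' two-sided p-value falls below `alpha` (no multiplicity correction). With
#' fewer than two usable levels the count is defined as 0.
#'
#' @param features patients x features numeric matrix.
#' @param batch per-patient batch level.
#' @param alpha significance level (default 0.05, two-sided).
#' @param exact passed to [stats::ks.test()]; default `FALSE` uses the
#'   asymptotic p-value.
#' @return list with `flags` (named logical per feature) and `count`.
#' @export
ks_flag_count <- function(features, batch, alpha = 0.05, exact = FALSE) {
  x <- as_feature_matrix(features)
  batch <- factor(batch)
  check_scalar_prob(alpha, "alpha", open_right = TRUE)
  tab <- table(batch)
  levs <- names(tab)[tab >= 2L]
  flags <- stats::setNames(rep(FALSE, ncol(x)), colnames(x))
  if (length(levs) < 2L) return(list(flags = flags, count = 0L))
  pairs <- utils::combn(levs, 2L)
  for (g in seq_len(ncol(x))) {
    for (j in seq_len(ncol(pairs))) {
      a <- x[batch == pairs[1L, j], g]
      b <- x[batch == pairs[2L, j], g]
      pval <- suppressWarnings(stats::ks.test(a, b, exact = exact)$p.value)
      if (pval < alpha) { flags[g] <- TRUE; break }
    }
  }
  list(flags = flags, count = sum(flags))
}

#' Nested multi-batch ComBat harmonization
#'
#' Harmonizes a feature matrix across several batch variables by a greedy
#' nested loop. Features are z-scored once at initialization. Then, while
#' candidate batch variables remain, the current matrix is harmonized
#' separately by each candidate, each result is scored by the number of
#' features the Kolmogorov-Smirnov diagnostic still flags for that
#' candidate's own variable, and the result with the lowest flag count is
#' adopted; its variable is appended to the applied order and dropped from
#' the candidate list. Ties go to the variable earliest in the input
#' ordering. Exactly one variable is consumed per iteration, so the loop
#' runs `ncol(batches)` times.
#'
#' @param features patients x features numeric matrix (raw; z-scored
#'   internally).
#' @param batches data.frame of batch variables (an optional `patient_id`
#'   column is used to align rows); each remaining column is one categorical
#'   batch variable.
#' @param alpha KS significance level for the diagnostics (default 0.05).
#' @param covariates optional protected covariate design matrix, passed to
#'   every [combat_harmonize()] call.
#' @param eb_tol,eb_max_iter,min_batch_size passed to [combat_harmonize()].
#' @param exact_ks passed as `exact` to [ks_flag_count()].
#' @return an object of class `radphen_nested`: list with `applied_order`,
#'   `per_iteration` (list of named candidate -> flag-count vectors),
#'   `initial_counts` (pre-harmonization KS counts per variable, on the
#'   z-scored input), `final_counts`, `final_features`, and
#'   `per_step_estimates`.
#' @export
nested_combat <- function(features, batches, alpha = 0.05, covariates = NULL,
                          eb_tol = 1e-6, eb_max_iter = 1000L,
                          min_batch_size = 2L, exact_ks = FALSE) {
  x <- as_feature_matrix(features)
  if (is.data.frame(batches)) {
    bt <- batches
    if ("patient_id" %in% names(bt)) {
      ids <- as.character(bt$patient_id)
      if (!identical(sort(ids), sort(rownames(x))))
        stop_radphen("batch table patient ids do not match the feature matrix")
      bt <- bt[match(rownames(x), ids), setdiff(names(bt), "patient_id"), drop = FALSE]
    }
  } else stop_radphen("batches must be a data.frame of batch variables")
  if (ncol(bt) < 1L) stop_radphen("at least one batch variable is required")
  vars <- names(bt)

  z <- suppressWarnings(zscore_features(x))
  initial_counts <- vapply(vars, function(v) ks_flag_count(z, bt[[v]], alpha,
                                                           exact_ks)$count,
                           integer(1))
  current <- z
  candidates <- vars
  applied <- character(0)
  per_iter <- list()
  step_est <- list()
  while (length(candidates) > 0L) {
    harm <- lapply(candidates, function(v)
      combat_harmonize(current, bt[[v]], covariates = covariates,
                       eb_tol = eb_tol, eb_max_iter = eb_max_iter,
                       min_batch_size = min_batch_size))
    counts <- vapply(seq_along(candidates), function(i)
      ks_flag_count(harm[[i]]$features, bt[[candidates[i]]], alpha,
                    exact_ks)$count, integer(1))
    names(counts) <- candidates
    best <- which.min(counts)   # ties: earliest in input order
    v <- candidates[best]
    per_iter[[length(per_iter) + 1L]] <- counts
    step_est[[v]] <- harm[[best]]$estimates
    current <- harm[[best]]$features
    applied <- c(applied, v)
    candidates <- candidates[-best]
  }
  final_counts <- vapply(vars, function(v) ks_flag_count(current, bt[[v]], alpha,
                                                         exact_ks)$count,
                         integer(1))
  structure(list(applied_order = applied,
                 per_iteration = per_iter,
                 initial_counts = initial_counts,
                 final_counts = final_counts,
                 final_features = current,
                 per_step_estimates = step_est,
                 alpha = alpha),
            class = "radphen_nested")
}

#' @export
print.radphen_nested <- function(x, ...) {
  cat("Nested ComBat harmonization\n")
  cat("  applied order:", paste(x$applied_order, collapse = " -> "), "\n")
  cat("  KS flag counts (pre -> post):\n")
  for (v in names(x$initial_counts))
    cat(sprintf("    %-10s %3d -> %3d\n", v, x$initial_counts[[v]],
                x$final_counts[[v]]))
  invisible(x)
}
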