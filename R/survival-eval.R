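#' Fit a Cox proportional-hazards model
#'
#' Thin, validated wrapper around [survival::coxph()] (Newton-Raphson on the
#' partial likelihood with step-halving) with the Efron tie correction by
#' default and a tight convergence tolerance, returning the quantities the
#' evaluation stage needs: coefficients, hazard ratios and the maximized log
#' partial likelihood.
#'
#' @param design numeric covariate matrix or data.frame with named columns;
#'   categorical covariates must be pre-expanded to indicators.
#' @param outcome data.frame with `time` (> 0) and `event` (0/1).
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @return object of class `radphen_cox`: `coefficients`, `hazard_ratios`,
#'   `log_partial_likelihood` (at the estimate), `null_log_likelihood`,
#'   `covariate_names`, `tie_method`, `n`, `n_event`, and the underlying
#'   `fit`.
#' @export
cox_fit <- function(design, outcome, tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || any(!is.finite(X))) stop_radphen("design contains non-finite values")
  if (nrow(X) != nrow(outcome)) stop_radphen("design and outcome sizes differ")
  if (any(outcome$time <= 0)) stop_radphen("all times must be positive")
  if (sum(outcome$event) < 1L) stop_radphen("no events observed; cannot fit a Cox model")
  if (qr(X)$rank < ncol(X)) stop_radphen("design matrix is rank deficient")
  conv_warnings <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(outcome$time, outcome$event) ~ X,
      ties = tie_method,
      control = survival::coxph.control(eps = 1e-12, iter.max = 100)),
    warning = function(w) {
      conv_warnings <<- c(conv_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!is.null(fit$info) && isTRUE(grepl("infinite", fit$info)))
    stop_radphen("Cox fit did not converge (possible separation)")
  beta <- stats::setNames(unname(stats::coef(fit)), colnames(X))
  if (anyNA(beta)) stop_radphen("Cox fit produced undefined coefficients")
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 log_partial_likelihood = fit$loglik[2],
                 null_log_likelihood = fit$loglik[1],
                 covariate_names = colnames(X),
                 tie_method = tie_method,
                 n = nrow(X), n_event = sum(outcome$event),
                 fit = fit, convergence_warnings = conv_warnings,
                 design = X, outcome = outcome),
            class = "radphen_cox")
}

#' @export
print.radphen_cox <- function(x, ...) {
  cat(sprintf("Cox model (%s ties), n = %d, events = %d, logLik = %.3f\n",
              x$tie_method, x$n, x$n_event, x$log_partial_likelihood))
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios))
  invisible(x)
}

#' Cox partial log-likelihood at arbitrary coefficients
#'
#' Evaluates the (Efron or Breslow) log partial likelihood at a given
#' coefficient vector by a zero-iteration refit. Useful for likelihood
#' surfaces and for numerical score-equation checks.
#'
#' @param model a `radphen_cox` fit.
#' @param beta coefficient vector.
#' @return scalar log partial likelihood.
#' @export
cox_loglik_at <- function(model, beta) {
  fit <- survival::coxph(
    survival::Surv(model$outcome$time, model$outcome$event) ~ model$design,
    ties = model$tie_method, init = beta,
    control = survival::coxph.control(iter.max = 0))
  fit$loglik[2]
}

#' Harrell's concordance index
#'
#' Over all usable pairs -- those in which the shorter observed time is an
#' event (pairs with tied event times both observed are unusable; in an
#' event-versus-censored tie the censored subject is treated as surviving
#' longer) -- a pair is concordant when the earlier-failing subject carries
#' the higher risk score; tied scores contribute 1/2.
#'
#' @param risk_scores numeric risk scores (higher = higher risk).
#' @param outcome data.frame with `time` and `event`.
#' @return C in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, outcome) {
  s <- as.numeric(risk_scores)
  time <- outcome$time; event <- outcome$event
  n <- length(s)
  if (any(!is.finite(s))) stop_radphen("risk scores must be finite")
  if (n != length(time)) stop_radphen("scores and outcome sizes differ")
  dt <- outer(time, time, "-")          # dt[i,j] = t_i - t_j
  ev_i <- matrix(event == 1, n, n)
  ## i fails first: t_i < t_j and i is an event, or t_i == t_j, i event, j censored
  first <- (dt < 0 & ev_i) | (dt == 0 & ev_i & !t(ev_i))
  ds <- outer(s, s, "-")
  conc <- sum(first & ds > 0)
  tied <- sum(first & ds == 0)
  usable <- sum(first)
  if (usable == 0L) stop_radphen("no usable pairs for concordance")
  (conc + 0.5 * tied) / usable
}

#' Bootstrap t-approximation confidence interval
#'
#' Draws `n_bootstrap` patient-level resamples with replacement, re-evaluates
#' `statistic` on each, and forms the interval
#' `mean +/- t_{(1+level)/2, B-1} * sd` of the replicate statistics.
#' Replicates on which the statistic fails (e.g., a degenerate refit) are
#' dropped and counted; more than 10% failures is an error.
#'
#' @param statistic function taking an integer index vector (the resampled
#'   patient rows) and returning a single number.
#' @param n number of patients to resample from.
#' @param n_bootstrap number of replicates (>= 2).
#' @param ci_level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed.
#' @return list with `mean`, `ci_low`, `ci_high`, `sd`, `n_bootstrap`,
#'   `n_failed`.
#' @export
bootstrap_ci <- function(statistic, n, n_bootstrap = 50000L, ci_level = 0.95,
                         seed = 1L) {
  if (n_bootstrap < 2L) stop_radphen("n_bootstrap must be >= 2")
  check_scalar_prob(ci_level, "ci_level", open_right = TRUE)
  set.seed(seed)
  vals <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- tryCatch(statistic(idx), error = function(e) NA_real_)
  }
  failed <- sum(is.na(vals))
  if (failed > 0.1 * n_bootstrap)
    stop_radphen(sprintf("%d of %d bootstrap replicates failed to evaluate",
                         failed, n_bootstrap))
  vals <- vals[!is.na(vals)]
  m <- mean(vals); sdv <- stats::sd(vals)
  tq <- stats::qt((1 + ci_level) / 2, df = length(vals) - 1L)
  list(mean = m, ci_low = m - tq * sdv, ci_high = m + tq * sdv,
       sd = sdv, n_bootstrap = n_bootstrap, n_failed = failed)
}

#' Likelihood ratio test between nested Cox models
#'
#' @param nested,full `radphen_cox` fits on identical subjects; the nested
#'   model's covariates must be a subset of the full model's.
#' @return list with `statistic` (`2 * (llik_full - llik_nested)`, clamped
#'   at 0 against rounding), `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (!all(nested$covariate_names %in% full$covariate_names))
    stop_radphen("models are not nested: covariates of the reduced model must be a subset")
  if (nested$n != full$n || nested$n_event != full$n_event)
    stop_radphen("models must be fit on identical subjects")
  stat <- max(0, 2 * (full$log_partial_likelihood - nested$log_partial_likelihood))
  df <- length(full$covariate_names) - length(nested$covariate_names)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param outcome data.frame with positive `time` and 0/1 `event`.
#' @param groups optional per-patient group labels; empty groups are skipped
#'   with a warning.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct observed time per group.
#' @export
km_estimate <- function(outcome, groups = NULL) {
  if (any(outcome$time <= 0)) stop_radphen("all times must be positive")
  if (is.null(groups)) groups <- rep("all", nrow(outcome))
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(groups))
    if (length(idx) == 0L) { warning(sprintf("group '%s' is empty; skipped", g)); next }
    sf <- survival::survfit(
      survival::Surv(outcome$time[idx], outcome$event[idx]) ~ 1)
    out[[g]] <- data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
                           n_event = sf$n.event, survival = sf$surv,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
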