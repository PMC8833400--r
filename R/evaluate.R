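#' Evaluation configuration
#'
#' @param n_bootstrap bootstrap replicates for the C-score confidence
#'   intervals (production default 50000; tests and examples use less).
#' @param ci_level confidence level (default 0.95).
#' @param lrt_alpha significance level for the likelihood ratio tests.
#' @param screen_alpha Wald significance level for the PC screening in the
#'   multivariate stage.
#' @param seed integer master seed.
#' @return list of class `radphen_eval_config`.
#' @export
eval_config <- function(n_bootstrap = 50000L, ci_level = 0.95,
                        lrt_alpha = 0.05, screen_alpha = 0.05, seed = 1L) {
  if (n_bootstrap < 2L) stop_radphen("n_bootstrap must be >= 2")
  check_scalar_prob(ci_level, "ci_level", open_right = TRUE)
  structure(list(n_bootstrap = as.integer(n_bootstrap), ci_level = ci_level,
                 lrt_alpha = lrt_alpha, screen_alpha = screen_alpha,
                 seed = as.integer(seed)),
            class = "radphen_eval_config")
}

## indicator expansion with the most frequent level as reference
expand_categorical <- function(x, name) {
  f <- factor(x)
  ref <- names(sort(table(f), decreasing = TRUE))[1]
  f <- stats::relevel(f, ref = ref)
  if (nlevels(f) < 2L) return(NULL)
  mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
  colnames(mm) <- paste0(name, "_", levels(f)[-1])
  mm
}

## phenotype design columns: a single 0/1 indicator for the binary low/high
## risk labels, k-1 cluster indicators otherwise
phenotype_design <- function(x, name) {
  f <- factor(x)
  if (identical(levels(f), c("low", "high"))) {
    out <- cbind(as.numeric(f == "high"))
    colnames(out) <- name
    return(out)
  }
  expand_categorical(f, name)
}

## assemble the covariate columns for one named predictor
predictor_design <- function(name, clinical, phenotypes) {
  switch(name,
    age        = cbind(age = clinical$age),
    bmi        = cbind(bmi = clinical$bmi),
    pack_years = cbind(pack_years = clinical$pack_years),
    sex        = expand_categorical(clinical$sex, "sex"),
    race       = expand_categorical(clinical$race, "race"),
    ecog       = cbind(ecog = ecog_numeric(clinical$ecog)),
    phenotype_combat    = phenotype_design(phenotypes$combat,
                                           "phenotype_combat"),
    phenotype_noncombat = phenotype_design(phenotypes$noncombat,
                                           "phenotype_noncombat"),
    stop_radphen(sprintf("unknown predictor '%s'", name)))
}

## complete-case rows: ECOG "Unknown" is excluded wherever ECOG enters
complete_rows <- function(X) which(stats::complete.cases(X))

## C-score with bootstrap-t CI for one fixed design; the bootstrap refits
## the Cox model per resample with phenotype labels held fixed
c_with_ci <- function(X, outcome, config, tie_method = "efron") {
  fit <- cox_fit(X, outcome, tie_method)
  risk <- drop(X %*% fit$coefficients)
  c_full <- concordance_index(risk, outcome)
  ## resample refits drop columns that go constant or aliased in the
  ## resample (rare indicator levels) instead of failing the replicate
  stat <- function(idx) {
    oc <- outcome[idx, , drop = FALSE]
    Xb <- X[idx, , drop = FALSE]
    keep <- apply(Xb, 2, function(v) length(unique(v)) > 1L)
    if (!any(keep)) stop("degenerate resample")
    Xk <- Xb[, keep, drop = FALSE]
    qrX <- qr(Xk)
    if (qrX$rank < ncol(Xk))
      Xk <- Xk[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    fb <- suppressWarnings(survival::coxph(
      survival::Surv(oc$time, oc$event) ~ Xk, ties = tie_method,
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)))
    beta <- stats::coef(fb)
    ok <- !is.na(beta)
    if (!any(ok)) stop("degenerate resample")
    concordance_index(drop(Xk[, ok, drop = FALSE] %*% beta[ok]), oc)
  }
  ci <- bootstrap_ci(stat, n = nrow(X), n_bootstrap = config$n_bootstrap,
                     ci_level = config$ci_level,
                     seed = sub_seed(config$seed, 7L))
  ## the reported C-score is the bootstrap average (the quantity the CI is
  ## for); the apparent full-sample C is kept alongside
  list(fit = fit, c_score = ci$mean, c_apparent = c_full, ci = ci)
}

#' Univariate prognostic evaluation
#'
#' Fits one single-predictor Cox model per clinical variable (age, BMI,
#' pack-years, sex, race, ECOG) and per imaging phenotype (harmonized and
#' non-harmonized), and reports each model's Harrell C-score with a
#' bootstrap t-approximation confidence interval, sorted by C-score.
#' Patients with unknown ECOG are excluded from the ECOG model
#' (complete-case); constant predictors are excluded with a warning.
#'
#' @param cohort a validated cohort (list with `clinical`, `survival`).
#' @param phenotypes list with `combat` and `noncombat` phenotype labels:
#'   binary low/high risk labels enter as a single indicator, k-level
#'   cluster labels as k-1 indicators against the largest cluster.
#' @param config an [eval_config()].
#' @return data.frame of class `radphen_eval_report` with columns `model`,
#'   `c_score` (bootstrap-averaged), `ci_low`, `ci_high`, `c_apparent`
#'   (full-sample), `n`.
#' @export
run_univariate <- function(cohort, phenotypes, config = eval_config()) {
  preds <- c("ecog", "phenotype_combat", "age", "sex", "bmi", "pack_years",
             "race", "phenotype_noncombat")
  rows <- list()
  for (nm in preds) {
    X <- predictor_design(nm, cohort$clinical, phenotypes)
    if (is.null(X) || all(apply(X, 2, function(v) length(unique(v[!is.na(v)])) < 2L))) {
      warning(sprintf("predictor '%s' is constant; excluded", nm))
      next
    }
    keep <- complete_rows(X)
    res <- c_with_ci(X[keep, , drop = FALSE],
                     cohort$survival[keep, , drop = FALSE], config)
    rows[[nm]] <- data.frame(model = nm, c_score = res$c_score,
                             ci_low = res$ci$ci_low, ci_high = res$ci$ci_high,
                             c_apparent = res$c_apparent,
                             n = length(keep), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$c_score), ]
  rownames(out) <- NULL
  class(out) <- c("radphen_eval_report", class(out))
  out
}

#' Multivariate prognostic evaluation
#'
#' Compares four Cox models against the clinical baseline: the baseline
#' itself (ECOG + age, ECOG ordinal numeric); baseline plus the harmonized
#' phenotype; baseline plus the non-harmonized phenotype; and baseline plus
#' the screened principal components -- PCs whose Wald test in the joint Cox
#' fit of all retained PCs rejects HR = 1 at `screen_alpha`. Each model gets
#' a C-score with bootstrap CI and a likelihood ratio test against the
#' baseline. If no PC passes screening, the PC model is reported as
#' baseline-equivalent with a note. Patients with unknown ECOG are excluded
#' from all four models (complete-case).
#'
#' @param cohort a validated cohort.
#' @param phenotypes list with `combat` and `noncombat` phenotype labels
#'   (low/high risk labels, or k-level cluster labels expanded to
#'   indicators).
#' @param pc_scores n x m matrix of (harmonized) PC scores, for the screened
#'   PC model; `NULL` skips that model.
#' @param config an [eval_config()].
#' @return data.frame of class `radphen_eval_report` with columns `model`,
#'   `c_score` (bootstrap-averaged), `ci_low`, `ci_high`, `c_apparent`
#'   (full-sample), `lrt_p`, `n`, `note`.
#' @export
run_multivariate <- function(cohort, phenotypes, pc_scores = NULL,
                             config = eval_config()) {
  base_X <- cbind(ecog = ecog_numeric(cohort$clinical$ecog),
                  age = cohort$clinical$age)
  keep <- complete_rows(base_X)
  oc <- cohort$survival[keep, , drop = FALSE]
  base_X <- base_X[keep, , drop = FALSE]

  designs <- list(baseline = base_X)
  notes <- list(baseline = "")
  ph_c <- phenotype_design(phenotypes$combat, "phenotype_combat")[keep, , drop = FALSE]
  ph_n <- phenotype_design(phenotypes$noncombat, "phenotype_noncombat")[keep, , drop = FALSE]
  designs$phenotype_combat_ecog_age <- cbind(base_X, ph_c)
  notes$phenotype_combat_ecog_age <- ""
  designs$phenotype_noncombat_ecog_age <- cbind(base_X, ph_n)
  notes$phenotype_noncombat_ecog_age <- ""
  if (!is.null(pc_scores)) {
    pcs <- as.matrix(pc_scores)[keep, , drop = FALSE]
    joint <- cox_fit(pcs, oc)
    wald_p <- 2 * stats::pnorm(-abs(joint$coefficients /
                                      sqrt(diag(joint$fit$var))))
    sel <- which(wald_p < config$screen_alpha)
    if (length(sel) == 0L) {
      designs$screened_pcs_ecog_age <- base_X
      notes$screened_pcs_ecog_age <-
        "no PC passed HR screening; model equals the baseline"
    } else {
      designs$screened_pcs_ecog_age <- cbind(base_X, pcs[, sel, drop = FALSE])
      notes$screened_pcs_ecog_age <-
        paste("screened PCs:", paste(colnames(pcs)[sel], collapse = ", "))
    }
  }

  base_fit <- cox_fit(base_X, oc)
  rows <- list()
  for (nm in names(designs)) {
    res <- c_with_ci(designs[[nm]], oc, config)
    lrt_p <- NA_real_
    if (nm != "baseline") {
      lrt_p <- if (identical(ncol(designs[[nm]]), ncol(base_X)) &&
                   all(colnames(designs[[nm]]) == colnames(base_X))) 1
               else likelihood_ratio_test(base_fit, res$fit)$p_value
    }
    rows[[nm]] <- data.frame(model = nm, c_score = res$c_score,
                             ci_low = res$ci$ci_low, ci_high = res$ci$ci_high,
                             c_apparent = res$c_apparent, lrt_p = lrt_p,
                             n = nrow(oc), note = notes[[nm]],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("radphen_eval_report", class(out))
  out
}
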