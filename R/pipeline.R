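#' Validate and align the four cohort tables
#'
#' Checks that the feature, batch, clinical and survival tables cover an
#' identical set of patient ids, reorders every table to the feature
#' matrix's (sorted) id order, and rejects missing or non-numeric feature
#' cells with their coordinates.
#'
#' @param features patients x features matrix or data.frame with
#'   `patient_id`.
#' @param batches,clinical,survival data.frames with a `patient_id` column.
#' @param latent_phenotype optional named ground-truth vector (simulation).
#' @return a validated `radphen_cohort` list in canonical patient order.
#' @export
validate_cohort <- function(features, batches, clinical, survival,
                            latent_phenotype = NULL) {
  if (is.data.frame(features)) {
    fid <- as.character(features$patient_id)
    fv <- features[setdiff(names(features), "patient_id")]
    bad <- which(!vapply(fv, is.numeric, logical(1)))
    if (length(bad) > 0L) {
      coords <- lapply(bad, function(j) {
        i <- which(is.na(suppressWarnings(as.numeric(as.character(fv[[j]])))))[1]
        sprintf("(row %s, column %s)", fid[i %||% 1], names(fv)[j])
      })
      stop_radphen("non-numeric feature cell(s) at ",
                   paste(unlist(coords), collapse = ", "))
    }
    x <- as.matrix(fv); rownames(x) <- fid
  } else {
    x <- features
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop_radphen(sprintf("missing feature value at (row %s, column %s)",
                         rownames(x)[idx[1]] %||% idx[1],
                         colnames(x)[idx[2]] %||% idx[2]))
  }
  x <- as_feature_matrix(x)
  ids <- sort(rownames(x))
  for (nm in c("batches", "clinical", "survival")) {
    tab <- get(nm)
    tid <- as.character(tab$patient_id)
    missing <- setdiff(ids, tid); extra <- setdiff(tid, ids)
    if (length(missing) > 0L || length(extra) > 0L)
      stop_radphen(sprintf("patient id mismatch in %s table: missing [%s], extra [%s]",
                           nm, paste(missing, collapse = ", "),
                           paste(extra, collapse = ", ")))
  }
  reord <- function(tab) { out <- tab[match(ids, as.character(tab$patient_id)), ]
                           rownames(out) <- NULL; out }
  sv <- reord(survival)
  if (anyNA(sv$time) || any(sv$time <= 0) || !all(sv$event %in% c(0, 1)))
    stop_radphen("survival table needs positive times and 0/1 events")
  out <- list(features = x[ids, , drop = FALSE],
              batches = reord(batches),
              clinical = reord(clinical),
              survival = sv)
  if (!is.null(latent_phenotype)) out$latent_phenotype <- latent_phenotype[ids]
  class(out) <- "radphen_cohort"
  out
}

#' Pipeline configuration
#'
#' One structured configuration drives the whole pipeline. Exactly one of
#' `input_dir` (a directory of cohort CSVs, see [read_cohort()]) or
#' `simulation` (a [sim_config()]) must be supplied.
#'
#' @param input_dir directory holding `features.csv`, `batches.csv`,
#'   `clinical.csv`, `survival.csv`.
#' @param simulation a [sim_config()] for a synthetic cohort.
#' @param alpha KS significance level of the harmonization diagnostics.
#' @param variance_threshold PCA cumulative-variance cutoff.
#' @param k fixed cluster count (`NULL` selects by consensus).
#' @param k_range,n_resamples,subsample_fraction consensus parameters.
#' @param n_bootstrap,ci_level evaluation parameters.
#' @param outcome_blind orient phenotype risk without outcomes.
#' @param seed master seed (substreams derive from it).
#' @param output_dir where artifacts are written; `NULL` keeps results in
#'   memory only.
#' @return list of class `radphen_pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = NULL,
                            alpha = 0.05, variance_threshold = 0.85,
                            k = NULL, k_range = 2:6, n_resamples = 1000L,
                            subsample_fraction = 0.8,
                            n_bootstrap = 2000L, ci_level = 0.95,
                            outcome_blind = FALSE, seed = 1L,
                            output_dir = NULL) {
  if (is.null(input_dir) == is.null(simulation))
    stop_radphen("supply exactly one of input_dir or simulation")
  structure(list(input_dir = input_dir, simulation = simulation,
                 alpha = alpha, variance_threshold = variance_threshold,
                 k = k, k_range = k_range, n_resamples = as.integer(n_resamples),
                 subsample_fraction = subsample_fraction,
                 n_bootstrap = as.integer(n_bootstrap), ci_level = ci_level,
                 outcome_blind = outcome_blind, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "radphen_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate-or-load, validate, z-score, nested ComBat harmonization,
#' phenotype derivation on the harmonized features and (as the
#' non-harmonized comparator) on the merely z-scored features, univariate
#' and multivariate Cox evaluation, and Kaplan-Meier curves by phenotype.
#' When `config$output_dir` is set, every stage writes its artifact as CSV
#' or JSON plus a run manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of class `radphen_result` with `cohort`, `harmonization`,
#'   `phenotype_combat`, `phenotype_noncombat`, `associations`,
#'   `univariate`, `multivariate`, `km`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "radphen_pipeline_config"))
  stages <- character(0)
  step <- function(nm) stages <<- c(stages, nm)

  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation, seed = sub_seed(config$seed, 11L))
    cohort <- validate_cohort(cohort$features, cohort$batches, cohort$clinical,
                              cohort$survival, cohort$latent_phenotype)
  } else {
    raw <- read_cohort(config$input_dir)
    cohort <- validate_cohort(raw$features, raw$batches, raw$clinical,
                              raw$survival)
  }
  step("cohort")

  harm <- nested_combat(cohort$features, cohort$batches, alpha = config$alpha)
  step("harmonization")

  z <- suppressWarnings(zscore_features(cohort$features))
  ph_args <- list(survival = cohort$survival,
                  variance_threshold = config$variance_threshold,
                  k = config$k, k_range = config$k_range,
                  n_resamples = config$n_resamples,
                  subsample_fraction = config$subsample_fraction,
                  outcome_blind = config$outcome_blind)
  ph_c <- do.call(derive_phenotype,
                  c(list(harm$final_features, seed = sub_seed(config$seed, 21L)),
                    ph_args))
  ph_n <- do.call(derive_phenotype,
                  c(list(z, seed = sub_seed(config$seed, 22L)), ph_args))
  step("phenotyping")

  ## binary phenotypes carry low/high risk labels; when consensus selects
  ## k != 2 the raw cluster labels stand in for all downstream stages
  phen_labels <- function(ph)
    if (!is.null(ph$risk_labels)) ph$risk_labels else factor(ph$labels)

  assoc <- suppressWarnings(
    associate_covariates(phen_labels(ph_c), cohort$clinical, cohort$survival))

  ev_cfg <- eval_config(n_bootstrap = config$n_bootstrap,
                        ci_level = config$ci_level,
                        seed = sub_seed(config$seed, 31L))
  phenos <- list(combat = phen_labels(ph_c), noncombat = phen_labels(ph_n))
  uni <- suppressWarnings(run_univariate(cohort, phenos, ev_cfg))
  multi <- run_multivariate(cohort, phenos, pc_scores = ph_c$scores,
                            config = ev_cfg)
  step("evaluation")

  km <- km_estimate(cohort$survival, groups = as.character(phen_labels(ph_c)))
  step("km_curves")

  manifest <- list(stages = stages, seed = config$seed,
                   substreams = list(simulation = sub_seed(config$seed, 11L),
                                     consensus_combat = sub_seed(config$seed, 21L),
                                     consensus_noncombat = sub_seed(config$seed, 22L),
                                     bootstrap = sub_seed(config$seed, 31L)),
                   parameters = config[c("alpha", "variance_threshold",
                                         "n_resamples", "subsample_fraction",
                                         "n_bootstrap", "ci_level")],
                   package_version = as.character(utils::packageVersion("radphen")))

  res <- structure(list(cohort = cohort, harmonization = harm,
                        phenotype_combat = ph_c, phenotype_noncombat = ph_n,
                        associations = assoc, univariate = uni,
                        multivariate = multi, km = km, manifest = manifest),
                   class = "radphen_result")
  if (!is.null(config$output_dir)) write_result(res, config$output_dir)
  res
}

#' @export
print.radphen_result <- function(x, ...) {
  cat("radphen pipeline result\n")
  cat("  harmonization order:",
      paste(x$harmonization$applied_order, collapse = " -> "), "\n")
  cat(sprintf("  phenotype: %d PCs, k = %d\n", x$phenotype_combat$m,
              x$phenotype_combat$k))
  cat("  multivariate models:\n")
  print(x$multivariate[, c("model", "c_score", "ci_low", "ci_high", "lrt_p")],
        digits = 3)
  invisible(x)
}
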