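#' Write a cohort to CSV files
#'
#' Writes `features.csv`, `batches.csv`, `clinical.csv`, `survival.csv` to a
#' directory, each keyed by a shared `patient_id` first column. Ground-truth
#' latent phenotype labels, when present (simulated cohorts), go to a
#' separate `latent_phenotype.csv` that no analysis stage reads.
#'
#' @param cohort a `radphen_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, nm) {
    p <- file.path(dir, nm)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  feat <- data.frame(patient_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  w(feat, "features.csv")
  w(cohort$batches, "batches.csv")
  w(cohort$clinical, "clinical.csv")
  w(cohort$survival, "survival.csv")
  if (!is.null(cohort$latent_phenotype))
    w(data.frame(patient_id = names(cohort$latent_phenotype),
                 latent_phenotype = as.integer(cohort$latent_phenotype)),
      "latent_phenotype.csv")
  invisible(paths)
}

#' Read a cohort from a directory of CSV files
#'
#' Counterpart of [write_cohort()]; reads the four analysis tables (never
#' the ground-truth file) and returns them unvalidated -- pass the result
#' through [validate_cohort()].
#'
#' @param dir directory holding the cohort CSVs.
#' @return list with `features`, `batches`, `clinical`, `survival`.
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, nm)
    if (!file.exists(p)) stop_radphen(sprintf("missing cohort file: %s", p))
    utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(features = rd("features.csv"), batches = rd("batches.csv"),
       clinical = rd("clinical.csv"), survival = rd("survival.csv"))
}

## write all pipeline artifacts + manifest
write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  wcsv <- function(df, nm) {
    p <- file.path(dir, nm); utils::write.csv(df, p, row.names = FALSE)
    files[[nm]] <<- nm
  }
  feat <- data.frame(patient_id = rownames(res$harmonization$final_features),
                     res$harmonization$final_features, check.names = FALSE)
  wcsv(feat, "harmonized_features.csv")
  wcsv(data.frame(patient_id = rownames(res$phenotype_combat$scores),
                  res$phenotype_combat$scores, check.names = FALSE),
       "pc_scores.csv")
  wcsv(data.frame(patient_id = names(res$phenotype_combat$risk_labels) %||%
                    rownames(res$cohort$features),
                  phenotype_combat = as.character(res$phenotype_combat$risk_labels),
                  phenotype_noncombat = as.character(res$phenotype_noncombat$risk_labels)),
       "phenotypes.csv")
  if (!is.null(res$associations)) wcsv(res$associations, "associations.csv")
  wcsv(res$univariate, "univariate.csv")
  wcsv(res$multivariate, "multivariate.csv")
  wcsv(res$km, "km_curves.csv")
  audit <- list(applied_order = res$harmonization$applied_order,
                initial_counts = as.list(res$harmonization$initial_counts),
                per_iteration = lapply(res$harmonization$per_iteration, as.list),
                final_counts = as.list(res$harmonization$final_counts))
  jsonlite::write_json(audit, file.path(dir, "harmonization_audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files[["harmonization_audit.json"]] <- "harmonization_audit.json"
  manifest <- res$manifest
  manifest$artifacts <- unname(unlist(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
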