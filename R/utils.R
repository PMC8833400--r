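#' @keywords internal
"_PACKAGE"

## NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages (simulation, consensus resampling, bootstrap) draw
#' their seeds from one master seed through this map, so a single integer
#' reproduces a whole pipeline run while keeping the stages' streams distinct.
#'
#' @param seed master seed (integer).
#' @param stream stream index (small non-negative integer).
#' @return an integer in [0, 2^31 - 2].
#' @export
sub_seed <- function(seed, stream = 0L) {
  ## Lehmer step keeps the result a valid 32-bit R integer
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(stream) + 1) %% 2147483647)
}

stop_radphen <- function(...) stop(..., call. = FALSE)

check_scalar_prob <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop_radphen(sprintf("`%s` must be a single number in (0,1%s]",
                                name, if (open_right) ")" else ""))
  invisible(x)
}

## feature matrix coercion: accepts matrix or data.frame with patient_id column
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("patient_id" %in% names(x)) {
      ids <- as.character(x$patient_id)
      x <- as.matrix(x[setdiff(names(x), "patient_id")])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.numeric(x)) stop_radphen("feature matrix must be numeric")
  if (anyNA(x) || any(!is.finite(x)))
    stop_radphen("feature matrix contains missing or non-finite values")
  if (nrow(x) < 2L) stop_radphen("feature matrix needs at least 2 patients")
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("feat_%03d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop_radphen("duplicate patient ids")
  if (anyDuplicated(colnames(x))) stop_radphen("duplicate feature names")
  x
}
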