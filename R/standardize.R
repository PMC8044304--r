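#' Fit a z-score standardization on the pooled cohort
#'
#' Computes per-biomarker means and sample standard deviations (n-1
#' denominator) of the ratio, p-tau and t-tau columns on the pooled table
#' (both centers merged), so that downstream clustering operates on
#' z-scored, dimensionless features.
#'
#' @param table A `cohort_table` (or data frame with `ratio`, `ptau`,
#'   `ttau` columns) with at least two rows.
#' @return A `standardization` object: list with `feature_names`, `means`,
#'   `sds`.
#' @seealso [apply_standardization()], [invert_standardization()]
#' @export
fit_standardization <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 records", call. = FALSE)
  m <- vapply(BIOMARKERS, function(f) mean(table[[f]]), numeric(1))
  s <- vapply(BIOMARKERS, function(f) sd(table[[f]]), numeric(1))
  zero <- !is.finite(s) | s <= 0
  if (any(zero)) {
    stop("zero variance: ", paste(BIOMARKERS[zero], collapse = ", "),
         call. = FALSE)
  }
  structure(list(feature_names = BIOMARKERS, means = m, sds = s),
            class = "standardization")
}

#' Apply a fitted standardization
#'
#' Maps natural-unit biomarker values to z-scores, column by column.
#'
#' @param transform A `standardization` from [fit_standardization()].
#' @param x A `cohort_table`/data frame with the biomarker columns, or a
#'   numeric matrix with one column per feature in `transform` order.
#' @return An n x 3 numeric z-score matrix with columns `ratio`, `ptau`,
#'   `ttau`.
#' @export
apply_standardization <- function(transform, x) {
  stopifnot(inherits(transform, "standardization"))
  if (is.data.frame(x)) {
    x <- as.matrix(x[, transform$feature_names, drop = FALSE])
  }
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2, transform$means, "-"), 2, transform$sds, "/")
  colnames(z) <- transform$feature_names
  z
}

#' Invert a fitted standardization
#'
#' Exact inverse of [apply_standardization()]: maps z-scores back to
#' natural units.
#'
#' @param transform A `standardization`.
#' @param z A numeric matrix of z-scores (columns in `transform` order).
#' @return A matrix in natural units.
#' @export
invert_standardization <- function(transform, z) {
  stopifnot(inherits(transform, "standardization"))
  z <- as.matrix(z)
  x <- sweep(sweep(z, 2, transform$sds, "*"), 2, transform$means, "+")
  colnames(x) <- transform$feature_names
  x
}

#' @export
print.standardization <- function(x, ...) {
  cat("<standardization> pooled z-score transform\n")
  print(rbind(mean = x$means, sd = x$sds))
  invisible(x)
}
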