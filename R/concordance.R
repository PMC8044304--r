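#' Inter-assay coefficients of variation for paired measurements
#'
#' For each remeasured sample the inter-assay CV is the two-point sample
#' standard deviation (n-1 denominator) of the two centers' values divided
#' by their mean, i.e. `|a - b| / (sqrt(2) * mean(a, b))`; the summary is
#' the arithmetic mean over samples.
#'
#' @param pairs A paired-measurement table as produced by
#'   [generate_paired_measurements()] (columns `analyte`, `center1_value`,
#'   `center2_value`).
#' @param analyte Which analyte to summarise (e.g. `"ratio"`).
#' @return A `concordance_stats` list: `analyte`, `per_sample_cv`,
#'   `mean_cv`, `n_pairs`.
#' @export
concordance_stats <- function(pairs, analyte) {
  sub <- pairs[pairs$analyte == analyte, , drop = FALSE]
  if (nrow(sub) < 1) stop("no pairs for analyte ", analyte, call. = FALSE)
  a <- sub$center1_value
  b <- sub$center2_value
  if (any(a <= 0 | b <= 0)) {
    stop("non-positive measurement for analyte ", analyte, call. = FALSE)
  }
  cv <- abs(a - b) / (sqrt(2) * ((a + b) / 2))
  structure(list(analyte = analyte, per_sample_cv = cv,
                 mean_cv = mean(cv), n_pairs = length(cv)),
            class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  cat(sprintf("Inter-assay CV for %s: mean %.1f%% over %d pairs\n",
              x$analyte, 100 * x$mean_cv, x$n_pairs))
  invisible(x)
}

#' Principal-component projection with per-cohort 95% ellipses
#'
#' Eigendecomposition of the sample covariance of the (z-scored) biomarker
#' matrix. Scores are the centered data projected on the loadings; the
#' loading sign convention makes each loading's largest-magnitude element
#' positive. For each cohort, the 95% data-range ellipse in the PC1-PC2
#' plane is derived from the 2x2 covariance of that cohort's scores with
#' squared Mahalanobis radius `qchisq(0.95, 2)`.
#'
#' @param z_matrix Numeric matrix (subjects x features), typically
#'   z-scored biomarkers.
#' @param cohort_labels Vector of cohort identifiers, one per row.
#' @return A `pca_projection` list: `loadings`, `explained_variance`,
#'   `explained_share`, `scores`, `center`, `ellipses` (per cohort:
#'   `center`, `semi_axes`, `angle` in radians).
#' @export
pca_projection <- function(z_matrix, cohort_labels) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  stopifnot(length(cohort_labels) == n)

  mu <- colMeans(z_matrix)
  xc <- sweep(z_matrix, 2, mu, "-")
  S <- cov(z_matrix)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-magnitude element of each loading positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(z_matrix),
                         paste0("PC", seq_len(ncol(vecs))))
  scores <- xc %*% vecs

  r2 <- qchisq(0.95, df = 2)
  ellipses <- lapply(split(seq_len(n), cohort_labels), function(idx) {
    sc <- scores[idx, 1:2, drop = FALSE]
    ctr <- colMeans(sc)
    S2 <- cov(sc)
    e2 <- eigen(S2, symmetric = TRUE)
    list(center = ctr,
         semi_axes = sqrt(pmax(e2$values, 0) * r2),
         angle = atan2(e2$vectors[2, 1], e2$vectors[1, 1]))
  })

  structure(list(
    loadings = vecs,
    explained_variance = vals,
    explained_share = vals / sum(vals),
    scores = scores,
    center = mu,
    ellipses = ellipses
  ), class = "pca_projection")
}
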