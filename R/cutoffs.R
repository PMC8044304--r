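youden_scan <- function(values, is_positive, direction) {
  sv <- sort(unique(values))
  u <- length(sv)
  cand <- if (u > 1) c(-Inf, (sv[-u] + sv[-1]) / 2, Inf) else c(-Inf, Inf)
  idx <- match(values, sv)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  # cumulative class counts at each distinct value (<= sv[i])
  pos_cum <- cumsum(tabulate(idx[is_positive], nbins = u))
  neg_cum <- cumsum(tabulate(idx[!is_positive], nbins = u))
  # candidate i+1 sits between sv[i] and sv[i+1]; prepend the -Inf
  # sentinel (no value below it)
  below_pos <- c(0, pos_cum) / n_pos   # P(value < t) among positives
  below_neg <- c(0, neg_cum) / n_neg
  if (u == 1) { below_pos <- c(0, 1); below_neg <- c(0, 1) }
  if (direction == "lower_is_positive") {
    sens <- below_pos
    spec <- 1 - below_neg
  } else {
    sens <- 1 - below_pos
    spec <- below_neg
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {                 # tie: highest sensitivity
    best <- best[sens[best] >= max(sens[best]) - 1e-12]
  }
  if (length(best) > 1) {                 # then the more conservative edge
    best <- if (direction == "higher_is_positive") min(best) else max(best)
  }
  list(cutoff = cand[best], youden_j = max(j[best], 0),
       sensitivity = sens[best], specificity = spec[best])
}

#' Youden-index optimal cut-off
#'
#' Finds the threshold maximizing Youden's index `J = sensitivity +
#' specificity - 1`. Candidate thresholds are the midpoints between
#' adjacent distinct sorted values, plus -Inf/+Inf sentinels. The test
#' calls a subject positive when the value is below the threshold
#' (`direction = "lower_is_positive"`, appropriate for the Abeta42/40
#' ratio) or above it (`"higher_is_positive"`, for the tau markers).
#' Ties on J are broken toward the highest sensitivity, then toward the
#' smaller threshold for `higher_is_positive` (larger for
#' `lower_is_positive`).
#'
#' @param values Numeric biomarker values.
#' @param is_positive Logical (or 0/1) disease labels, same length.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @return A `cutoff_result`: list with `cutoff`, `direction`, `youden_j`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`, `ci` (`NA` until
#'   [bootstrap_cutoff_ci()] is used).
#' @export
youden_cutoff <- function(values, is_positive,
                          direction = c("lower_is_positive",
                                        "higher_is_positive")) {
  direction <- match.arg(direction)
  is_positive <- as.logical(is_positive)
  stopifnot(length(values) == length(is_positive))
  ok <- is.finite(values) & !is.na(is_positive)
  values <- values[ok]; is_positive <- is_positive[ok]
  if (!any(is_positive) || all(is_positive)) {
    stop("need at least one positive and one negative subject",
         call. = FALSE)
  }
  sc <- youden_scan(values, is_positive, direction)
  structure(list(
    cutoff = sc$cutoff, direction = direction, youden_j = sc$youden_j,
    sensitivity = sc$sensitivity, specificity = sc$specificity,
    n_pos = sum(is_positive), n_neg = sum(!is_positive),
    ci = c(NA_real_, NA_real_)
  ), class = "cutoff_result")
}

#' Bootstrap confidence interval for a Youden cut-off
#'
#' Percentile 95% interval of the Youden-optimal threshold over `n_boot`
#' stratified bootstrap replicates (positives and negatives resampled
#' within class, so every replicate retains both classes).
#'
#' @inheritParams youden_cutoff
#' @param n_boot Number of replicates (default 2000, minimum 100).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric length-2 vector `(lower, upper)`.
#' @export
bootstrap_cutoff_ci <- function(values, is_positive,
                                direction = c("lower_is_positive",
                                              "higher_is_positive"),
                                n_boot = 2000, seed = 1,
                                conf_level = 0.95) {
  direction <- match.arg(direction)
  is_positive <- as.logical(is_positive)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  pos <- values[is_positive]
  neg <- values[!is_positive]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("need at least one positive and one negative subject",
         call. = FALSE)
  }
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pb <- sample(pos, length(pos), replace = TRUE)
    nb <- sample(neg, length(neg), replace = TRUE)
    sc <- youden_scan(c(pb, nb),
                      c(rep(TRUE, length(pb)), rep(FALSE, length(nb))),
                      direction)
    reps[b] <- sc$cutoff
  }
  alpha <- (1 - conf_level) / 2
  finite <- reps[is.finite(reps)]
  if (length(finite) == 0) return(c(-Inf, Inf))
  unname(quantile(finite, c(alpha, 1 - alpha), type = 7))
}

cutoff_row <- function(values, is_positive, direction, biomarker,
                       comparison, n_boot, seed) {
  res <- youden_cutoff(values, is_positive, direction)
  ci <- bootstrap_cutoff_ci(values, is_positive, direction,
                            n_boot = n_boot, seed = seed)
  data.frame(
    biomarker = biomarker, comparison = comparison, direction = direction,
    cutoff = res$cutoff, ci_low = ci[1], ci_high = ci[2],
    youden_j = res$youden_j, sensitivity = res$sensitivity,
    specificity = res$specificity, n_pos = res$n_pos, n_neg = res$n_neg,
    stringsAsFactors = FALSE
  )
}

default_directions <- c(ratio = "lower_is_positive",
                        ptau = "higher_is_positive",
                        ttau = "higher_is_positive")

#' Diagnostic cut-off table over clinical and cluster-based comparisons
#'
#' Computes Youden-index cut-offs with stratified bootstrap 95% CIs for
#' each biomarker (ratio, p-tau, t-tau) over three families of
#' comparisons:
#'
#' * `clinical`: clinically diagnosed AD (positive) vs OND (negative);
#' * `control_vs_AD_clusters`: the AD-like cluster union (positive) vs the
#'   control cluster (negative);
#' * `clusterJ_vs_AD_clusters`: the AD-like union (positive) vs each
#'   intermediate cluster J (negative).
#'
#' Directions are fixed a priori by disease biology: low ratio is
#' AD-positive, high p-tau/t-tau are AD-positive. A comparison whose
#' groups are missing is recorded as a failure and the others are still
#' computed.
#'
#' @param table A `cohort_table`.
#' @param labels Integer cluster labels (from a `mixture_fit`).
#' @param labeling A `cluster_labeling` from [label_clusters()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param directions Named character vector of per-biomarker directions.
#' @return A data frame with one row per (biomarker, comparison):
#'   `biomarker`, `comparison`, `direction`, `cutoff`, `ci_low`,
#'   `ci_high`, `youden_j`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`; attribute `errors` lists skipped comparisons.
#' @export
cutoff_table <- function(table, labels, labeling, n_boot = 2000, seed = 1,
                         directions = default_directions) {
  comparisons <- list(
    clinical = list(pos = table$diagnosis == "AD",
                    neg = table$diagnosis == "OND")
  )
  ad_union <- labels %in% labeling$ad_like
  if (length(labeling$ad_like) > 0) {
    comparisons$control_vs_AD_clusters <-
      list(pos = ad_union, neg = labels == labeling$control)
    for (j in labeling$intermediate) {
      comparisons[[sprintf("cluster%d_vs_AD_clusters", j)]] <-
        list(pos = ad_union, neg = labels == j)
    }
  }

  rows <- list()
  errors <- character(0)
  i <- 0L
  for (cmp in names(comparisons)) {
    grp <- comparisons[[cmp]]
    for (b in BIOMARKERS) {
      i <- i + 1L
      sel <- grp$pos | grp$neg
      row <- tryCatch(
        cutoff_row(table[[b]][sel], grp$pos[sel], directions[[b]],
                   b, cmp, n_boot, seed + i),
        error = function(e) {
          errors[[sprintf("%s:%s", cmp, b)]] <<- conditionMessage(e)
          NULL
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "Youden cut-off %.4g (%s): J = %.3f, sens %.3f, spec %.3f (n+ %d, n- %d)\n",
    x$cutoff, x$direction, x$youden_j, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}
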