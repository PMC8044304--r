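#' Per-cluster biomarker medians and 95% data ranges
#'
#' For each cluster and biomarker (natural units), the median and the
#' central 95% data range (2.5th and 97.5th percentiles, linear
#' interpolation between order statistics, i.e. quantile type 7).
#'
#' @param table A `cohort_table`.
#' @param labels Integer cluster labels in `1..K`, one per row of `table`.
#' @return A data frame with columns `cluster`, `n`, `biomarker`,
#'   `median`, `lo95`, `hi95`.
#' @export
cluster_profiles <- function(table, labels) {
  stopifnot(nrow(table) == length(labels))
  K <- max(labels)
  if (!all(labels %in% seq_len(K))) {
    stop("labels must be integers in 1..K", call. = FALSE)
  }
  empty <- setdiff(seq_len(K), unique(labels))
  if (length(empty) > 0) {
    stop("empty cluster: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(K), function(k) {
    idx <- labels == k
    do.call(rbind, lapply(BIOMARKERS, function(b) {
      v <- table[[b]][idx]
      q <- quantile(v, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
      data.frame(cluster = k, n = sum(idx), biomarker = b,
                 median = q[2], lo95 = q[1], hi95 = q[3])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnosis-by-cluster prevalence matrix
#'
#' For every diagnostic category with at least `min_n` subjects, the
#' percentage of that category's subjects falling in each cluster
#' (rows sum to 100).
#'
#' @param diagnoses Character vector of diagnoses.
#' @param labels Integer cluster labels (same length).
#' @param min_n Minimum category size for inclusion (default 5).
#' @return A numeric matrix, rows = retained diagnoses, columns =
#'   `cluster1..clusterK`, entries in percent.
#' @export
prevalence_matrix <- function(diagnoses, labels, min_n = 5) {
  stopifnot(length(diagnoses) == length(labels))
  K <- max(labels)
  counts <- table(diagnoses)
  keep <- names(counts)[counts >= min_n]
  if (length(keep) == 0) {
    return(matrix(numeric(0), 0, K,
                  dimnames = list(NULL, paste0("cluster", seq_len(K)))))
  }
  m <- t(vapply(keep, function(d) {
    idx <- diagnoses == d
    100 * tabulate(labels[idx], nbins = K) / sum(idx)
  }, numeric(K)))
  colnames(m) <- paste0("cluster", seq_len(K))
  m
}

#' Hierarchical ordering of heatmap rows or columns
#'
#' Agglomerative clustering of the rows of a matrix with Euclidean
#' distance and average (UPGMA) linkage, as used to order the prevalence
#' heatmap. Apply to `t(m)` for columns.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return A list: `order` (leaf order, a permutation of row indices),
#'   `heights` (merge heights), `hclust` (the underlying object).
#' @export
hierarchical_order <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 items", call. = FALSE)
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  list(order = hc$order, heights = hc$height, hclust = hc)
}

#' Label clusters as control / AD-like / intermediate
#'
#' Prevalence-based semantic labeling: the control cluster is the single
#' cluster holding the largest share of all OND subjects (ties broken
#' toward the cluster with the higher median ratio); AD-like clusters are
#' those holding at least `ad_share_threshold` of all AD subjects whose
#' within-cluster AD count also exceeds their within-cluster OND count;
#' everything else is intermediate. The control cluster must not itself
#' qualify as AD-like - if it does, the labeling is refused (pathological
#' data).
#'
#' @param table A `cohort_table` (diagnoses AD and OND must be present).
#' @param labels Integer cluster labels in `1..K`.
#' @param ad_share_threshold Minimum share of all AD subjects for an
#'   AD-like call (default 0.10).
#' @return A `cluster_labeling`: list with `labels` (character vector of
#'   `"control"`/`"AD-like"`/`"intermediate"` per cluster), `control`,
#'   `ad_like`, `intermediate` (cluster indices), `ond_share`, `ad_share`.
#' @export
label_clusters <- function(table, labels, ad_share_threshold = 0.10) {
  stopifnot(nrow(table) == length(labels))
  K <- max(labels)
  dg <- table$diagnosis
  if (!any(dg == "AD") || !any(dg == "OND")) {
    stop("both AD and OND must be present", call. = FALSE)
  }
  ond_in <- tabulate(labels[dg == "OND"], nbins = K)
  ad_in <- tabulate(labels[dg == "AD"], nbins = K)
  ond_share <- ond_in / sum(ond_in)
  ad_share <- ad_in / sum(ad_in)

  top <- which(ond_share == max(ond_share))
  if (length(top) > 1) {
    med_ratio <- vapply(top, function(k) median(table$ratio[labels == k]),
                        numeric(1))
    top <- top[which.max(med_ratio)]
  }
  control <- top

  ad_like <- which(ad_share >= ad_share_threshold & ad_in > ond_in)
  if (control %in% ad_like) {
    stop("labeling conflict: control cluster also qualifies as AD-like",
         call. = FALSE)
  }
  lab <- rep("intermediate", K)
  lab[control] <- "control"
  lab[ad_like] <- "AD-like"

  structure(list(labels = lab, control = control,
                 ad_like = sort(ad_like),
                 intermediate = which(lab == "intermediate"),
                 ond_share = ond_share, ad_share = ad_share),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("<cluster_labeling>\n")
  for (k in seq_along(x$labels)) {
    cat(sprintf("  cluster %d: %-12s (OND share %4.1f%%, AD share %4.1f%%)\n",
                k, x$labels[k], 100 * x$ond_share[k], 100 * x$ad_share[k]))
  }
  invisible(x)
}

#' Misdiagnosis tolerance of the cluster labeling
#'
#' Smallest number m of OND subjects that, if relabeled as AD, would
#' change the control-cluster designation or the AD-like set. Relabeling
#' an OND subject only removes it from the OND counts and adds it to the
#' AD counts of its own cluster, so m is found by closed-form counting:
#'
#' * flip the control cluster: remove OND from the current control until
#'   its OND count falls below the runner-up's (n_control - n_runnerup
#'   + 1 relabels suffice and are optimal);
#' * promote an intermediate cluster j to AD-like: relabel r OND inside j
#'   until (AD_j + r) / (AD_total + r) reaches the share threshold and
#'   AD_j + r exceeds OND_j - r;
#' * demote an AD-like cluster a: relabel OND elsewhere until a's AD
#'   share drops below the threshold (r exceeding
#'   AD_a / threshold - AD_total).
#'
#' The reported m is the minimum over mechanisms.
#'
#' @param table A `cohort_table`.
#' @param labels Integer cluster labels.
#' @param labeling A `cluster_labeling` from [label_clusters()].
#' @param ad_share_threshold The threshold used for the labeling.
#' @return List with `m` (minimal relabels), `fraction` (`m / n_OND`),
#'   `mechanism` (which change m achieves).
#' @export
misdiagnosis_tolerance <- function(table, labels, labeling,
                                   ad_share_threshold = 0.10) {
  K <- length(labeling$labels)
  dg <- table$diagnosis
  ond_in <- tabulate(labels[dg == "OND"], nbins = K)
  ad_in <- tabulate(labels[dg == "AD"], nbins = K)
  n_ond <- sum(ond_in)
  ad_total <- sum(ad_in)
  if (sum(ond_in > 0) < 2) {
    stop("misdiagnosis tolerance undefined: OND present in fewer than 2 clusters",
         call. = FALSE)
  }
  ctrl <- labeling$control

  cand <- list()
  # mechanism 1: flip the control designation
  runner_up <- max(ond_in[-ctrl])
  m1 <- ond_in[ctrl] - runner_up + 1
  if (m1 >= 1 && m1 <= ond_in[ctrl]) {
    cand <- c(cand, list(list(m = m1, mechanism = "control_flips")))
  }
  # mechanism 2: promote an intermediate cluster to AD-like
  for (j in labeling$intermediate) {
    if (ond_in[j] == 0) next
    for (r in seq_len(ond_in[j])) {
      share_ok <- (ad_in[j] + r) / (ad_total + r) >= ad_share_threshold
      majority_ok <- (ad_in[j] + r) > (ond_in[j] - r)
      if (share_ok && majority_ok) {
        cand <- c(cand, list(list(
          m = r, mechanism = sprintf("cluster_%d_becomes_AD_like", j))))
        break
      }
    }
  }
  # mechanism 3: demote an AD-like cluster by diluting its AD share
  for (a in labeling$ad_like) {
    need <- floor(ad_in[a] / ad_share_threshold - ad_total) + 1
    avail <- n_ond - ond_in[a]  # relabels must happen outside a
    if (need >= 1 && need <= avail) {
      cand <- c(cand, list(list(
        m = need, mechanism = sprintf("cluster_%d_drops_AD_like", a))))
    }
  }
  if (length(cand) == 0) {
    stop("no relabeling of OND subjects can change the labeling",
         call. = FALSE)
  }
  ms <- vapply(cand, `[[`, numeric(1), "m")
  best <- cand[[which.min(ms)]]
  list(m = as.integer(best$m), fraction = best$m / n_ond,
       mechanism = best$mechanism)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of independence for the table `[[a, b], [c, d]]` by
#' hypergeometric enumeration: with fixed margins, the two-sided p-value
#' sums the probabilities of every table whose probability does not exceed
#' the observed table's (within a 1e-7 relative slack for floating-point
#' ties).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) stop("at least one margin must be positive",
                         call. = FALSE)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
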