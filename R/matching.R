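#' Age histogram matching by random within-bin exclusion
#'
#' Equalizes the age distributions of two groups over fixed-width bins
#' anchored at age 0 (`[40, 45)`, `[45, 50)`, ...). Within each bin the
#' larger group is randomly down-sampled (seeded) to the smaller group's
#' count; bins populated in only one group are excluded entirely.
#'
#' @param ids_a,ages_a Identifiers and ages of group A.
#' @param ids_b,ages_b Identifiers and ages of group B.
#' @param bin_width Bin width in years (default 5).
#' @param seed Integer seed for the random exclusions.
#' @return A list: `retained_a`, `retained_b` (identifier vectors),
#'   `bins` (data frame with per-bin lower/upper bounds and retained
#'   counts), `excluded_a`, `excluded_b` (counts).
#' @export
age_histogram_match <- function(ids_a, ages_a, ids_b, ages_b,
                                bin_width = 5, seed = 1) {
  stopifnot(length(ids_a) == length(ages_a),
            length(ids_b) == length(ages_b))
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  set.seed(seed)
  bin_a <- floor(ages_a / bin_width)
  bin_b <- floor(ages_b / bin_width)
  common <- intersect(unique(bin_a), unique(bin_b))
  if (length(common) == 0) {
    stop("no overlapping age bins: matching is empty", call. = FALSE)
  }
  common <- sort(common)
  retained_a <- character(0)
  retained_b <- character(0)
  bins <- data.frame(lower = common * bin_width,
                     upper = (common + 1) * bin_width,
                     n_retained = NA_integer_)
  for (i in seq_along(common)) {
    ia <- which(bin_a == common[i])
    ib <- which(bin_b == common[i])
    m <- min(length(ia), length(ib))
    if (length(ia) > m) ia <- sample(ia, m)
    if (length(ib) > m) ib <- sample(ib, m)
    retained_a <- c(retained_a, as.character(ids_a[ia]))
    retained_b <- c(retained_b, as.character(ids_b[ib]))
    bins$n_retained[i] <- m
  }
  list(retained_a = retained_a, retained_b = retained_b, bins = bins,
       excluded_a = length(ids_a) - length(retained_a),
       excluded_b = length(ids_b) - length(retained_b))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary group indicator on age
#' (years, continuous) and sex (F = 0, M = 1), used to verify covariate
#' balance after matching. Convergence is declared when the relative
#' deviance change falls below 1e-8 (at most 100 iterations). Wald
#' p-values use the normal approximation. Complete separation (diverging
#' coefficients / degenerate fitted probabilities) is detected and
#' flagged, not silently returned.
#'
#' @param outcome Binary group indicator (0/1 or logical).
#' @param age Age in years.
#' @param sex Sex as `"F"`/`"M"` or 0/1.
#' @return A `logistic_fit`: list with `coefficients` (intercept, age,
#'   sex), `se`, `z`, `p_values`, `deviance`, `iterations`, `converged`,
#'   `separation`.
#' @export
logistic_fit_irls <- function(outcome, age, sex) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.numeric(as.character(sex) == "M")
  }
  n <- length(y)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  X <- cbind(intercept = 1, age = as.numeric(age), sex = as.numeric(sex))
  const <- apply(X[, -1, drop = FALSE], 2, function(v) {
    length(unique(v)) < 2
  })
  if (any(const)) {
    stop("covariate(s) inestimable (constant): ",
         paste(names(const)[const], collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(100)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% z),
                     error = function(e) stop("IRLS failed: singular system",
                                              call. = FALSE))
    beta <- drop(beta)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    dev <- -2 * sum(y * log(pmax(p, 1e-300)) +
                      (1 - y) * log(pmax(1 - p, 1e-300)))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / max(abs(dev_old), 1e-12) < 1e-8) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  separation <- max(abs(beta)) > 50 ||
    all(p < 1e-8 | p > 1 - 1e-8)

  w <- pmax(p * (1 - p), 1e-10)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  names(beta) <- names(se) <- names(zval) <- names(pval) <-
    c("intercept", "age", "sex")

  structure(list(coefficients = beta, se = se, z = zval, p_values = pval,
                 deviance = dev, iterations = iter, converged = converged,
                 separation = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> deviance %.3f in %d IRLS iterations%s\n",
              x$deviance, x$iterations,
              if (x$separation) " [SEPARATION FLAGGED]" else ""))
  print(cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p_values))
  invisible(x)
}

#' Iterative sex rebalancing after age matching
#'
#' Starting from an age-matched subset, repeatedly fits the logistic
#' balance model `group ~ age + sex` and, while either p-value is at or
#' below `p_threshold`, randomly excludes (seeded) one subject of the
#' over-represented sex from the group where that sex is over-represented.
#' Stops as soon as both Wald p-values exceed the threshold; fails with a
#' diagnostic p-value trajectory if `max_iter` exclusions do not suffice.
#'
#' @param ids Subject identifiers of the age-matched subset.
#' @param sexes Sex per subject (`"F"`/`"M"`).
#' @param ages Age per subject (years).
#' @param group Binary group indicator per subject (0/1 or logical).
#' @param p_threshold Balance threshold on both p-values (default 0.25).
#' @param seed Integer seed.
#' @param max_iter Maximum exclusions (default: 25% of subjects).
#' @return A list: `retained` (identifiers), `report` (a
#'   `matching_report` with the final logistic fit, per-sex exclusion
#'   counts, iterations and the p-value trajectory).
#' @export
gender_balance <- function(ids, sexes, ages, group, p_threshold = 0.25,
                           seed = 1, max_iter = NULL) {
  n <- length(ids)
  stopifnot(length(sexes) == n, length(ages) == n, length(group) == n)
  if (is.null(max_iter)) max_iter <- max(1L, floor(0.25 * n))
  set.seed(seed)
  grp <- as.numeric(group)
  keep <- rep(TRUE, n)
  trajectory <- data.frame(iteration = integer(0), p_age = numeric(0),
                           p_sex = numeric(0))
  excluded_by_sex <- c(F = 0L, M = 0L)

  for (it in 0:max_iter) {
    fit <- logistic_fit_irls(grp[keep], ages[keep], sexes[keep])
    p_age <- fit$p_values[["age"]]
    p_sex <- fit$p_values[["sex"]]
    trajectory <- rbind(trajectory,
                        data.frame(iteration = it, p_age = p_age,
                                   p_sex = p_sex))
    if (p_age > p_threshold && p_sex > p_threshold) {
      report <- structure(list(
        final_fit = fit, iterations = it, p_threshold = p_threshold,
        excluded_by_sex = excluded_by_sex, trajectory = trajectory,
        converged = TRUE, seed = seed
      ), class = "matching_report")
      return(list(retained = as.character(ids[keep]), report = report))
    }
    if (it == max_iter) break
    # exclude one subject of the over-represented sex from the group in
    # which that sex is over-represented
    m1 <- mean(sexes[keep & grp == 1] == "M")
    m0 <- mean(sexes[keep & grp == 0] == "M")
    # if males are over-represented in group 1 then females are
    # over-represented in group 0 (and vice versa): both cells qualify;
    # draw from the currently larger group so neither is exhausted
    cells <- if (m1 >= m0) {
      list(list(g = 1, s = "M"), list(g = 0, s = "F"))
    } else {
      list(list(g = 0, s = "M"), list(g = 1, s = "F"))
    }
    n_grp <- c(sum(keep & grp == cells[[1]]$g),
               sum(keep & grp == cells[[2]]$g))
    if (n_grp[2] > n_grp[1]) cells <- cells[c(2, 1)]
    pool <- which(keep & grp == cells[[1]]$g & sexes == cells[[1]]$s)
    if (length(pool) == 0) {
      pool <- which(keep & grp == cells[[2]]$g & sexes == cells[[2]]$s)
    }
    if (length(pool) == 0) break
    drop_i <- if (length(pool) == 1) pool else sample(pool, 1)
    keep[drop_i] <- FALSE
    excluded_by_sex[sexes[drop_i]] <- excluded_by_sex[sexes[drop_i]] + 1L
  }
  stop(paste0(
    "sex rebalancing did not reach p > ", p_threshold, " within ",
    max_iter, " exclusions; final p_age = ",
    signif(trajectory$p_age[nrow(trajectory)], 3), ", p_sex = ",
    signif(trajectory$p_sex[nrow(trajectory)], 3)), call. = FALSE)
}

#' @export
print.matching_report <- function(x, ...) {
  cat(sprintf(
    "<matching_report> balanced after %d exclusion(s) (p threshold %.2f)\n",
    x$iterations, x$p_threshold))
  cat(sprintf("  final p-values: age %.3f, sex %.3f\n",
              x$final_fit$p_values[["age"]], x$final_fit$p_values[["sex"]]))
  invisible(x)
}

#' Match two groups on age and sex
#'
#' Convenience wrapper chaining [age_histogram_match()] (5-year bins) and
#' [gender_balance()] for a cohort table and a binary grouping.
#'
#' @param table A `cohort_table`.
#' @param group Logical vector: `TRUE` for group A (e.g. AD-like
#'   cluster members), `FALSE` for group B (e.g. control cluster);
#'   subjects in neither group must already be excluded.
#' @param bin_width Age bin width in years (default 5).
#' @param p_threshold Logistic balance threshold (default 0.25).
#' @param seed Integer seed.
#' @return A list: `retained` ids, `age_match` (from
#'   [age_histogram_match()]), `report` (from [gender_balance()]).
#' @export
match_cohort <- function(table, group, bin_width = 5, p_threshold = 0.25,
                         seed = 1) {
  stopifnot(nrow(table) == length(group))
  am <- age_histogram_match(
    table$subject_id[group], table$age[group],
    table$subject_id[!group], table$age[!group],
    bin_width = bin_width, seed = seed)
  ids <- c(am$retained_a, am$retained_b)
  sub <- table[match(ids, table$subject_id), , drop = FALSE]
  grp <- as.numeric(sub$subject_id %in% am$retained_a)
  gb <- gender_balance(sub$subject_id, sub$sex, sub$age, grp,
                       p_threshold = p_threshold, seed = seed + 1)
  list(retained = gb$retained, age_match = am, report = gb$report)
}

#' Recompute cluster-based cut-offs on a matched subset
#'
#' Recomputes the control-vs-AD-clusters cut-offs on the retained subset
#' and reports them side by side with the unmatched ones, flagging for
#' each biomarker whether the matched cut-off falls inside the unmatched
#' bootstrap 95% CI.
#'
#' @param table A `cohort_table`.
#' @param retained_ids Identifiers retained by matching.
#' @param labels Integer cluster labels for all rows of `table`.
#' @param labeling A `cluster_labeling`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return A data frame with one row per biomarker: matched and unmatched
#'   cutoff/CI columns and `same_within_ci`.
#' @export
matched_cutoffs <- function(table, retained_ids, labels, labeling,
                            n_boot = 2000, seed = 1) {
  keep <- table$subject_id %in% retained_ids
  sub <- table[keep, , drop = FALSE]
  sub_labels <- labels[keep]
  if (!any(sub_labels %in% labeling$ad_like) ||
      !any(sub_labels == labeling$control)) {
    stop("matching lost one of the comparison groups", call. = FALSE)
  }

  run <- function(tab, labs, seed_offset) {
    pos <- labs %in% labeling$ad_like
    neg <- labs == labeling$control
    sel <- pos | neg
    do.call(rbind, lapply(seq_along(BIOMARKERS), function(i) {
      b <- BIOMARKERS[i]
      cutoff_row(tab[[b]][sel], pos[sel], default_directions[[b]], b,
                 "control_vs_AD_clusters", n_boot, seed + seed_offset + i)
    }))
  }
  un <- run(table, labels, 0)
  ma <- run(sub, sub_labels, 100)
  data.frame(
    biomarker = un$biomarker,
    cutoff_unmatched = un$cutoff, ci_low_unmatched = un$ci_low,
    ci_high_unmatched = un$ci_high,
    cutoff_matched = ma$cutoff, ci_low_matched = ma$ci_low,
    ci_high_matched = ma$ci_high,
    same_within_ci = ma$cutoff >= un$ci_low & ma$cutoff <= un$ci_high,
    stringsAsFactors = FALSE
  )
}
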