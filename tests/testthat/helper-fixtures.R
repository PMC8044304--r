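# Shared fixtures and independent oracles used across the test files.

# a tiny, fully valid cohort data frame built in code
tiny_cohort_df <- function(n = 6) {
  set.seed(42)
  data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    cohort = rep_len(c(1L, 2L), n),
    diagnosis = rep_len(c("AD", "OND", "FTD"), n),
    age = seq(55, 80, length.out = n),
    sex = rep_len(c("F", "M"), n),
    abeta42 = seq(400, 900, length.out = n),
    abeta40 = rep(10000, n),
    ptau = seq(30, 120, length.out = n),
    ttau = seq(200, 900, length.out = n),
    stringsAsFactors = FALSE
  )
}

# brute-force Passing-Bablok slope: explicit pair enumeration, the
# exclusion rule, and direct indexing of the sorted kept slopes
pb_slope_oracle <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j) {
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        if (dx == 0 && dy == 0) next
        if (dx == 0) next            # undefined: excluded
        s <- dy / dx
        if (s == -1) next            # excluded by construction
        slopes <- c(slopes, s)
      }
    }
  }
  if (length(slopes) == 0) return(NA_real_)
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  if (N %% 2 == 1) slopes[(N + 1) %/% 2 + K]
  else mean(slopes[c(N %/% 2 + K, N %/% 2 + 1 + K)])
}

# exhaustive Youden search over every midpoint threshold (plus sentinels)
youden_oracle <- function(values, is_positive, direction) {
  sv <- sort(unique(values))
  cand <- if (length(sv) > 1) {
    c(-Inf, (sv[-length(sv)] + sv[-1]) / 2, Inf)
  } else c(-Inf, Inf)
  pos <- values[is_positive]; neg <- values[!is_positive]
  best <- NULL
  for (t in cand) {
    if (direction == "lower_is_positive") {
      sens <- mean(pos < t); spec <- mean(neg >= t)
    } else {
      sens <- mean(pos > t); spec <- mean(neg <= t)
    }
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         ((direction == "higher_is_positive" && t < best$t) ||
          (direction == "lower_is_positive" && t > best$t)))) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# two-sided Fisher p by direct enumeration of all tables with the margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- sapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  })
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

default_z_cohort <- function(n = 616, seed = 17, with_truth = FALSE) {
  tab <- generate_cohort(n = n, seed = seed, with_truth = with_truth)
  st <- fit_standardization(tab)
  list(table = tab, transform = st, z = apply_standardization(st, tab))
}

# hungarian-free best-permutation matcher for small K
best_permutation_dist <- function(est, truth) {
  K <- nrow(truth)
  perms <- combinat_permn(seq_len(K))
  best <- Inf
  for (p in perms) {
    d <- max(sqrt(rowSums((est[p, , drop = FALSE] - truth)^2)))
    if (d < best) best <- d
  }
  best
}

combinat_permn <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_permn(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
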