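kmeanspp_means <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[k, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ], "-")^2))
    }
  }
  centers
}

gmm_n_params <- function(K, d) {
  as.integer((K - 1) + K * d + K * d * (d + 1) / 2)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' Expectation-maximization for a K-component multivariate normal mixture
#' with unrestricted (full) component covariances, intended for z-scored
#' biomarker matrices. Each run is initialized from a k-means partition
#' (k-means++-style seeding refined by Lloyd iterations, converted to
#' one-hot responsibilities; EM starts with an M-step on them); the best
#' of `n_init` seeded runs by final log-likelihood is returned, preferring
#' non-degenerate solutions. Convergence is declared when the relative
#' log-likelihood change drops below `tol`; `reg` is added to every
#' covariance diagonal at each M-step for numerical stability.
#'
#' @param z_matrix Numeric matrix (n subjects x d features).
#' @param K Number of components (1 <= K < n).
#' @param seed Integer master seed (initializations are derived from it).
#' @param n_init Number of random initializations (default 10).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param reg Covariance diagonal regularization (default 1e-6).
#' @param max_iter Maximum EM iterations per run (default 500).
#' @param min_eig Degeneracy guard: an initialization whose solution
#'   contains a component with smallest covariance eigenvalue below
#'   `min_eig`, or with fewer than d + 1 effective members, is a spurious
#'   spike on a handful of points; such runs are only kept if every
#'   initialization degenerates (default 1e-3, in squared feature units).
#' @return A `mixture_fit`: list with `K`, `weights`, `means` (K x d),
#'   `covariances` (list of d x d), `log_likelihood`, `n_params`, `bic`,
#'   `responsibilities` (n x K), `hard_labels`, `n_iter`, `converged`,
#'   `ll_trace` (of the winning run), `n`, `d`.
#' @export
fit_gmm_em <- function(z_matrix, K, seed = 1, n_init = 10, tol = 1e-6,
                       reg = 1e-6, max_iter = 500, min_eig = 1e-3) {
  x <- as.matrix(z_matrix)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K >= n) stop("K must be smaller than the number of subjects",
                   call. = FALSE)

  set.seed(seed)
  init_seeds <- sample.int(.Machine$integer.max - 1, n_init)
  best <- NULL
  best_degen <- NULL
  for (s in init_seeds) {
    set.seed(s)
    means0 <- kmeanspp_means(x, K)
    assign0 <- if (K == 1) {
      rep(1L, n)
    } else {
      km <- tryCatch(
        stats::kmeans(x, centers = means0, iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) {
        # fall back to nearest-seed assignment
        d2 <- vapply(seq_len(K), function(k) {
          rowSums(sweep(x, 2, means0[k, ], "-")^2)
        }, numeric(n))
        max.col(-d2, ties.method = "first")
      } else {
        km$cluster
      }
    }
    resp0 <- matrix(0, n, K)
    resp0[cbind(seq_len(n), assign0)] <- 1
    fit <- .gmm_em_cpp(x, resp0, tol, reg, max_iter)
    nk <- colSums(fit$responsibilities)
    eig_min <- min(vapply(seq_len(K), function(k) {
      S <- matrix(fit$covariances[, , k], d, d)
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    }, numeric(1)))
    degenerate <- eig_min < min_eig || min(nk) < d + 1
    if (degenerate) {
      if (is.null(best_degen) ||
          fit$log_likelihood > best_degen$log_likelihood) {
        best_degen <- fit
      }
    } else if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
      best <- fit
    }
  }
  if (is.null(best)) best <- best_degen

  covs <- lapply(seq_len(K), function(k) {
    S <- best$covariances[, , k, drop = TRUE]
    if (d == 1) S <- matrix(S, 1, 1)
    dimnames(S) <- list(colnames(x), colnames(x))
    S
  })
  means <- best$means
  colnames(means) <- colnames(x)
  p <- gmm_n_params(K, d)

  structure(list(
    K = as.integer(K),
    weights = as.numeric(best$weights),
    means = means,
    covariances = covs,
    log_likelihood = best$log_likelihood,
    n_params = p,
    bic = -2 * best$log_likelihood + p * log(n),
    responsibilities = best$responsibilities,
    hard_labels = max.col(best$responsibilities, ties.method = "first"),
    n_iter = best$n_iter,
    converged = best$converged,
    ll_trace = as.numeric(best$ll_trace),
    n = n, d = d
  ), class = "mixture_fit")
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = -2 * logL + p * log(n)`, where the number of free parameters of
#' a K-component, d-dimensional full-covariance Gaussian mixture is
#' `p = (K - 1) + K * d + K * d * (d + 1) / 2` (weights + means + distinct
#' covariance entries). Lower is better.
#'
#' @param fit A `mixture_fit`.
#' @param n Number of observations (defaults to the fit's own n).
#' @return The BIC value.
#' @export
bic_score <- function(fit, n = fit$n) {
  -2 * fit$log_likelihood + fit$n_params * log(n)
}

#' Select the number of mixture components by BIC
#'
#' Fits a full-covariance Gaussian mixture for every K in `k_range` and
#' returns the K minimizing BIC, with ties (within 1e-9) broken toward the
#' smaller K (parsimony). Ks whose fit fails are recorded in the curve
#' with `NA` BIC and skipped.
#'
#' @inheritParams fit_gmm_em
#' @param k_range Integer vector of candidate K values (default 1:10).
#' @return A list: `k_best`, `bic_curve` (data frame K/bic/log_likelihood/
#'   converged/error), `fits` (per-K `mixture_fit`s, named by K).
#' @export
select_num_clusters <- function(z_matrix, k_range = 1:10, seed = 1,
                                n_init = 10, tol = 1e-6, reg = 1e-6,
                                max_iter = 500, min_eig = 1e-3) {
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  n <- nrow(as.matrix(z_matrix))
  if (max(k_range) >= n) stop("max(k_range) must be < n", call. = FALSE)
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max - 1, length(k_range))

  fits <- vector("list", length(k_range))
  names(fits) <- as.character(k_range)
  curve <- data.frame(K = k_range, bic = NA_real_,
                      log_likelihood = NA_real_, converged = NA,
                      error = NA_character_)
  for (i in seq_along(k_range)) {
    res <- tryCatch(
      fit_gmm_em(z_matrix, k_range[i], seed = k_seeds[i], n_init = n_init,
                 tol = tol, reg = reg, max_iter = max_iter,
                 min_eig = min_eig),
      error = function(e) e)
    if (inherits(res, "error")) {
      curve$error[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      curve$bic[i] <- res$bic
      curve$log_likelihood[i] <- res$log_likelihood
      curve$converged[i] <- res$converged
    }
  }
  if (all(is.na(curve$bic))) stop("no K could be fitted", call. = FALSE)
  best_bic <- min(curve$bic, na.rm = TRUE)
  k_best <- min(curve$K[!is.na(curve$bic) & curve$bic <= best_bic + 1e-9])
  list(k_best = as.integer(k_best), bic_curve = curve, fits = fits)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> K = %d, d = %d, n = %d; logL = %.2f, BIC = %.2f (%s, %d EM iterations)\n",
    x$K, x$d, x$n, x$log_likelihood, x$bic,
    if (x$converged) "converged" else "not converged", x$n_iter))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}
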