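#' Default six-component biomarker mixture specification
#'
#' Returns the package's default generating model for synthetic cohorts: a
#' six-component trivariate Gaussian mixture over (Abeta42/Abeta40 ratio,
#' p-tau, t-tau) in natural units, with a per-component clinical-diagnosis
#' composition, per-diagnosis age models and sex models. The components
#' emulate the biomarker strata seen in mixed memory-clinic populations:
#'
#' * component 1 ("control-like", weight 0.30): high ratio (mean 0.095,
#'   SD 0.012), low p-tau/t-tau; holds most OND, PD, MS, PSP, MSA mass;
#' * component 2 ("heterogeneous", weight 0.10): intermediate ratio
#'   (0.075, SD 0.020) with very wide tau variance (t-tau SD 600 pg/mL);
#'   holds the CJD/NPH/FTD/encephalopathy mass;
#' * components 3-6 ("AD-like", weights 0.20/0.15/0.15/0.10): low ratio
#'   (0.045, SD 0.008) with tau graded upward (p-tau means 55/80/110/150,
#'   t-tau means 350/550/800/1200 pg/mL); hold most AD, DLB, PDD mass.
#'
#' Within-component p-tau/t-tau correlation is positive (tau measures are
#' biologically coupled). Age models are deliberately imbalanced between
#' AD and OND so that the matching module has work to do.
#'
#' @return A validated `mixture_spec` object (list with `n_components`,
#'   `weights`, `means`, `covariances`, `diagnosis_composition`,
#'   `age_model`, `sex_model`).
#' @export
default_mixture_spec <- function() {
  feature <- BIOMARKERS
  comp_names <- paste0("comp", 1:6)

  means <- rbind(
    c(0.095, 25,  220),   # control-like
    c(0.075, 60,  900),   # heterogeneous (CJD/NPH-like, wide)
    c(0.045, 55,  350),   # AD-like, mild tau
    c(0.045, 80,  550),
    c(0.045, 110, 800),
    c(0.045, 150, 1200)   # AD-like, severe tau
  )
  colnames(means) <- feature
  rownames(means) <- comp_names

  sds <- rbind(
    c(0.012, 8,  70),
    c(0.020, 45, 600),
    c(0.008, 6,  40),
    c(0.008, 7,  50),
    c(0.008, 8,  65),
    c(0.008, 10, 85)
  )
  # residual p-tau/t-tau correlation within component; across the AD-like
  # strata the tau gradient itself is carried by the component means, so
  # the residual within-stratum correlation is modest
  tau_cor <- c(0.5, 0.3, 0.15, 0.15, 0.15, 0.15)
  covariances <- lapply(1:6, function(k) {
    R <- diag(3)
    R[2, 3] <- R[3, 2] <- tau_cor[k]
    S <- diag(sds[k, ]) %*% R %*% diag(sds[k, ])
    dimnames(S) <- list(feature, feature)
    S
  })
  names(covariances) <- comp_names

  comp_row <- function(...) {
    v <- setNames(rep(0, length(DIAGNOSIS_VOCAB)), DIAGNOSIS_VOCAB)
    args <- c(...)
    v[names(args)] <- args
    v / sum(v)
  }
  diagnosis_composition <- rbind(
    comp_row(OND = .27, PD = .24, MS = .025, PSP = .055, MSA = .03,
             sMCI = .065, SCD = .03, FTD = .07, NPH = .04, AD = .035,
             CVD = .012, uDEM = .008, ENC = .01, VAD = .005, DLB = .015,
             CAA = .008, CBD = .012, other = .07),
    comp_row(CJD = .08, NPH = .17, FTD = .18, ENC = .05, VAD = .03,
             OND = .06, AD = .06, uDEM = .02, CVD = .015, DLB = .03,
             PDD = .015, PD = .04, sMCI = .02, SCD = .005, CAA = .015,
             PSP = .02, MSA = .01, CBD = .02, other = .16),
    comp_row(AD = .60, DLB = .05, PDD = .02, FTD = .06, CBD = .02,
             NPH = .03, sMCI = .01, OND = .02, PD = .02, CAA = .01,
             VAD = .015, CVD = .005, uDEM = .01, ENC = .005, SCD = .005,
             PSP = .01, MSA = .005, other = .105),
    comp_row(AD = .63, DLB = .06, PDD = .025, FTD = .05, CBD = .025,
             NPH = .02, OND = .015, PD = .01, CAA = .01, VAD = .01,
             uDEM = .005, ENC = .005, sMCI = .005, CVD = .005,
             PSP = .005, other = .12),
    comp_row(AD = .66, DLB = .06, PDD = .03, FTD = .04, CBD = .02,
             NPH = .015, OND = .01, PD = .005, CAA = .01, VAD = .005,
             uDEM = .005, PSP = .005, other = .135),
    comp_row(AD = .68, DLB = .05, PDD = .03, FTD = .03, CBD = .015,
             NPH = .01, OND = .005, CJD = .02, other = .16)
  )
  rownames(diagnosis_composition) <- comp_names

  age_model <- list(
    default = c(mean = 68, sd = 10),
    AD      = c(mean = 72, sd = 8),
    OND     = c(mean = 58, sd = 12)
  )

  sex_model <- c(default = 0.50, AD = 0.55, OND = 0.45, PD = 0.35,
                 PSP = 0.40, MSA = 0.40)

  spec <- structure(list(
    n_components = 6L,
    weights = c(0.30, 0.10, 0.20, 0.15, 0.15, 0.10),
    means = means,
    covariances = covariances,
    diagnosis_composition = diagnosis_composition,
    age_model = age_model,
    age_bounds = c(40, 90),
    sex_model = sex_model
  ), class = "mixture_spec")
  validate_mixture_spec(spec)
  spec
}

#' Validate a mixture specification
#'
#' Checks the structural invariants of a `mixture_spec`: weights on the
#' simplex, symmetric positive-definite covariances, diagnosis composition
#' rows summing to one over the controlled vocabulary.
#'
#' @param spec A `mixture_spec`.
#' @return `spec`, invisibly; errors describe the first violated invariant.
#' @export
validate_mixture_spec <- function(spec) {
  K <- spec$n_components
  if (length(spec$weights) != K || abs(sum(spec$weights) - 1) > 1e-12 ||
      any(spec$weights < 0)) {
    stop("weights must be a length-", K, " simplex vector", call. = FALSE)
  }
  if (!is.matrix(spec$means) || nrow(spec$means) != K ||
      ncol(spec$means) != 3) {
    stop("means must be a ", K, " x 3 matrix", call. = FALSE)
  }
  for (k in seq_len(K)) {
    S <- spec$covariances[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10))) {
      stop("covariance ", k, " is not symmetric", call. = FALSE)
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      stop("covariance ", k, " is not positive-definite", call. = FALSE)
    }
  }
  dc <- spec$diagnosis_composition
  if (nrow(dc) != K || any(abs(rowSums(dc) - 1) > 1e-12) || any(dc < 0)) {
    stop("diagnosis_composition rows must each sum to 1", call. = FALSE)
  }
  if (!all(colnames(dc) %in% DIAGNOSIS_VOCAB)) {
    stop("diagnosis_composition columns outside the controlled vocabulary",
         call. = FALSE)
  }
  invisible(spec)
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  p <- runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic biomarker cohort
#'
#' Draws `n` subjects from a mixture specification: mixture component from
#' the weights; biomarker triple (ratio, p-tau, t-tau) from the component's
#' trivariate normal, rejection-resampled until all values are positive
#' (after 100 redraws the offending values are clamped to 1e-6); clinical
#' diagnosis from the component's composition row; age from the
#' per-diagnosis truncated normal; sex from the per-diagnosis Bernoulli.
#' Abeta40 is drawn around 10000 pg/mL and Abeta42 set to ratio * Abeta40,
#' so the concentration columns are consistent with the ratio. Subjects
#' alternate between cohort 1 and 2.
#'
#' @param spec A `mixture_spec`; defaults to [default_mixture_spec()].
#' @param n Number of subjects.
#' @param seed Integer seed; the same (spec, n, seed) gives an identical
#'   table.
#' @param with_truth If `TRUE`, retain the generating component index in a
#'   hidden `.component` column (used by parameter-recovery tests).
#' @return A `cohort_table` of `n` records.
#' @export
generate_cohort <- function(spec = default_mixture_spec(), n, seed,
                            with_truth = FALSE) {
  validate_mixture_spec(spec)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  K <- spec$n_components

  comp <- sample.int(K, n, replace = TRUE, prob = spec$weights)
  X <- matrix(NA_real_, n, 3, dimnames = list(NULL, BIOMARKERS))
  for (i in seq_len(n)) {
    k <- comp[i]
    x <- MASS::mvrnorm(1, spec$means[k, ], spec$covariances[[k]])
    tries <- 1
    while (any(x <= 0) && tries < 100) {
      x <- MASS::mvrnorm(1, spec$means[k, ], spec$covariances[[k]])
      tries <- tries + 1
    }
    x[x <= 0] <- 1e-6
    X[i, ] <- x
  }

  vocab <- colnames(spec$diagnosis_composition)
  diagnosis <- vapply(seq_len(n), function(i) {
    sample(vocab, 1, prob = spec$diagnosis_composition[comp[i], ])
  }, character(1))

  age_par <- function(d) {
    if (!is.null(spec$age_model[[d]])) spec$age_model[[d]]
    else spec$age_model[["default"]]
  }
  age <- vapply(diagnosis, function(d) {
    p <- age_par(d)
    truncated_normal(1, p["mean"], p["sd"],
                     spec$age_bounds[1], spec$age_bounds[2])
  }, numeric(1), USE.NAMES = FALSE)

  p_female <- function(d) {
    if (!is.na(spec$sex_model[d])) spec$sex_model[[d]]
    else spec$sex_model[["default"]]
  }
  sex <- vapply(diagnosis, function(d) {
    if (runif(1) < p_female(d)) "F" else "M"
  }, character(1), USE.NAMES = FALSE)

  abeta40 <- truncated_normal(n, 10000, 2300, 3000, 20000)
  abeta42 <- X[, "ratio"] * abeta40

  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    cohort = rep_len(c(1L, 2L), n),
    diagnosis = diagnosis,
    age = age,
    sex = sex,
    abeta42 = abeta42,
    abeta40 = abeta40,
    ptau = X[, "ptau"],
    ttau = X[, "ttau"],
    stringsAsFactors = FALSE
  )
  if (with_truth) df$.component <- comp
  as_cohort_table(df, strict = TRUE)
}

#' Generate paired two-center remeasurements
#'
#' Emulates an inter-center concordance experiment: `n_pairs` subjects are
#' sampled without replacement from the cohort, and for each requested
#' analyte, each center's value is the subject's true value times
#' `(1 + eps)`, with `eps ~ N(0, cv^2)` drawn independently per center
#' (proportional inter-assay noise at the given coefficient of variation).
#' Values are floored at 1e-6 to remain positive.
#'
#' @param table A `cohort_table`.
#' @param cv_per_analyte Named numeric vector of CV fractions, names among
#'   `ratio`, `ptau`, `ttau`, `abeta42`, `abeta40` (e.g.
#'   `c(ratio = 0.07, ptau = 0.04, ttau = 0.09)`).
#' @param n_pairs Number of subjects to remeasure (default 40).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `subject_id`, `analyte`,
#'   `center1_value`, `center2_value`.
#' @export
generate_paired_measurements <- function(table,
                                         cv_per_analyte = c(ratio = 0.07,
                                                            ptau = 0.04,
                                                            ttau = 0.09),
                                         n_pairs = 40, seed = 1) {
  if (any(cv_per_analyte < 0)) stop("CVs must be >= 0", call. = FALSE)
  bad <- setdiff(names(cv_per_analyte),
                 c("ratio", "ptau", "ttau", "abeta42", "abeta40"))
  if (length(bad) > 0) stop("unknown analyte: ", bad[1], call. = FALSE)
  if (n_pairs < 1 || n_pairs > nrow(table)) {
    stop("n_pairs must be in 1..nrow(table)", call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(nrow(table), n_pairs, replace = FALSE)
  out <- lapply(names(cv_per_analyte), function(a) {
    truth <- table[[a]][idx]
    cv <- cv_per_analyte[[a]]
    data.frame(
      subject_id = table$subject_id[idx],
      analyte = a,
      center1_value = pmax(truth * (1 + rnorm(n_pairs, 0, cv)), 1e-6),
      center2_value = pmax(truth * (1 + rnorm(n_pairs, 0, cv)), 1e-6),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
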