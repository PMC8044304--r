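test_that("perfectly separated classes give J = 1 at the gap midpoint", {
  values <- c(0.08, 0.085, 0.09, 0.05, 0.055, 0.06)
  pos <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  res <- youden_cutoff(values, pos, "lower_is_positive")
  expect_equal(res$cutoff, 0.07)
  expect_equal(res$youden_j, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1,
               tolerance = 1e-12)
})

test_that("ties on J resolve toward sensitivity then the stated edge", {
  # negatives {1,3}, positives {2,4}: thresholds 1.5/2.5/3.5 give
  # J = 0.5 / 0 / 0.5; highest sensitivity selects 1.5
  res <- youden_cutoff(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE),
                       "higher_is_positive")
  expect_equal(res$cutoff, 1.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 0.5)
})

test_that("the cutoff is invariant to observation order", {
  set.seed(3)
  v <- rnorm(60); p <- rbinom(60, 1, 0.4) == 1
  if (!any(p)) p[1] <- TRUE
  if (all(p)) p[2] <- FALSE
  a <- youden_cutoff(v, p, "higher_is_positive")
  o <- sample(60)
  b <- youden_cutoff(v[o], p[o], "higher_is_positive")
  expect_identical(a$cutoff, b$cutoff)
})

test_that("the fast scan equals the exhaustive oracle on random instances", {
  set.seed(17)
  for (i in 1:500) {
    n <- sample(4:40, 1)
    v <- round(rnorm(n), sample(1:2, 1))
    p <- rbinom(n, 1, runif(1, 0.2, 0.8)) == 1
    if (!any(p)) p[1] <- TRUE
    if (all(p)) p[1] <- FALSE
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    mine <- youden_cutoff(v, p, dir)
    oracle <- youden_oracle(v, p, dir)
    expect_identical(mine$cutoff, oracle$t)
    expect_equal(mine$youden_j, max(oracle$j, 0), tolerance = 1e-12)
  }
})

test_that("rank-preserving piecewise-linear transforms move the cutoff along", {
  set.seed(4)
  v <- sort(sample(seq(1, 200, by = 0.5), 50))
  p <- rbinom(50, 1, plogis((v - 100) / 20)) == 1
  if (!any(p)) p[50] <- TRUE
  if (all(p)) p[1] <- FALSE
  base <- youden_cutoff(v, p, "higher_is_positive")
  # affine maps preserve midpoints exactly
  tr <- youden_cutoff(3 * v + 7, p, "higher_is_positive")
  expect_equal(tr$cutoff, 3 * base$cutoff + 7)
  expect_equal(tr$youden_j, base$youden_j)
})

test_that("bootstrap CI is degenerate for constant classes and reproducible", {
  v <- c(rep(10, 12), rep(0, 12))
  p <- rep(c(TRUE, FALSE), each = 12)
  ci <- bootstrap_cutoff_ci(v, p, "higher_is_positive", n_boot = 200,
                            seed = 8)
  expect_equal(unname(ci), c(5, 5))
  set.seed(1)
  v2 <- c(rnorm(30, 2), rnorm(30))
  p2 <- rep(c(TRUE, FALSE), each = 30)
  c1 <- bootstrap_cutoff_ci(v2, p2, "higher_is_positive", 300, seed = 2)
  c2 <- bootstrap_cutoff_ci(v2, p2, "higher_is_positive", 300, seed = 2)
  expect_identical(c1, c2)
  expect_error(bootstrap_cutoff_ci(v2, p2, "higher_is_positive", 50, 1),
               "100")
})

test_that("the CI covers the equal-variance Gaussian optimum (midpoint)", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    v <- c(rnorm(200, 2), rnorm(200, 0))
    p <- rep(c(TRUE, FALSE), each = 200)
    ci <- bootstrap_cutoff_ci(v, p, "higher_is_positive", n_boot = 200,
                              seed = s)
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("the estimated cutoff converges to the Gaussian midpoint", {
  biases <- vapply(1:50, function(s) {
    set.seed(s)
    v <- c(rnorm(2500, 2), rnorm(2500, 0))
    p <- rep(c(TRUE, FALSE), each = 2500)
    youden_cutoff(v, p, "higher_is_positive")$cutoff - 1
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.05)
})

test_that("single-class input is refused", {
  expect_error(youden_cutoff(1:5, rep(TRUE, 5), "higher_is_positive"),
               "positive and")
})

test_that("the three-comparison cutoff table is coherent on a synthetic cohort", {
  co <- default_z_cohort(n = 616, seed = 17)
  fit <- fit_gmm_em(co$z, K = 6, seed = 17)
  lbl <- label_clusters(co$table, fit$hard_labels)
  ct <- cutoff_table(co$table, fit$hard_labels, lbl, n_boot = 300,
                     seed = 17)
  expect_true(all(c("clinical", "control_vs_AD_clusters") %in%
                    ct$comparison))
  # the cluster-based ratio cutoff separates the generating means
  r <- ct[ct$biomarker == "ratio" &
            ct$comparison == "control_vs_AD_clusters", ]
  expect_gt(r$cutoff, 0.045)
  expect_lt(r$cutoff, 0.095)
  expect_true(all(ct$ci_low <= ct$cutoff & ct$cutoff <= ct$ci_high))
  expect_equal(ct$youden_j, ct$sensitivity + ct$specificity - 1,
               tolerance = 1e-12)
  # directions fixed a priori per biomarker
  expect_true(all(ct$direction[ct$biomarker == "ratio"] ==
                    "lower_is_positive"))
  expect_true(all(ct$direction[ct$biomarker != "ratio"] ==
                    "higher_is_positive"))
})
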