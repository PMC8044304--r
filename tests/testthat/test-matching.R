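test_that("within-bin down-sampling equalizes per-bin counts", {
  ids_a <- paste0("a", 1:5); ages_a <- c(70, 71, 72, 73, 74)
  ids_b <- paste0("b", 1:3); ages_b <- c(70.5, 71.5, 74.9)
  m <- age_histogram_match(ids_a, ages_a, ids_b, ages_b, seed = 1)
  expect_equal(length(m$retained_a), 3)
  expect_equal(length(m$retained_b), 3)
  expect_equal(m$excluded_a, 2)
  expect_equal(m$bins$lower, 70)

  # identical age multisets: nothing dropped
  m2 <- age_histogram_match(ids_a, ages_a, paste0("b", 1:5), ages_a,
                            seed = 2)
  expect_equal(m2$excluded_a + m2$excluded_b, 0)

  expect_error(
    age_histogram_match(ids_a, rep(42, 5), ids_b, rep(82, 3)),
    "no overlapping")
})

test_that("per-bin counts are exactly equal after matching", {
  set.seed(6)
  tab <- generate_cohort(n = 400, seed = 6)
  grp <- tab$diagnosis == "AD"
  other <- tab$diagnosis == "OND"
  m <- age_histogram_match(tab$subject_id[grp], tab$age[grp],
                           tab$subject_id[other], tab$age[other], seed = 3)
  age_of <- function(ids) tab$age[match(ids, tab$subject_id)]
  bins_a <- table(floor(age_of(m$retained_a) / 5))
  bins_b <- table(floor(age_of(m$retained_b) / 5))
  expect_identical(as.vector(bins_a), as.vector(bins_b))
  expect_identical(names(bins_a), names(bins_b))
})

test_that("the 2x2 sex-only structure reproduces the closed-form log odds ratio", {
  # group x sex table [[20, 10], [10, 20]]; age alternates 60/61 inside
  # every (group, sex) cell so it is exactly orthogonal to both
  outcome <- rep(c(1, 0), each = 30)
  sex <- c(rep("M", 20), rep("F", 10), rep("M", 10), rep("F", 20))
  age <- c(rep(c(60, 61), 10), rep(c(60, 61), 5),
           rep(c(60, 61), 5), rep(c(60, 61), 10))
  fit <- logistic_fit_irls(outcome, age, sex)
  expect_equal(unname(fit$coefficients["sex"]), log(4), tolerance = 1e-6)
  expect_equal(unname(fit$se["sex"]),
               sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20), tolerance = 1e-4)
  p_closed <- 2 * pnorm(-log(4) / sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20))
  expect_equal(unname(fit$p_values["sex"]), p_closed, tolerance = 1e-4)
})

test_that("IRLS coefficients match glm on random datasets", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(30:200, 1)
    age <- runif(n, 40, 90)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    eta <- -2 + 0.03 * age + 0.5 * (sex == "M")
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    mine <- logistic_fit_irls(y, age, sex)
    if (mine$separation) next
    ref <- suppressWarnings(
      glm(y ~ age + I(sex == "M"), family = binomial()))
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-5)
    expect_equal(unname(mine$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-4)
  }
})

test_that("balanced groups show null age and sex effects", {
  set.seed(2)
  n <- 200
  age <- rep(runif(n / 2, 50, 80), 2)
  sex <- rep(sample(c("F", "M"), n / 2, replace = TRUE), 2)
  y <- rep(c(0, 1), each = n / 2)
  fit <- logistic_fit_irls(y, age, sex)
  expect_gt(fit$p_values[["age"]], 0.25)
  expect_gt(fit$p_values[["sex"]], 0.25)
})

test_that("complete separation is flagged, constant sex is an error", {
  age <- c(40:49, 70:79)
  y <- rep(c(0, 1), each = 10)
  sex <- rep(c("F", "M"), 10)
  fit <- logistic_fit_irls(y, age, sex)
  expect_true(fit$separation)
  expect_error(logistic_fit_irls(y, age, rep("F", 20)), "constant")
  expect_error(logistic_fit_irls(rep(1, 10), 40:49, rep(c("F", "M"), 5)),
               "classes")
})

test_that("already balanced input needs zero exclusions", {
  set.seed(11)
  n <- 120
  age <- rep(runif(n / 2, 50, 80), 2)
  sex <- rep(sample(c("F", "M"), n / 2, replace = TRUE), 2)
  gb <- gender_balance(sprintf("s%03d", 1:n), sex, age,
                       rep(c(0, 1), each = n / 2), seed = 5)
  expect_equal(gb$report$iterations, 0)
  expect_equal(length(gb$retained), n)
})

test_that("a strong sex imbalance is rebalanced to p > 0.25", {
  set.seed(21)
  n <- 200
  age <- c(runif(n, 55, 75), runif(n, 55, 75))
  sex <- c(sample(c("M", "F"), n, TRUE, prob = c(0.9, 0.1)),
           sample(c("M", "F"), n, TRUE, prob = c(0.5, 0.5)))
  grp <- rep(c(1, 0), each = n)
  gb <- gender_balance(sprintf("s%03d", 1:(2 * n)), sex, age, grp,
                       seed = 9, max_iter = 250)
  expect_gt(gb$report$final_fit$p_values[["age"]], 0.25)
  expect_gt(gb$report$final_fit$p_values[["sex"]], 0.25)
  expect_gt(sum(gb$report$excluded_by_sex), 0)
  # reproducible from the same seed
  gb2 <- gender_balance(sprintf("s%03d", 1:(2 * n)), sex, age, grp,
                        seed = 9, max_iter = 250)
  expect_identical(gb$retained, gb2$retained)
})

test_that("matched cut-offs equal unmatched ones when nothing is excluded", {
  co <- default_z_cohort(n = 616, seed = 31)
  fit <- fit_gmm_em(co$z, K = 6, seed = 31)
  lbl <- label_clusters(co$table, fit$hard_labels)
  in_cmp <- fit$hard_labels %in% c(lbl$ad_like, lbl$control)
  mc <- matched_cutoffs(co$table, co$table$subject_id, fit$hard_labels,
                        lbl, n_boot = 200, seed = 2)
  expect_equal(mc$cutoff_matched, mc$cutoff_unmatched)
  expect_error(
    matched_cutoffs(co$table,
                    co$table$subject_id[fit$hard_labels == lbl$control],
                    fit$hard_labels, lbl, n_boot = 200, seed = 2),
    "lost")
})

test_that("matched control-vs-AD cutoffs stay inside the unmatched CI", {
  co <- default_z_cohort(n = 616, seed = 31)
  fit <- fit_gmm_em(co$z, K = 6, seed = 31)
  lbl <- label_clusters(co$table, fit$hard_labels)
  in_cmp <- fit$hard_labels %in% c(lbl$ad_like, lbl$control)
  sub <- co$table[in_cmp, ]
  m <- match_cohort(sub, fit$hard_labels[in_cmp] %in% lbl$ad_like,
                    seed = 7)
  mc <- matched_cutoffs(co$table, m$retained, fit$hard_labels, lbl,
                        n_boot = 500, seed = 3)
  expect_true(all(mc$same_within_ci))
})
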