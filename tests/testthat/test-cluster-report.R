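test_that("profiles use type-7 percentiles for the 95% data range", {
  df <- tiny_cohort_df(100)
  df$diagnosis <- rep_len(c("AD", "OND"), 100)
  df$abeta40 <- 10000
  df$abeta42 <- (1:100) * 10      # ratio = (1:100) / 1000
  df$ptau <- 1:100
  df$ttau <- rep(500, 100)
  tab <- as_cohort_table(df)
  prof <- cluster_profiles(tab, rep(1L, 100))
  p <- prof[prof$biomarker == "ptau", ]
  expect_equal(p$median, 50.5)
  expect_equal(p$lo95, 3.475)
  expect_equal(p$hi95, 97.525)
  t <- prof[prof$biomarker == "ttau", ]
  expect_equal(t$lo95, t$hi95)    # zero-width range for constant values
})

test_that("single-member clusters collapse to the member's value", {
  df <- tiny_cohort_df(3)
  tab <- as_cohort_table(df)
  prof <- cluster_profiles(tab, c(1L, 1L, 2L))
  p2 <- prof[prof$cluster == 2 & prof$biomarker == "ptau", ]
  expect_equal(p2$median, tab$ptau[3])
  expect_equal(p2$lo95, tab$ptau[3])
  expect_equal(p2$hi95, tab$ptau[3])
  expect_error(cluster_profiles(tab, c(1L, 1L, 3L)), "empty cluster: 2")
})

test_that("prevalence rows are percentages that sum to 100", {
  dg <- c(rep("AD", 10), rep("OND", 4))
  lb <- c(rep(1L, 7), rep(2L, 3), rep(1L, 4))
  m <- prevalence_matrix(dg, lb, min_n = 5)
  expect_equal(rownames(m), "AD")          # OND (n = 4) excluded
  expect_equal(unname(m["AD", ]), c(70, 30))
  m2 <- prevalence_matrix(dg, lb, min_n = 4)
  expect_equal(unname(rowSums(m2)), rep(100, 2), tolerance = 1e-9)
})

test_that("average-linkage ordering matches a hand UPGMA computation", {
  m <- matrix(c(0, 1, 10), ncol = 1)
  h <- hierarchical_order(m)
  expect_equal(h$heights, c(1, 9.5))       # {0,1} at 1; then (10+9)/2
  expect_setequal(h$order, 1:3)
  m2 <- rbind(c(1, 2), c(1, 2), c(5, 9))
  h2 <- hierarchical_order(m2)
  expect_equal(h2$heights[1], 0)           # identical rows merge first
})

test_that("cluster labeling follows OND/AD shares with the stated tie-break", {
  mk_tab <- function(diag, ratio) {
    df <- tiny_cohort_df(length(diag))
    df$diagnosis <- diag
    df$abeta40 <- 10000
    df$abeta42 <- ratio * 10000
    as_cohort_table(df)
  }
  # cluster 1 holds most OND; clusters 3-6 share AD with AD majority
  diag <- c(rep("OND", 10), rep("AD", 20), rep("FTD", 5))
  lab <- c(rep(1L, 8), rep(2L, 2),           # OND: 80% in cluster 1
           rep(3L, 6), rep(4L, 5), rep(5L, 5), rep(6L, 4),
           rep(2L, 5))                       # FTD in cluster 2
  tab <- mk_tab(diag, seq(0.04, 0.1, length.out = 35))
  lbl <- label_clusters(tab, lab)
  expect_equal(lbl$control, 1L)
  expect_equal(lbl$ad_like, 3:6)
  expect_equal(lbl$labels[2], "intermediate")
  expect_equal(sum(lbl$labels == "control"), 1L)

  # exact OND tie between clusters 1 and 2 -> higher median ratio wins
  diag2 <- c(rep("OND", 8), rep("AD", 6))
  lab2 <- c(rep(1L, 4), rep(2L, 4), rep(3L, 6))
  ratio2 <- c(rep(0.09, 4), rep(0.11, 4), rep(0.045, 6))
  lbl2 <- label_clusters(mk_tab(diag2, ratio2), lab2)
  expect_equal(lbl2$control, 2L)
})

test_that("a control cluster that qualifies as AD-like is a refused conflict", {
  df <- tiny_cohort_df(20)
  df$diagnosis <- c(rep("OND", 4), rep("AD", 16))
  lab <- c(rep(1L, 12), rep(2L, 8))  # all OND and most AD in cluster 1
  expect_error(label_clusters(as_cohort_table(df[seq_along(lab), ]), lab),
               "conflict")
})

test_that("misdiagnosis tolerance matches brute force on the counting example", {
  # OND counts per cluster (10, 9, 0): two relabels flip the argmax
  df <- tiny_cohort_df(60)
  df$diagnosis <- c(rep("OND", 19), rep("AD", 41))
  df$abeta40 <- 10000
  lab <- c(rep(1L, 10), rep(2L, 9),          # OND
           rep(2L, 11), rep(3L, 30))         # AD
  df$abeta42 <- 10000 * c(rep(0.095, 10), rep(0.07, 20), rep(0.045, 30))
  tab <- as_cohort_table(df)
  lbl <- label_clusters(tab, lab)
  expect_equal(lbl$control, 1L)
  tol <- misdiagnosis_tolerance(tab, lab, lbl)
  expect_equal(tol$m, 2L)
  expect_equal(tol$fraction, 2 / 19)
  expect_lte(tol$m, 10)                      # never exceeds control's OND

  # brute force: relabeling any single OND subject must not change the
  # labeling, confirming m > 1
  changed <- FALSE
  for (i in which(tab$diagnosis == "OND")) {
    t2 <- tab; t2$diagnosis[i] <- "AD"
    l2 <- tryCatch(label_clusters(t2, lab), error = function(e) NULL)
    if (is.null(l2) || l2$control != lbl$control ||
        !identical(l2$ad_like, lbl$ad_like)) changed <- TRUE
  }
  expect_false(changed)
})

test_that("misdiagnosis tolerance requires OND spread over clusters", {
  df <- tiny_cohort_df(12)
  df$diagnosis <- c(rep("OND", 4), rep("AD", 8))
  lab <- c(rep(1L, 4), rep(2L, 8))
  tab <- as_cohort_table(df)
  lbl <- label_clusters(tab, lab)
  expect_error(misdiagnosis_tolerance(tab, lab, lbl), "fewer than 2")
})

test_that("Fisher's exact p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), fisher_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 0.485714, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)   # zero margin
  set.seed(9)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 fisher.test(tb)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})
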