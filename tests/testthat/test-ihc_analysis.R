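test_that("composite score hits its ceiling, floor and bin edges", {
  expect_equal(composite_score(1.0, 3)$total, 8)   # maximum score
  expect_equal(composite_score(0, 0)$total, 0)
  sc <- composite_score(0.005, 2)
  expect_equal(sc$proportion_bin, 1L)
  expect_equal(sc$total, 3)
  # declared bin edges
  expect_equal(composite_score(c(0, 0.009, 0.01, 0.1, 1 / 3, 2 / 3), 0)$proportion_bin,
               c(0L, 1L, 2L, 3L, 4L, 5L))
  expect_error(composite_score(1.2, 1), "\\[0,1\\]")
  expect_error(composite_score(0.5, 3.2), "\\[0,3\\]")
})

test_that("composite score is monotone in both inputs", {
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(composite_score(p, 1.5)$total) >= 0))
  i <- seq(0, 3, by = 0.05)
  expect_true(all(diff(composite_score(0.5, i)$total) >= 0))
})

test_that("replicate aggregation follows the chosen rule before binning", {
  ihc <- data.frame(tumor_id = "t1", marker = "ER",
                    proportion_positive = c(0.2, 0.4, 0.6),
                    intensity = c(1, 2, 3),
                    replicate_id = c("r1", "r2", "r3"))
  m <- aggregate_replicates(ihc, "mean")
  expect_equal(m$proportion_bin, composite_score(0.4, 2)$proportion_bin)
  expect_equal(m$total, composite_score(0.4, 2)$total)
  expect_equal(m$n_replicates_aggregated, 3L)

  ihc2 <- data.frame(tumor_id = "t1", marker = "ER",
                     proportion_positive = c(0.2, 0.8),
                     intensity = c(1, 3),
                     replicate_id = c("r1", "r2"))
  expect_equal(aggregate_replicates(ihc2, "max")$total,
               composite_score(0.8, 3)$total)

  same <- ihc2; same$proportion_positive <- 0.5; same$intensity <- 2
  for (rule in c("mean", "median", "max"))
    expect_equal(aggregate_replicates(same, rule)$total,
                 composite_score(0.5, 2)$total)
})

test_that("positivity calls use >= on the cut-off", {
  expect_identical(as.character(call_marker_status(4, 4)), "positive")
  expect_identical(as.character(call_marker_status(3, 3)), "positive")
  expect_identical(as.character(call_marker_status(2.9, 3)), "negative")
})

test_that("Kruskal-Wallis H matches the hand-ranked example and Dunn behaves", {
  cmp <- compare_groups(1:6, rep(c("A", "B", "C"), each = 2))
  expect_equal(cmp$kw_H, 12 / (6 * 7) * 16, tolerance = 1e-12)  # 4.571...
  expect_equal(nrow(cmp$pairwise), 3L)
  expect_true(all(cmp$pairwise$adjusted_p >= cmp$pairwise$p_value))

  # identical value multisets: H ~ 0, adjusted p ~ 1
  cmp0 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_lt(cmp0$kw_H, 1e-10)
  expect_true(all(cmp0$pairwise$adjusted_p > 0.99))

  expect_error(compare_groups(rep(2, 6), rep(c("A", "B"), each = 3)),
               "identical")
  expect_error(compare_groups(1:3, c("A", "A", "B")), ">= 2")
})

test_that("relabeling groups permutes pairs but changes no statistic", {
  set.seed(9)
  x <- rnorm(30)
  g <- rep(c("A", "B", "C"), 10)
  relabel <- c(A = "Z", B = "Y", C = "X")
  c1 <- compare_groups(x, g)
  c2 <- compare_groups(x, relabel[g])
  expect_equal(c1$kw_H, c2$kw_H)
  expect_equal(sort(abs(c1$pairwise$dunn_z)), sort(abs(c2$pairwise$dunn_z)))
  expect_equal(sort(c1$pairwise$adjusted_p), sort(c2$pairwise$adjusted_p))
})

test_that("marker regression: exact fits and the R2 = r^2 identity", {
  x <- setNames(c(1, 2, 3, 4), paste0("t", 1:4))
  fit <- pairwise_marker_regression(x, x)
  expect_equal(fit$slope, 1); expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  y <- setNames(c(1, 3, 2, 4), paste0("t", 1:4))
  fit2 <- pairwise_marker_regression(x, y)
  expect_equal(fit2$r_squared, 0.64)
  expect_equal(fit2$r_squared, pearson_correlation(unname(x), unname(y))^2,
               tolerance = 1e-10)

  expect_equal(pairwise_marker_regression(x, setNames(rep(2, 4), names(x)))$r_squared, 0)
  expect_error(pairwise_marker_regression(setNames(rep(1, 4), names(x)), y),
               "zero variance")
  expect_error(pairwise_marker_regression(x[1:2], y[1:2]), ">= 3")
})

test_that("R2 = r^2 holds on synthetic marker scores to 1e-10", {
  co <- generate_cohort(cohort_params(n_samples = 300, seed = 19))
  sm <- score_matrix(co$ihc)
  fit <- pairwise_marker_regression(sm[, "ER"], sm[, "CAXII"])
  expect_equal(fit$r_squared,
               pearson_correlation(sm[, "ER"], sm[, "CAXII"])^2,
               tolerance = 1e-10)
})

test_that("trough cut-off plus >= call recovers planted classes", {
  set.seed(31)
  pl <- planted_scores(400)
  cut <- trough_cutoff_from_scores(pl$scores)
  called <- ifelse(call_marker_status(pl$scores, cut) == "positive",
                   "high", "low")
  expect_gte(mean(called == pl$truth), 0.95)
})

test_that("ER-positive tumors' CAXII scores dominate ER-negative tumors'", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(cohort_params(n_samples = 500, seed = 100 + s))
    sm <- score_matrix(co$ihc)
    er_pos <- co$clinical$er_status[match(rownames(sm),
                                          co$clinical$sample_id)] == "positive"
    p <- wilcox.test(sm[er_pos, "CAXII"], sm[!er_pos, "CAXII"],
                     alternative = "greater", exact = FALSE)$p.value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 9L)
})

test_that("clinical receptor groups are derived correctly", {
  cl <- data.frame(sample_id = paste0("s", 1:5),
                   er_status = c("positive", "positive", "negative",
                                 "negative", "unknown"),
                   pr_status = c("positive", "negative", "negative",
                                 "positive", "positive"),
                   her2_status = c("negative", "negative", "positive",
                                   "negative", "negative"))
  g <- clinical_groups(cl)
  expect_identical(unname(g),
                   c("ER+PR+", "ER+PR-", "ER-HER2+", "ER-HER2-", NA))
})
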