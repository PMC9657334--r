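test_that("Pearson wrapper reproduces hand-computed values", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(-1, -2, -3)), -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("exclusion statistic matches the worked example", {
  vals <- c(1:10, 8, 9.5, 11, 12, 20)
  cls <- rep(c("low", "high"), c(10, 5))
  ex <- exclusion_at_reference_specificity(vals, cls, q = 0.9)
  expect_equal(ex$threshold, 9)
  expect_equal(ex$excluded_low_fraction, 0.9)
  expect_equal(ex$excluded_high_fraction, 0.2)  # only the 8
  expect_equal(ex$excluded_high_as_fraction_of_all, 1 / 15)
  expect_equal(ex$n_low + ex$n_high, 15L)
})

test_that("exclusion edge cases: separation, q = 1, bad inputs", {
  vals <- c(1:10, 20:24)
  cls <- rep(c("low", "high"), c(10, 5))
  ex <- exclusion_at_reference_specificity(vals, cls, q = 0.9)
  expect_equal(ex$excluded_high_fraction, 0)

  vals2 <- c(1:10, 2:6)
  ex2 <- exclusion_at_reference_specificity(vals2, cls, q = 1)
  expect_equal(ex2$threshold, 10)
  expect_equal(ex2$excluded_high_fraction, 1)

  expect_error(exclusion_at_reference_specificity(vals, cls, q = 0), "\\(0, 1\\]")
  expect_error(exclusion_at_reference_specificity(1:5, rep("low", 5)),
               "non-empty")
})

test_that("exclusion agrees exactly with a brute-force threshold scan", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(20:200, 1)
    cls <- ifelse(runif(n) < 0.4, "low", "high")
    if (length(unique(cls)) < 2) cls[1:2] <- c("low", "high")
    vals <- round(rnorm(n, ifelse(cls == "high", 2, 0), 1.5), 2)
    q <- runif(1, 0.5, 1)
    ex <- exclusion_at_reference_specificity(vals, cls, q)
    bf <- brute_exclusion(vals, cls, q)
    expect_identical(ex$threshold, bf$threshold)
    expect_identical(ex$excluded_low_fraction, bf$excluded_low_fraction)
    expect_identical(ex$excluded_high_fraction, bf$excluded_high_fraction)
  }
})

test_that("excluded-high fraction is non-decreasing in q", {
  set.seed(12)
  n <- 150
  cls <- rep(c("low", "high"), c(60, 90))
  vals <- rnorm(n, ifelse(cls == "high", 2, 0))
  qs <- seq(0.05, 1, by = 0.05)
  fr <- vapply(qs, function(q)
    exclusion_at_reference_specificity(vals, cls, q)$excluded_high_fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("exclusion metrics are rank-invariant; Pearson is affine-invariant", {
  set.seed(6)
  cls <- rep(c("low", "high"), c(40, 60))
  vals <- rnorm(100, ifelse(cls == "high", 3, 0))
  ex <- exclusion_at_reference_specificity(vals, cls, 0.9)
  ex_t <- exclusion_at_reference_specificity(exp(vals / 2), cls, 0.9)
  expect_equal(ex_t$excluded_low_fraction, ex$excluded_low_fraction)
  expect_equal(ex_t$excluded_high_fraction, ex$excluded_high_fraction)

  x <- rnorm(50); y <- x + rnorm(50, 0, 0.5)
  expect_equal(pearson_correlation(3 * x - 1, y), pearson_correlation(x, y))
  expect_false(isTRUE(all.equal(pearson_correlation(exp(x), y),
                                pearson_correlation(x, y))))
})

test_that("status discordance counts both directions and skips unknowns", {
  cls <- rep(c("high", "low"), c(3, 3))
  st <- c("positive", "negative", "positive", "negative", "positive", "unknown")
  d <- status_discordance(cls, st)
  expect_equal(d$n_compared, 5L)
  expect_equal(d$n_unknown_excluded, 1L)
  expect_equal(d$n_high_but_negative, 1L)
  expect_equal(d$n_low_but_positive, 1L)
  expect_equal(d$discordance_rate, 2 / 5)

  expect_equal(status_discordance(c("high", "low"),
                                  c("positive", "negative"))$discordance_rate, 0)
  expect_equal(status_discordance(c("high", "low"),
                                  c("negative", "positive"))$discordance_rate, 1)
  expect_error(status_discordance(cls, rep("unknown", 6)), "unknown")
})

test_that("a planted 13.4% mismatch is counted exactly", {
  set.seed(20)
  n <- 1000
  cls <- ifelse(runif(n) < 0.6, "high", "low")
  st <- ifelse(cls == "high", "positive", "negative")
  flip <- sample(n, 134)
  st[flip] <- ifelse(st[flip] == "positive", "negative", "positive")
  expect_equal(status_discordance(cls, st)$discordance_rate, 0.134)
})

test_that("discordance is symmetric on fully known data", {
  set.seed(30)
  a <- ifelse(runif(200) < 0.5, "high", "low")
  b <- ifelse(runif(200) < 0.5, "high", "low")
  d1 <- status_discordance(a, ifelse(b == "high", "positive", "negative"))
  d2 <- status_discordance(b, ifelse(a == "high", "positive", "negative"))
  expect_equal(d1$n_discordant, d2$n_discordant)
})

test_that("rescue fractions count the target group correctly", {
  ref <- rep("high", 6); pri <- c(rep("low", 4), "high", "high")
  alt <- list(TFF1 = c("high", "high", "high", "low", "low", "low"))
  r <- rescue_fraction(ref, pri, alt)
  expect_equal(r$n_target_group, 4L)
  expect_equal(unname(r$per_gene_high_fraction["TFF1"]), 0.75)

  r0 <- rescue_fraction(ref, pri, list(A = rep("low", 6), B = rep("low", 6)))
  expect_true(all(r0$per_gene_high_fraction == 0))
  expect_equal(r0$union_high_fraction, 0)

  # union bound tight case: each gene rescues a different tumor
  ref2 <- c("high", "high"); pri2 <- c("low", "low")
  r2 <- rescue_fraction(ref2, pri2,
                        list(A = c("high", "low"), B = c("low", "high")))
  expect_equal(unname(r2$per_gene_high_fraction), c(0.5, 0.5))
  expect_equal(r2$union_high_fraction, 1)

  expect_error(rescue_fraction(rep("low", 3), rep("low", 3),
                               list(A = rep("high", 3))), "size 0")
})

test_that("evaluate_candidates: self-comparison, empty list, missing gene", {
  co <- generate_cohort(cohort_params(n_samples = 400, seed = 14))
  rep0 <- evaluate_candidates(co$expression, "ESR1", character(0), seed = 14)
  expect_equal(nrow(rep0$candidates), 0L)
  expect_s3_class(rep0$fit, "mixture_fit")

  rep1 <- evaluate_candidates(co$expression, "ESR1", "ESR1", seed = 14,
                              primary_candidate = NULL)
  expect_equal(rep1$candidates$pearson_r, 1.0)

  expect_error(evaluate_candidates(co$expression, "ESR1", "NOSUCH"),
               "NOSUCH")
})

test_that("on a default cohort CA12 excludes fewer reference-high tumors than PGR", {
  co <- generate_cohort(cohort_params(n_samples = 750, seed = 77))
  rep <- evaluate_candidates(co$expression, "ESR1", c("PGR", "CA12"),
                             clinical = co$clinical, seed = 77)
  tab <- rep$candidates
  expect_lt(tab$excluded_high_fraction[tab$gene == "CA12"],
            tab$excluded_high_fraction[tab$gene == "PGR"])
  expect_gt(tab$pearson_r[tab$gene == "CA12"],
            tab$pearson_r[tab$gene == "PGR"])
  expect_false(is.null(rep$reference_discordance))
})
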