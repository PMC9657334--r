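# Immunohistochemistry arm: composite (Allred-style) scores from
# proportion-of-positive-cells and staining intensity, replicate
# aggregation, trough-calibrated positivity calls, inter-marker
# regression and rank-based group comparisons.

# Allred-style bin edges for the proportion of positive cells.
# Overridable because the exact digitization used by a given image-
# analysis pipeline may differ.
default_proportion_bins <- function() c(0, 0.01, 0.10, 1 / 3, 2 / 3)

bin_proportion <- function(p, edges = default_proportion_bins()) {
  # 0: p = 0; 1: 0 < p < edges[2]; ...; 5: p >= edges[5]
  out <- integer(length(p))
  out[p > edges[1]] <- 1L
  for (j in 2:length(edges)) out[p >= edges[j]] <- j
  out
}

#' Composite IHC score from proportion and intensity
#'
#' The proportion of positive cells is digitized to a 0-5 bin
#' (Allred-style edges: 0; (0, 0.01); \[0.01, 0.10); \[0.10, 1/3);
#' \[1/3, 2/3); \[2/3, 1\]) and added to the staining intensity, kept
#' as a real value on its 0-3 scale, for a maximum total score of 8.
#'
#' @param proportion_positive Numeric in \[0,1\] (vectorized).
#' @param intensity Numeric in \[0,3\] (vectorized).
#' @param proportion_edges Bin edges (5 increasing values starting
#'   at 0).
#' @return data.frame with `proportion_bin`, `intensity_component`,
#'   `total`.
#' @examples
#' composite_score(1.0, 3)   # the score ceiling: total 8
#' composite_score(0.005, 2) # bin 1, total 3
#' @export
composite_score <- function(proportion_positive, intensity,
                            proportion_edges = default_proportion_bins()) {
  if (any(!is.finite(proportion_positive) | proportion_positive < 0 |
          proportion_positive > 1))
    stop_data("proportion_positive must lie in [0,1]")
  if (any(!is.finite(intensity) | intensity < 0 | intensity > 3))
    stop_data("intensity must lie in [0,3]")
  bin <- bin_proportion(proportion_positive, proportion_edges)
  data.frame(proportion_bin = bin,
             intensity_component = intensity,
             total = bin + intensity)
}

#' Aggregate replicate IHC cores into one composite score per tumor/marker
#'
#' Raw proportion and intensity are combined across replicates by the
#' chosen rule *before* binning (binning after averaging is less
#' quantization-noisy than averaging bins), then scored.
#'
#' @param ihc IHC data.frame as from [read_ihc()].
#' @param rule `"mean"` (default), `"median"` or `"max"`.
#' @return data.frame with one row per (tumor_id, marker):
#'   `tumor_id`, `marker`, `proportion_bin`, `intensity_component`,
#'   `total`, `n_replicates_aggregated`.
#' @export
aggregate_replicates <- function(ihc, rule = c("mean", "median", "max")) {
  rule <- match.arg(rule)
  f <- switch(rule, mean = mean, median = median, max = max)
  key <- interaction(ihc$tumor_id, ihc$marker, drop = TRUE, sep = "\r")
  agg <- function(v) tapply(v, key, f)
  prop <- agg(ihc$proportion_positive)
  inten <- agg(ihc$intensity)
  nrep <- tapply(ihc$proportion_positive, key, length)
  ids <- strsplit(names(prop), "\r", fixed = TRUE)
  sc <- composite_score(unname(prop), pmin(3, unname(inten)))
  out <- data.frame(tumor_id = vapply(ids, `[[`, "", 1L),
                    marker = vapply(ids, `[[`, "", 2L),
                    sc,
                    n_replicates_aggregated = as.integer(nrep),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Positivity call from a composite score
#'
#' Positive iff `score >= cutoff` (the IHC convention: cut-offs are
#' quoted as "score >= c", e.g. >= 4 for a nuclear marker, >= 3 for a
#' membrane marker, after trough calibration).
#'
#' @param score Numeric in \[0,8\] (vectorized).
#' @param cutoff Numeric in \[0,8\].
#' @return Factor with levels `negative`, `positive`.
#' @export
call_marker_status <- function(score, cutoff) {
  stopifnot(all(score >= 0 & score <= 8), cutoff >= 0, cutoff <= 8)
  factor(ifelse(score >= cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Kruskal-Wallis test with Dunn's post-hoc pairwise comparisons
#'
#' The omnibus H statistic (tie-corrected) comes from
#' [stats::kruskal.test()]; Dunn's pairwise z statistics are computed
#' from the joint ranks with the tie correction
#' `sum(t^3 - t) / (12 (N - 1))`, and two-sided p-values are adjusted
#' across all unordered pairs (Bonferroni by default, Holm available).
#'
#' @param scores Numeric vector.
#' @param groups Group label per observation, aligned with `scores`.
#' @param p_adjust_method `"bonferroni"` (default) or `"holm"`.
#' @return Object of class `group_comparison`: `kw_H`, `kw_df`,
#'   `kw_p`, `group_sizes`, `pairwise` (data.frame with `group_a`,
#'   `group_b`, `dunn_z`, `p_value`, `adjusted_p`).
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("A", "B", "C"), each = 2))
#' @export
compare_groups <- function(scores, groups,
                           p_adjust_method = c("bonferroni", "holm")) {
  p_adjust_method <- match.arg(p_adjust_method)
  if (length(scores) != length(groups))
    stop_data("scores and groups must be aligned")
  ok <- is.finite(scores) & !is.na(groups)
  scores <- scores[ok]; groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (nlevels(groups) < 2L || any(sizes < 2L))
    stop_data("need >= 2 groups with >= 2 observations each")
  if (length(unique(scores)) == 1L)
    stop_data("all scores identical: rank statistics undefined")

  kw <- kruskal.test(scores, groups)

  N <- length(scores)
  r <- rank(scores)
  ties <- table(scores)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                         dunn_z = z, p_value = p_raw,
                         adjusted_p = pmin(1, p.adjust(p_raw,
                                                       p_adjust_method)),
                         stringsAsFactors = FALSE)
  structure(list(kw_H = unname(kw$statistic), kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, group_sizes = sizes,
                 pairwise = pairwise,
                 p_adjust_method = p_adjust_method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d), p = %.3g\n",
              x$kw_H, x$kw_df, x$kw_p))
  cat("Dunn post-hoc (", x$p_adjust_method, "-adjusted):\n", sep = "")
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Ordinary least-squares regression between two markers' scores
#'
#' Regresses `scores_y` on `scores_x` over tumors present in both
#' score vectors (matched by name) and reports the coefficient of
#' determination, which for simple OLS equals the squared Pearson
#' correlation of the paired scores.
#'
#' @param scores_x,scores_y Named numeric vectors (tumor id -> score).
#' @param marker_x,marker_y Optional marker names for the report.
#' @return Object of class `regression_fit`: `marker_x`, `marker_y`,
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
pairwise_marker_regression <- function(scores_x, scores_y,
                                       marker_x = NA_character_,
                                       marker_y = NA_character_) {
  if (is.null(names(scores_x)) || is.null(names(scores_y)))
    stop_data("score vectors must be named by tumor id")
  shared <- intersect(names(scores_x), names(scores_y))
  if (length(shared) < 3L)
    stop_data("need >= 3 shared tumors (got ", length(shared), ")")
  x <- scores_x[shared]; y <- scores_y[shared]
  if (sd(x) == 0) stop_data("zero variance in x: regression undefined")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(marker_x = marker_x, marker_y = marker_y,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2, n = length(shared)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit %s ~ %s: slope %.3f, intercept %.3f, R2 %.3f (n = %d)\n",
              x$marker_y, x$marker_x, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Composite-score matrix from an IHC table
#'
#' Convenience wrapper: aggregates replicates, then spreads total
#' scores to a tumors x markers matrix.
#'
#' @param ihc IHC data.frame as from [read_ihc()].
#' @param rule Replicate aggregation rule (see
#'   [aggregate_replicates()]).
#' @return Numeric matrix, rownames = tumor ids, colnames = markers.
#' @export
score_matrix <- function(ihc, rule = "mean") {
  agg <- aggregate_replicates(ihc, rule)
  tumors <- unique(agg$tumor_id)
  markers <- unique(agg$marker)
  m <- matrix(NA_real_, length(tumors), length(markers),
              dimnames = list(tumors, markers))
  m[cbind(match(agg$tumor_id, tumors), match(agg$marker, markers))] <-
    agg$total
  m
}

#' Clinical receptor groups for score comparisons
#'
#' Derives the standard four-way grouping ER+PR+ / ER+PR- / ER-HER2+ /
#' ER-HER2- from a clinical table; tumors with unknown ER status (or
#' unknown PR/HER2 where needed) get `NA`.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @return Named character vector (sample id -> group label).
#' @export
clinical_groups <- function(clinical) {
  er <- clinical$er_status; pr <- clinical$pr_status
  her2 <- clinical$her2_status
  g <- rep(NA_character_, nrow(clinical))
  g[er == "positive" & pr == "positive"] <- "ER+PR+"
  g[er == "positive" & pr == "negative"] <- "ER+PR-"
  g[er == "negative" & her2 == "positive"] <- "ER-HER2+"
  g[er == "negative" & her2 == "negative"] <- "ER-HER2-"
  setNames(g, clinical$sample_id)
}
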