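# Paper-level statistics comparing candidate surrogate genes against a
# reference gene: Pearson correlation, exclusion at fixed reference
# specificity, RNA/clinical-status discordance, and rescue
# cross-tabulation over alternative target genes.

as_low_high <- function(cls) {
  if (is.logical(cls)) cls <- ifelse(cls, "high", "low")
  cls <- as.character(cls)
  bad <- setdiff(unique(cls[!is.na(cls)]), c("low", "high"))
  if (length(bad))
    stop_data("class vector must contain only 'low'/'high' (found: ",
              paste(bad, collapse = ", "), ")")
  factor(cls, levels = c("low", "high"))
}

#' Sample Pearson correlation
#'
#' Thin, validating wrapper around [stats::cor()]: equal lengths of at
#' least 3 and nonzero variance in both vectors are enforced so that a
#' degenerate input fails loudly rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (length(x) < 3L) stop_data("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop_data("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("zero variance: Pearson correlation undefined")
  cor(x, y)
}

#' Exclusion of reference-high samples at fixed reference-low specificity
#'
#' Finds the candidate-gene threshold `t` = the smallest observed
#' candidate value such that at least a fraction `q` of reference-low
#' samples have value <= `t` (the empirical inverse CDF of the low
#' group; no interpolation). A sample is *excluded* iff its candidate
#' value is <= `t`. The statistic of interest is how many
#' reference-high samples that low-capturing cut-off also excludes: a
#' perfect surrogate excludes none.
#'
#' @param candidate_values Numeric vector of the candidate gene's
#'   expression, aligned with `reference_class`.
#' @param reference_class `low`/`high` factor (or logical, TRUE =
#'   high) for the reference gene.
#' @param q Required specificity on the reference-low group, in (0,1].
#' @param candidate_gene Optional name carried into the result.
#' @return An object of class `exclusion_result`: `candidate_gene`,
#'   `specificity_q`, `threshold`, `excluded_low_fraction` (>= q by
#'   construction), `excluded_high_fraction`,
#'   `excluded_high_as_fraction_of_all`,
#'   `excluded_low_as_fraction_of_all`, `n_low`, `n_high`.
#' @examples
#' vals <- c(1:10, 8, 9.5, 11, 12, 20)
#' cls <- rep(c("low", "high"), c(10, 5))
#' exclusion_at_reference_specificity(vals, cls, q = 0.9)
#' @export
exclusion_at_reference_specificity <- function(candidate_values,
                                               reference_class,
                                               q = 0.9,
                                               candidate_gene = NA_character_) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop_data("q must lie in (0, 1]")
  cls <- as_low_high(reference_class)
  if (length(candidate_values) != length(cls))
    stop_data("candidate_values and reference_class must be aligned")
  ok <- is.finite(candidate_values) & !is.na(cls)
  v <- candidate_values[ok]; cls <- cls[ok]
  low <- v[cls == "low"]; high <- v[cls == "high"]
  if (!length(low) || !length(high))
    stop_data("both reference classes must be non-empty")
  t <- unname(sort(low)[ceiling(q * length(low))])
  structure(list(
    candidate_gene = candidate_gene,
    specificity_q = q,
    threshold = t,
    excluded_low_fraction = mean(low <= t),
    excluded_high_fraction = mean(high <= t),
    excluded_high_as_fraction_of_all = sum(high <= t) / length(v),
    excluded_low_as_fraction_of_all = sum(low <= t) / length(v),
    n_low = length(low), n_high = length(high)),
    class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf(
    "exclusion_result [%s]: q=%.2f, threshold=%.4g\n  low excluded: %.1f%% (%.1f%% of all)\n  high excluded: %.1f%% (%.1f%% of all)  [n_low=%d, n_high=%d]\n",
    x$candidate_gene, x$specificity_q, x$threshold,
    100 * x$excluded_low_fraction, 100 * x$excluded_low_as_fraction_of_all,
    100 * x$excluded_high_fraction, 100 * x$excluded_high_as_fraction_of_all,
    x$n_low, x$n_high))
  invisible(x)
}

#' Discordance between an RNA-derived class and a clinical status
#'
#' Counts samples whose `low`/`high` RNA class contradicts their
#' ternary clinical status: (`high`, negative) or (`low`, positive).
#' Samples with unknown status are excluded from the denominator (the
#' count of exclusions is reported).
#'
#' @param rna_class `low`/`high` factor or logical (TRUE = high).
#' @param clinical_status Character vector in
#'   positive/negative/unknown, aligned with `rna_class`.
#' @param marker Optional marker name carried into the result.
#' @return Object of class `concordance_result`: `marker`,
#'   `n_compared`, `n_unknown_excluded`, `n_discordant`,
#'   `discordance_rate`, `n_high_but_negative`, `n_low_but_positive`.
#' @export
status_discordance <- function(rna_class, clinical_status,
                               marker = NA_character_) {
  cls <- as_low_high(rna_class)
  st <- as.character(clinical_status)
  if (length(st) != length(cls))
    stop_data("rna_class and clinical_status must be aligned")
  bad <- setdiff(unique(st), c("positive", "negative", "unknown", NA))
  if (length(bad))
    stop_data("clinical_status values must be positive/negative/unknown ",
              "(found: ", paste(bad, collapse = ", "), ")")
  st[is.na(st)] <- "unknown"
  known <- st != "unknown"
  if (!any(known)) stop_data("all clinical statuses are unknown")
  cls <- cls[known]; st <- st[known]
  hi_neg <- sum(cls == "high" & st == "negative")
  lo_pos <- sum(cls == "low" & st == "positive")
  structure(list(marker = marker,
                 n_compared = length(cls),
                 n_unknown_excluded = sum(!known),
                 n_discordant = hi_neg + lo_pos,
                 discordance_rate = (hi_neg + lo_pos) / length(cls),
                 n_high_but_negative = hi_neg,
                 n_low_but_positive = lo_pos),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance_result [%s]: %d/%d discordant (%.1f%%; high/neg %d, low/pos %d; %d unknown excluded)\n",
    x$marker, x$n_discordant, x$n_compared, 100 * x$discordance_rate,
    x$n_high_but_negative, x$n_low_but_positive, x$n_unknown_excluded))
  invisible(x)
}

#' Rescue of reference-high / primary-low samples by alternative genes
#'
#' Among samples that are reference-high but low for the primary
#' surrogate (e.g. ESR1-high, PGR-low), reports the fraction classed
#' high for each alternative target gene and for their union — i.e.
#' how many apparently surrogate-negative tumors are "rescued" by at
#' least one other readout of the reference's activity.
#'
#' @param reference_class,primary_candidate_class Aligned `low`/`high`
#'   vectors.
#' @param alt_gene_classes Named list of aligned `low`/`high` vectors,
#'   one per alternative gene.
#' @return Object of class `rescue_result`: `n_target_group`,
#'   `per_gene_high_fraction` (named), `union_high_fraction`.
#' @export
rescue_fraction <- function(reference_class, primary_candidate_class,
                            alt_gene_classes) {
  ref <- as_low_high(reference_class)
  pri <- as_low_high(primary_candidate_class)
  if (length(ref) != length(pri))
    stop_data("reference and primary class vectors must be aligned")
  target <- which(ref == "high" & pri == "low")
  if (!length(target))
    stop_data("target group (reference-high & primary-low) has size 0")
  any_high <- rep(FALSE, length(target))
  per_gene <- vapply(alt_gene_classes, function(cls) {
    cls <- as_low_high(cls)
    if (length(cls) != length(ref))
      stop_data("alternative class vector not aligned with reference")
    hi <- cls[target] == "high"
    any_high <<- any_high | hi
    mean(hi)
  }, 0)
  structure(list(n_target_group = length(target),
                 per_gene_high_fraction = per_gene,
                 union_high_fraction = mean(any_high)),
            class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("rescue_result: target group n=%d\n", x$n_target_group))
  for (g in names(x$per_gene_high_fraction))
    cat(sprintf("  %s high: %.1f%%\n", g, 100 * x$per_gene_high_fraction[g]))
  cat(sprintf("  union high: %.1f%%\n", 100 * x$union_high_fraction))
  invisible(x)
}

#' Evaluate candidate surrogate genes against a reference gene
#'
#' End-to-end RNA-level comparison: fits the reference gene's
#' two-component mixture and derives low/high classes, then for every
#' candidate computes the Pearson correlation with the reference, the
#' exclusion statistic at reference-low specificity `q`, and (when a
#' clinical table and status mapping are supplied) the discordance of
#' the candidate's own exclusion-derived class with its clinical
#' status. A rescue analysis is run for the designated primary
#' candidate using the remaining candidates as alternatives; all genes'
#' low/high classes in the rescue use their own `q`-specificity
#' thresholds, mirroring a common box construction across target
#' genes.
#'
#' @param expression Genes x samples numeric matrix (as from
#'   [read_expression()] or a synthetic cohort).
#' @param reference_gene Reference gene id (default `"ESR1"`).
#' @param candidate_genes Character vector of candidate gene ids.
#' @param clinical Optional clinical data.frame (see
#'   [read_clinical()]); aligned to the matrix by `sample_id`.
#' @param q Reference-low specificity for the exclusion statistic.
#' @param seed Seed for the mixture fit's random restart.
#' @param primary_candidate Gene whose low samples define the rescue
#'   target group (default `"PGR"`); set `NULL` to skip.
#' @param status_column_map Named map gene -> clinical status column
#'   used for discordance.
#' @return Object of class `surrogate_report`: `reference_gene`,
#'   `fit` (the reference `mixture_fit`), `reference_class`,
#'   `reference_discordance` (vs the reference's own status column, or
#'   `NULL`), `candidates` (one data.frame row per candidate),
#'   `exclusions` (list of `exclusion_result`), `rescue`
#'   (`rescue_result` or `NULL`).
#' @export
evaluate_candidates <- function(expression,
                                reference_gene = "ESR1",
                                candidate_genes,
                                clinical = NULL,
                                q = 0.9,
                                seed = 1L,
                                primary_candidate = "PGR",
                                status_column_map = c(ESR1 = "er_status",
                                                      PGR = "pr_status")) {
  genes <- unique(c(reference_gene, candidate_genes))
  absent <- setdiff(genes, rownames(expression))
  if (length(absent))
    stop_data("gene(s) not in expression matrix: ",
              paste(absent, collapse = ", "))
  if (!is.null(clinical)) {
    missing_samples <- setdiff(colnames(expression), clinical$sample_id)
    if (length(missing_samples))
      stop_data(length(missing_samples),
                " sample(s) absent from the clinical table, e.g. ",
                missing_samples[1])
    clinical <- clinical[match(colnames(expression), clinical$sample_id), ]
  }

  ref_values <- expression[reference_gene, ]
  fit <- fit_two_component_mixture(ref_values, seed = seed)
  if (is.na(fit$threshold))
    stop_data("reference gene ", reference_gene, " is not bimodal: ",
              "no low/high classes can be derived")
  ref_class <- classify_low_high(ref_values, fit)

  ref_disc <- NULL
  ref_col <- status_column_map[reference_gene]
  if (!is.null(clinical) && !is.na(ref_col) && ref_col %in% names(clinical))
    ref_disc <- status_discordance(ref_class, clinical[[ref_col]],
                                   marker = reference_gene)

  exclusions <- list()
  classes <- list()
  rows <- lapply(candidate_genes, function(g) {
    v <- expression[g, ]
    ex <- exclusion_at_reference_specificity(v, ref_class, q = q,
                                             candidate_gene = g)
    exclusions[[g]] <<- ex
    classes[[g]] <<- factor(ifelse(v > ex$threshold, "high", "low"),
                            levels = c("low", "high"))
    disc_rate <- NA_real_; n_cmp <- NA_integer_
    col <- status_column_map[g]
    if (!is.null(clinical) && !is.na(col) && col %in% names(clinical)) {
      d <- status_discordance(classes[[g]], clinical[[col]], marker = g)
      disc_rate <- d$discordance_rate; n_cmp <- d$n_compared
    }
    data.frame(gene = g,
               pearson_r = pearson_correlation(ref_values, v),
               threshold = ex$threshold,
               excluded_low_fraction = ex$excluded_low_fraction,
               excluded_high_fraction = ex$excluded_high_fraction,
               excluded_high_as_fraction_of_all = ex$excluded_high_as_fraction_of_all,
               excluded_low_as_fraction_of_all = ex$excluded_low_as_fraction_of_all,
               discordance_rate = disc_rate,
               n_status_compared = n_cmp,
               stringsAsFactors = FALSE)
  })
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0))
  rownames(candidates) <- NULL

  rescue <- NULL
  if (!is.null(primary_candidate) && primary_candidate %in% candidate_genes) {
    alts <- setdiff(candidate_genes, primary_candidate)
    if (length(alts) && any(ref_class == "high" &
                            classes[[primary_candidate]] == "low"))
      rescue <- rescue_fraction(ref_class, classes[[primary_candidate]],
                                classes[alts])
  }

  structure(list(reference_gene = reference_gene, fit = fit,
                 reference_class = ref_class,
                 reference_discordance = ref_disc,
                 candidates = candidates, exclusions = exclusions,
                 candidate_classes = classes, rescue = rescue,
                 specificity_q = q),
            class = "surrogate_report")
}

#' @export
print.surrogate_report <- function(x, ...) {
  cat(sprintf("surrogate_report: reference %s (threshold %.4g), q=%.2f\n",
              x$reference_gene, x$fit$threshold, x$specificity_q))
  if (!is.null(x$reference_discordance))
    cat(sprintf("  reference status discordance: %.1f%%\n",
                100 * x$reference_discordance$discordance_rate))
  print(x$candidates, digits = 3)
  if (!is.null(x$rescue)) print(x$rescue)
  invisible(x)
}
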