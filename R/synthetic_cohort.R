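# Synthetic tumor-cohort generator. Samples carry a subtype label and
# two latent regulator activities (ER, GATA3); each gene is a linear
# readout of those activities plus Gaussian noise, with optional
# subtype-specific dropout (loss of the regulatory input). Activities
# are on a nonnegative scale (~0 in receptor-low subtypes, ~3 in
# luminal), so `baseline` is a gene's floor expression and a dropped
# gene falls back to its low mode.

default_gene_models <- function(n_decoy_genes = 3L) {
  zero4 <- c(LumA = 0, LumB = 0, mApo = 0, Basal = 0)
  models <- list(
    ESR1  = list(baseline = 5.0, er_weight = 1.5, gata3_weight = 0.3,
                 noise_sd = 0.7, dropout = zero4),
    PGR   = list(baseline = 4.0, er_weight = 1.4, gata3_weight = 0.0,
                 noise_sd = 1.0,
                 dropout = c(LumA = 0.05, LumB = 0.35, mApo = 0, Basal = 0)),
    CA12  = list(baseline = 5.5, er_weight = 0.9, gata3_weight = 0.9,
                 noise_sd = 0.7, dropout = zero4),
    TFF1  = list(baseline = 4.5, er_weight = 1.4, gata3_weight = 0.0,
                 noise_sd = 2.0, dropout = zero4),
    GREB1 = list(baseline = 5.0, er_weight = 1.3, gata3_weight = 0.0,
                 noise_sd = 1.0, dropout = zero4),
    FOXA1 = list(baseline = 6.0, er_weight = 0.4, gata3_weight = 0.8,
                 noise_sd = 0.7, dropout = zero4),
    GATA3 = list(baseline = 5.0, er_weight = 0.0, gata3_weight = 1.3,
                 noise_sd = 0.6, dropout = zero4))
  if (n_decoy_genes > 0L) {
    for (i in seq_len(n_decoy_genes)) {
      models[[sprintf("DECOY%d", i)]] <-
        list(baseline = 7.0, er_weight = 0, gata3_weight = 0,
             noise_sd = 1.2, dropout = zero4)
    }
  }
  models
}

#' Parameters of the synthetic tumor cohort
#'
#' Returns a validated parameter set describing the generative model:
#' subtype prevalences, subtype-conditional latent ER and GATA3
#' activities, per-gene linear readout models (baseline, regulator
#' weights, noise, subtype-specific dropout), status flip rates and
#' HER2 positivity fractions. Defaults emulate a breast-tumor cohort:
#' ~70% luminal (LumA+LumB), PGR dropout concentrated in LumB, CA12
#' driven by both ER and GATA3, a GATA3-high fraction (0.4) of the
#' molecular apocrine subtype, and ER/PR clinical status flip rates of
#' 0.054 and 0.134.
#'
#' @param n_samples Number of tumors to simulate.
#' @param seed Integer seed; the full cohort is a deterministic
#'   function of the parameter set including this seed.
#' @param subtype_prevalence Named probability vector over subtypes
#'   LumA/LumB/mApo/Basal; must sum to 1.
#' @param er_activity_means,gata3_activity_means Named per-subtype means
#'   of the latent activities (for GATA3 in mApo see
#'   `gata3_mapo_means`).
#' @param er_activity_sd,gata3_activity_sd Common activity standard
#'   deviations (> 0).
#' @param gata3_mapo_means Length-2 named vector `c(high=, low=)`:
#'   the two-point mixture of GATA3 activity inside mApo.
#' @param gata3_high_mapo_fraction Fraction of mApo tumors drawing
#'   GATA3 activity from the high component.
#' @param gene_models Named list of per-gene models, each a list with
#'   `baseline`, `er_weight`, `gata3_weight`, `noise_sd` (>= 0; zero
#'   gives a noiseless readout) and `dropout` (named per-subtype
#'   probability vector).
#' @param status_flip_prob_er,status_flip_prob_pr Probability that the
#'   clinical ER (PR) status contradicts the true class.
#' @param her2_positive_fraction Named per-subtype probability of HER2
#'   positivity.
#' @param n_decoy_genes Number of unregulated decoy genes appended to
#'   the default gene models (ignored when `gene_models` is supplied).
#' @return A list of class `cohort_params`.
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_samples = 750L,
                          seed = 1L,
                          subtype_prevalence = c(LumA = 0.45, LumB = 0.25,
                                                 mApo = 0.10, Basal = 0.20),
                          er_activity_means = c(LumA = 3.2, LumB = 2.8,
                                                mApo = 0, Basal = 0),
                          er_activity_sd = 0.6,
                          gata3_activity_means = c(LumA = 3.0, LumB = 2.8,
                                                   Basal = 0),
                          gata3_activity_sd = 0.6,
                          gata3_mapo_means = c(high = 3.0, low = 0),
                          gata3_high_mapo_fraction = 0.4,
                          gene_models = default_gene_models(n_decoy_genes),
                          status_flip_prob_er = 0.054,
                          status_flip_prob_pr = 0.134,
                          her2_positive_fraction = c(LumA = 0.08, LumB = 0.12,
                                                     mApo = 0.70, Basal = 0.10),
                          n_decoy_genes = 3L) {
  p <- list(n_samples = as.integer(n_samples), seed = as.integer(seed),
            subtype_prevalence = subtype_prevalence,
            er_activity_means = er_activity_means,
            er_activity_sd = er_activity_sd,
            gata3_activity_means = gata3_activity_means,
            gata3_activity_sd = gata3_activity_sd,
            gata3_mapo_means = gata3_mapo_means,
            gata3_high_mapo_fraction = gata3_high_mapo_fraction,
            gene_models = gene_models,
            status_flip_prob_er = status_flip_prob_er,
            status_flip_prob_pr = status_flip_prob_pr,
            her2_positive_fraction = her2_positive_fraction)
  validate_cohort_params(p)
  class(p) <- "cohort_params"
  p
}

validate_cohort_params <- function(p) {
  if (is.na(p$n_samples) || p$n_samples < 2L)
    stop_data("n_samples must be >= 2")
  subtypes <- names(p$subtype_prevalence)
  if (is.null(subtypes) || any(subtypes == ""))
    stop_data("subtype_prevalence must be a named vector")
  if (abs(sum(p$subtype_prevalence) - 1) > 1e-8)
    stop_data("subtype_prevalence must sum to 1")
  if (any(p$subtype_prevalence < 0))
    stop_data("subtype prevalences must be non-negative")
  probs <- c(p$gata3_high_mapo_fraction, p$status_flip_prob_er,
             p$status_flip_prob_pr, p$her2_positive_fraction)
  if (any(probs < 0 | probs > 1))
    stop_data("all probabilities must lie in [0,1]")
  if (p$er_activity_sd <= 0 || p$gata3_activity_sd <= 0)
    stop_data("activity standard deviations must be > 0")
  for (g in names(p$gene_models)) {
    m <- p$gene_models[[g]]
    if (m$noise_sd < 0) stop_data("noise_sd must be >= 0 for gene ", g)
    if (any(m$dropout < 0 | m$dropout > 1))
      stop_data("dropout probabilities must lie in [0,1] for gene ", g)
  }
  invisible(p)
}

# Per-gene deterministic low/high midpoint: halfway between the lowest
# and highest activity-driven state means, where states are the
# subtypes with mApo split into its GATA3-high and GATA3-low branches.
gene_midpoints <- function(p) {
  subtypes <- names(p$subtype_prevalence)
  states <- lapply(subtypes, function(s) {
    if (s == "mApo") {
      list(c(er = unname(p$er_activity_means[s]),
             g3 = unname(p$gata3_mapo_means["high"])),
           c(er = unname(p$er_activity_means[s]),
             g3 = unname(p$gata3_mapo_means["low"])))
    } else {
      list(c(er = unname(p$er_activity_means[s]),
             g3 = unname(p$gata3_activity_means[s])))
    }
  })
  states <- do.call(c, states)
  vapply(p$gene_models, function(m) {
    mus <- vapply(states, function(st)
      m$baseline + m$er_weight * st["er"] + m$gata3_weight * st["g3"], 0)
    (max(mus) + min(mus)) / 2
  }, 0)
}

flip_status <- function(true_high, prob, u) {
  obs <- ifelse(true_high, "positive", "negative")
  flip <- u < prob
  obs[flip & true_high] <- "negative"
  obs[flip & !true_high] <- "positive"
  obs
}

#' Generate a synthetic tumor cohort with full ground truth
#'
#' Draws, in a documented fixed order from a single RNG stream seeded
#' by `params$seed`: subtype labels; latent ER and GATA3 activities
#' from subtype-conditional normals (GATA3 in mApo from a two-point
#' mixture); per-gene expression `baseline + er_weight*er_activity +
#' gata3_weight*gata3_activity + N(0, noise_sd)`, replaced by
#' `baseline + N(0, noise_sd)` with the subtype's dropout probability;
#' clinical ER/PR statuses as true classes flipped independently with
#' the configured probabilities; HER2 status; and triplicate IHC scores
#' for the default marker panel. True low/high classes are the
#' indicator that a sample's activity-driven mean (post-dropout)
#' exceeds the gene's global midpoint.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   `expression` (matrix genes x samples), `clinical` (data.frame),
#'   `ihc` (data.frame), `truth` (data.frame with subtype, activities,
#'   true classes and `pgr_dropped`), `gene_midpoints` and `params`.
#'   Regenerating with identical params reproduces the cohort exactly.
#' @examples
#' co <- generate_cohort(cohort_params(n_samples = 100, seed = 42))
#' dim(co$expression)
#' table(co$truth$subtype)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  p <- params
  n <- p$n_samples
  subtypes <- names(p$subtype_prevalence)

  with_seed(p$seed, {
    sample_ids <- sprintf("S%05d", seq_len(n))
    ## 1. subtype
    subtype <- sample(subtypes, n, replace = TRUE,
                      prob = p$subtype_prevalence)
    ## 2. ER activity
    er_act <- rnorm(n, p$er_activity_means[subtype], p$er_activity_sd)
    ## 3. GATA3 activity (mApo: two-point mixture; uniforms drawn for
    ##    all samples to keep the stream layout fixed)
    u_mapo <- runif(n)
    g3_mean <- numeric(n)
    is_mapo <- subtype == "mApo"
    g3_mean[!is_mapo] <- p$gata3_activity_means[subtype[!is_mapo]]
    g3_mean[is_mapo] <- ifelse(u_mapo[is_mapo] < p$gata3_high_mapo_fraction,
                               p$gata3_mapo_means["high"],
                               p$gata3_mapo_means["low"])
    gata3_act <- rnorm(n, g3_mean, p$gata3_activity_sd)

    ## 4. genes, in gene_models order
    genes <- names(p$gene_models)
    expr <- matrix(NA_real_, length(genes), n,
                   dimnames = list(genes, sample_ids))
    drive_mean <- expr   # activity-driven mean, post-dropout
    dropped <- matrix(FALSE, length(genes), n, dimnames = dimnames(expr))
    for (g in genes) {
      m <- p$gene_models[[g]]
      mu <- m$baseline + m$er_weight * er_act + m$gata3_weight * gata3_act
      noise <- rnorm(n, 0, m$noise_sd)
      u_drop <- runif(n)
      drop <- u_drop < m$dropout[subtype]
      mu[drop] <- m$baseline
      expr[g, ] <- mu + noise
      drive_mean[g, ] <- mu
      dropped[g, ] <- drop
    }

    midpoints <- gene_midpoints(p)
    true_er <- drive_mean["ESR1", ] > midpoints["ESR1"]
    true_pr <- drive_mean["PGR", ] > midpoints["PGR"]

    ## 5. clinical statuses
    er_status <- flip_status(true_er, p$status_flip_prob_er, runif(n))
    pr_status <- flip_status(true_pr, p$status_flip_prob_pr, runif(n))
    her2_status <- ifelse(runif(n) < p$her2_positive_fraction[subtype],
                          "positive", "negative")

    clinical <- data.frame(sample_id = sample_ids,
                           er_status = er_status, pr_status = pr_status,
                           her2_status = her2_status, subtype = subtype,
                           stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = sample_ids, subtype = subtype,
                        er_activity = er_act, gata3_activity = gata3_act,
                        true_er_class = ifelse(true_er, "high", "low"),
                        true_pr_class = ifelse(true_pr, "high", "low"),
                        pgr_dropped = dropped["PGR", ],
                        stringsAsFactors = FALSE)
    cohort <- structure(list(expression = expr, clinical = clinical,
                             ihc = NULL, truth = truth,
                             gene_midpoints = midpoints, params = p),
                        class = "synthetic_cohort")
    ## 6. IHC scores for the default marker panel (restricted to genes
    ##    present in this parameterization), continuing the stream
    panel <- c(ER = "ESR1", CAXII = "CA12", GATA3 = "GATA3", FOXA1 = "FOXA1")
    panel <- panel[panel %in% rownames(expr)]
    cohort$ihc <- if (length(panel)) generate_ihc_scores(cohort, markers = panel)
      else data.frame(tumor_id = character(0), marker = character(0),
                      proportion_positive = numeric(0), intensity = numeric(0),
                      replicate_id = character(0))
    cohort
  })
}

#' IHC score calibration used by the synthetic cohort
#'
#' A monotone map from log-scale expression to a staining readout:
#' Gaussian noise (`noise_sd`) is added to expression, then a linear
#' ramp centered on the gene's low/high midpoint and spanning
#' `center - half_range` to `center + half_range` is clipped to
#' produce `proportion_positive` in \[0,1\] and `intensity =
#' 3 * proportion`. Expression at or below the ramp floor yields
#' proportion 0 and intensity 0.
#'
#' @param half_range Half-width of the linear ramp on the expression
#'   scale (log2 units).
#' @param noise_sd Standard deviation of the staining noise added to
#'   expression before the ramp.
#' @param centers Optional named per-gene ramp centers; defaults to the
#'   cohort's `gene_midpoints`.
#' @return A list of class `ihc_calibration`.
#' @export
ihc_calibration <- function(half_range = 2.5, noise_sd = 0.5,
                            centers = NULL) {
  stopifnot(half_range > 0, noise_sd >= 0)
  structure(list(half_range = half_range, noise_sd = noise_sd,
                 centers = centers), class = "ihc_calibration")
}

#' Generate replicate IHC scores from a synthetic cohort
#'
#' For each marker and replicate, applies the calibration ramp to the
#' mapped gene's expression (plus staining noise) to obtain
#' `proportion_positive` and `intensity`, emulating triplicate tissue
#' microarray cores read per tumor.
#'
#' @param cohort A `synthetic_cohort` (only `expression` and
#'   `gene_midpoints` are used).
#' @param markers Named character vector, marker name -> gene id.
#' @param calibration An [ihc_calibration()] object.
#' @param n_replicates Cores per tumor (default 3).
#' @param seed Optional seed; `NULL` (the default) draws from the
#'   ambient RNG stream, which is how [generate_cohort()] keeps the
#'   whole cohort a function of one seed.
#' @return An IHC data.frame as from [read_ihc()].
#' @export
generate_ihc_scores <- function(cohort,
                                markers = c(ER = "ESR1", CAXII = "CA12",
                                            GATA3 = "GATA3", FOXA1 = "FOXA1"),
                                calibration = ihc_calibration(),
                                n_replicates = 3L,
                                seed = NULL) {
  stopifnot(inherits(calibration, "ihc_calibration"))
  expr <- cohort$expression
  absent <- setdiff(unname(markers), rownames(expr))
  if (length(absent))
    stop_data("marker mapped to absent gene(s): ",
              paste(absent, collapse = ", "))
  centers <- calibration$centers
  if (is.null(centers)) centers <- cohort$gene_midpoints
  hr <- calibration$half_range
  n <- ncol(expr)
  with_seed(seed, {
    rows <- vector("list", length(markers) * n_replicates)
    k <- 0L
    for (mk in names(markers)) {
      gene <- markers[[mk]]
      center <- centers[[gene]]
      if (is.null(center) || is.na(center))
        stop_data("no calibration center for gene ", gene)
      for (r in seq_len(n_replicates)) {
        latent <- expr[gene, ] + rnorm(n, 0, calibration$noise_sd)
        prop <- pmin(1, pmax(0, (latent - (center - hr)) / (2 * hr)))
        k <- k + 1L
        rows[[k]] <- data.frame(
          tumor_id = colnames(expr), marker = mk,
          proportion_positive = unname(prop),
          intensity = unname(3 * prop),
          replicate_id = sprintf("r%d", r),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$params$seed))
  print(table(x$truth$subtype))
  invisible(x)
}
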