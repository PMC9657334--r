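# Over-representation of subtype labels in a selected sample set:
# one-sided exact hypergeometric tail per label, Benjamini-Hochberg
# q-values across labels.

#' Exact hypergeometric enrichment of labels in a selection
#'
#' For each label, tests over-representation of that label in the
#' selected sample set against the labeled population by the exact
#' upper hypergeometric tail `P(X >= k)` with parameters (N, K, n),
#' computed by direct summation of the probability mass over the
#' support. Depletion is visible as `fold_enrichment < 1` but is not
#' separately tested. Q-values are Benjamini-Hochberg across the
#' labels of the one selection.
#'
#' @param selection Character vector of selected sample ids (must all
#'   be present in `labels`).
#' @param labels Named character vector mapping sample id -> label for
#'   the whole population.
#' @return A data.frame of class `enrichment_result`, one row per
#'   label: `label`, `N`, `K`, `n`, `k`, `fold_enrichment`, `p_value`,
#'   `q_value`, ordered by increasing p-value.
#' @examples
#' labels <- setNames(rep(c("LumA", "LumB"), c(6, 4)), paste0("s", 1:10))
#' hypergeometric_enrichment(paste0("s", 7:10), labels)
#' @export
hypergeometric_enrichment <- function(selection, labels) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop_data("labels must be a named vector (sample id -> label)")
  selection <- unique(as.character(selection))
  absent <- setdiff(selection, names(labels))
  if (length(absent))
    stop_data("selection sample(s) absent from label map: ",
              paste(absent, collapse = ", "))
  lab <- as.character(labels)
  N <- length(lab)
  n <- length(selection)
  sel_lab <- lab[match(selection, names(labels))]
  uniq <- sort(unique(lab))
  rows <- lapply(uniq, function(L) {
    K <- sum(lab == L)
    k <- sum(sel_lab == L)
    support <- k:min(K, n)
    p <- min(1, sum(dhyper(support, K, N - K, n)))
    data.frame(label = L, N = N, K = K, n = n, k = k,
               fold_enrichment = (k / n) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity
#' enforcement, returned in input order. Delegates to
#' [stats::p.adjust()] after validating that every p lies in (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, each >= its p and <= 1.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop_data("all p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}
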