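# Tabular I/O for the three cohort inputs (expression, clinical, IHC)
# and for result tables. One dialect everywhere: tab-separated, header
# row mandatory, '.' decimal point, UTF-8, '#' comment lines allowed at
# the top of a file (used for provenance headers on outputs).

#' Read a genes-by-samples expression matrix from TSV
#'
#' The first column holds gene identifiers; every remaining column is
#' one sample of log-scale expression values. Rows containing missing
#' or non-numeric cells are either dropped (with a reported count) or
#' cause the whole file to be rejected, depending on `on_missing`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param on_missing Either `"drop_row"` (default): rows with any
#'   missing/non-finite cell are removed and the count is reported via
#'   `message()` and the `"n_dropped"` attribute; or `"reject"`: any
#'   such cell is an error naming its row and column.
#' @return A numeric matrix (genes x samples) with unique `rownames`
#'   (gene ids) and `colnames` (sample ids), all values finite, and an
#'   `n_dropped` attribute.
#' @seealso [write_expression()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2\ts3", "ESR1\t1\t2\t3", "PGR\t4\t5\t6"), f)
#' read_expression(f)
#' @export
read_expression <- function(path, on_missing = c("drop_row", "reject")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop_data("expression file needs a gene id column plus >= 1 sample column")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop_data("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop_data("duplicate sample ids: ", paste(dup_s, collapse = ", "))

  values <- matrix(NA_real_, nrow(raw), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is.finite(num)
    if (any(bad) && on_missing == "reject") {
      i <- which(bad)[1L]
      stop_data(sprintf(
        "non-numeric or missing cell at gene '%s' (row %d), sample '%s': '%s'",
        gene_ids[i], i, sample_ids[j], cell[i]))
    }
    values[, j] <- num
  }
  keep <- apply(is.finite(values), 1L, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("read_expression: dropped ", n_dropped,
            " row(s) with missing values")
  values <- values[keep, , drop = FALSE]
  message(sprintf("read_expression: %d genes x %d samples (%d row(s) dropped)",
                  nrow(values), ncol(values), n_dropped))
  structure(values, n_dropped = n_dropped)
}

#' Default mapping from clinical status tokens to ternary calls
#'
#' Token matching is case-insensitive and whitespace-trimmed.
#' @return A named list with character vectors `positive`, `negative`
#'   and `unknown`.
#' @export
default_status_tokens <- function() {
  list(positive = c("positive", "pos", "+", "1", "true"),
       negative = c("negative", "neg", "-", "0", "false"),
       unknown  = c("", "na", "n/a", "unknown", "nd", "equivocal"))
}

normalize_status <- function(x, tokens, column) {
  key <- tolower(trimws(as.character(x)))
  key[is.na(x)] <- ""
  out <- rep(NA_character_, length(key))
  out[key %in% tolower(tokens$positive)] <- "positive"
  out[key %in% tolower(tokens$negative)] <- "negative"
  out[key %in% tolower(tokens$unknown)]  <- "unknown"
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop_data("unmapped status token(s) in column '", column, "': ",
              paste(sQuote(bad), collapse = ", "))
  }
  out
}

#' Read a per-sample clinical annotation table from TSV
#'
#' Expects a `sample_id` column plus any of `er_status`, `pr_status`,
#' `her2_status` and an optional subtype column (`subtype` or
#' `subtype_label`). Status tokens are normalized to the ternary
#' positive/negative/unknown via a configurable token map; an unmapped
#' token is an error. Missing status columns are filled with
#' `"unknown"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param status_tokens Token map as produced by
#'   [default_status_tokens()].
#' @return A data.frame with columns `sample_id`, `er_status`,
#'   `pr_status`, `her2_status`, `subtype`.
#' @export
read_clinical <- function(path, status_tokens = default_status_tokens()) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!"sample_id" %in% colnames(raw))
    stop_data("clinical table must contain a 'sample_id' column")
  status_cols <- c("er_status", "pr_status", "her2_status")
  if (!any(status_cols %in% colnames(raw)))
    stop_data("clinical table must contain at least one of: ",
              paste(status_cols, collapse = ", "))
  ids <- trimws(raw$sample_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_data("duplicate sample ids: ", paste(dup, collapse = ", "))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (col in status_cols) {
    if (col %in% colnames(raw)) {
      out[[col]] <- normalize_status(raw[[col]], status_tokens, col)
    } else {
      out[[col]] <- "unknown"
    }
  }
  sub_col <- intersect(c("subtype", "subtype_label"), colnames(raw))[1]
  out$subtype <- if (!is.na(sub_col)) as.character(raw[[sub_col]]) else NA_character_
  n_unknown <- vapply(out[status_cols], function(x) sum(x == "unknown"), 0L)
  if (any(n_unknown > 0L))
    message("read_clinical: unknown statuses - ",
            paste(sprintf("%s: %d", status_cols, n_unknown), collapse = ", "))
  out
}

#' Read a per-tumor IHC score table from TSV
#'
#' Expects columns `tumor_id`, `marker`, `proportion_positive` (in
#' \[0,1\]), `intensity` (in \[0,3\]) and an optional `replicate_id`
#' (e.g. TMA core). Replicate rows are retained; aggregation is a
#' separate step ([aggregate_replicates()]).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame with the columns above (`replicate_id` filled
#'   with `"r1"` when absent).
#' @export
read_ihc <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tumor_id", "marker", "proportion_positive", "intensity")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop_data("IHC table missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    tumor_id = as.character(raw$tumor_id),
    marker = as.character(raw$marker),
    proportion_positive = as.numeric(raw$proportion_positive),
    intensity = as.numeric(raw$intensity),
    replicate_id = if ("replicate_id" %in% colnames(raw))
      as.character(raw$replicate_id) else "r1",
    stringsAsFactors = FALSE)
  bad_p <- which(!is.finite(out$proportion_positive) |
                 out$proportion_positive < 0 | out$proportion_positive > 1)
  if (length(bad_p))
    stop_data("proportion_positive outside [0,1] at row(s): ",
              paste(bad_p, collapse = ", "))
  bad_i <- which(!is.finite(out$intensity) |
                 out$intensity < 0 | out$intensity > 3)
  if (length(bad_i))
    stop_data("intensity outside [0,3] at row(s): ",
              paste(bad_i, collapse = ", "))
  key <- paste(out$tumor_id, out$marker, out$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop_data("duplicate (tumor_id, marker, replicate_id) rows: ",
              paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  out
}

#' Provenance comment line for result files
#'
#' A single `#`-prefixed line recording package version, seed and a
#' hash of the configuration used, prepended to every table the
#' pipeline writes so that outputs are self-describing.
#'
#' @param seed Integer seed used for the run (or `NA`).
#' @param config Arbitrary R object describing the run configuration.
#' @return A single character string starting with `#`.
#' @export
provenance_line <- function(seed = NA, config = NULL) {
  hash <- "none"
  if (!is.null(config)) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(deparse(config), f)
    hash <- unname(md5sum(f))
  }
  sprintf("# surromark %s; seed=%s; config_hash=%s",
          as.character(packageVersion("surromark")),
          as.character(seed), hash)
}

write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write tables in the package's TSV dialect
#'
#' `write_expression()` writes a genes-by-samples matrix with a leading
#' `gene_id` column; `write_clinical()` and `write_ihc()` write the
#' corresponding data.frames. All three accept an optional provenance
#' comment line (see [provenance_line()]) and round-trip through their
#' `read_*` counterparts.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param df Clinical or IHC data.frame.
#' @param path Output file path.
#' @param provenance Optional character line(s) starting with `#`.
#' @return The path, invisibly.
#' @export
write_expression <- function(mat, path, provenance = NULL) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, provenance)
}

#' @rdname write_expression
#' @export
write_clinical <- function(df, path, provenance = NULL)
  write_tsv(df, path, provenance)

#' @rdname write_expression
#' @export
write_ihc <- function(df, path, provenance = NULL)
  write_tsv(df, path, provenance)
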