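# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

expr_fixture <- function() {
  write_lines_tmp(c("gene_id\ts1\ts2\ts3",
                    "ESR1\t1\t2\t3",
                    "PGR\t4\t5\t6"))
}

clinical_fixture <- function() {
  write_lines_tmp(c("sample_id\ter_status\tpr_status\ther2_status\tsubtype",
                    "s1\t+\t-\tNA\tLumA",
                    "s2\tpositive\tpositive\tnegative\tLumB",
                    "s3\t0\t1\tpos\tBasal"))
}

ihc_fixture <- function() {
  write_lines_tmp(c("tumor_id\tmarker\tproportion_positive\tintensity\treplicate_id",
                    "t1\tCAXII\t0.8\t2.5\tr1",
                    "t1\tCAXII\t0.6\t2.0\tr2",
                    "t1\tER\t0.9\t3\tr1",
                    "t2\tER\t0.05\t0.5\tr1"))
}

# Brute-force scan over every observed candidate value: the smallest
# value whose reference-low coverage reaches q, and the fractions it
# implies. Independent of the package's inverse-ecdf shortcut.
brute_exclusion <- function(values, cls, q) {
  low <- values[cls == "low"]; high <- values[cls == "high"]
  for (t in sort(unique(values))) {
    if (mean(low <= t) >= q) {
      return(list(threshold = t,
                  excluded_low_fraction = mean(low <= t),
                  excluded_high_fraction = mean(high <= t)))
    }
  }
  stop("no threshold found")
}

# Two-cluster samples with planted classes, for cut-off recovery tests.
planted_scores <- function(n, frac_high = 0.6, low_mean = 1.5,
                           high_mean = 6.5, sd = 0.6) {
  truth <- ifelse(runif(n) < frac_high, "high", "low")
  mu <- ifelse(truth == "high", high_mean, low_mean)
  scores <- pmin(8, pmax(0, rnorm(n, mu, sd)))
  list(scores = scores, truth = truth)
}
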