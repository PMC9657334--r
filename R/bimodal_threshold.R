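# Low/high classification of one gene (or marker score) by a
# two-component univariate Gaussian mixture fitted by EM. The between-
# mode boundary is the point of equal posterior membership; model
# selection against a single Gaussian is by BIC, so unimodal genes
# yield no threshold.

mixture_loglik <- function(x, w, m, s) {
  # log-sum-exp over the two components, column-wise
  l1 <- log(w[1]) + dnorm(x, m[1], s[1], log = TRUE)
  l2 <- log(w[2]) + dnorm(x, m[2], s[2], log = TRUE)
  mx <- pmax(l1, l2)
  sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
}

run_em <- function(x, w, m, s, max_iter, tol) {
  n <- length(x)
  sd_floor <- max(1e-6 * sd(x), .Machine$double.eps)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step
    l1 <- log(w[1]) + dnorm(x, m[1], s[1], log = TRUE)
    l2 <- log(w[2]) + dnorm(x, m[2], s[2], log = TRUE)
    mx <- pmax(l1, l2)
    den <- exp(l1 - mx) + exp(l2 - mx)
    r1 <- exp(l1 - mx) / den
    ll <- sum(mx + log(den))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    # M step
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break   # a component died
    w <- c(n1, n2) / n
    m <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s <- c(sqrt(sum(r1 * (x - m[1])^2) / n1),
           sqrt(sum((1 - r1) * (x - m[2])^2) / n2))
    s <- pmax(s, sd_floor)
  }
  list(w = w, m = m, s = s, loglik = ll_trace[length(ll_trace)],
       trace = ll_trace, converged = converged, iter = iter)
}

# Equal-posterior boundary between the two (mean-sorted) components:
# the root of the quadratic log-density-ratio lying strictly between
# the means. With mirror-image components this is their midpoint.
posterior_boundary <- function(w, m, s) {
  A <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  B <- m[1] / s[1]^2 - m[2] / s[2]^2
  C <- m[2]^2 / (2 * s[2]^2) - m[1]^2 / (2 * s[1]^2) +
    log(w[1] * s[2] / (w[2] * s[1]))
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m[1] & roots < m[2]]
  if (length(inside)) return(inside[1])
  # degenerate weights/variances: fall back to the sd-weighted midpoint
  (m[1] * s[2] + m[2] * s[1]) / (s[1] + s[2])
}

#' Fit a two-component Gaussian mixture and locate the low/high boundary
#'
#' Fits by EM from two starts — a deterministic median split and one
#' random restart drawn from `seed` — keeping the better likelihood.
#' The low/high `threshold` is the point between the two fitted means
#' where the posterior membership probabilities are equal; it is
#' reported only when the two-component model beats a single Gaussian
#' by BIC and the EM converged, i.e. only for genuinely bimodal data.
#'
#' @param values Numeric vector; at least 20 finite values with nonzero
#'   variance are required.
#' @param max_iter Maximum EM iterations per start (default 2000; flat unimodal likelihoods converge slowly).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Integer seed for the random restart (determinism).
#' @return An object of class `mixture_fit` with fields `means`, `sds`,
#'   `weights` (component-sorted by ascending mean), `log_likelihood`,
#'   `loglik_trace`, `bic_one_component`, `bic_two_component`,
#'   `threshold` (`NA` when the data are not bimodal or the fit did not
#'   converge), `converged` and `n_iterations`.
#' @examples
#' x <- c(rnorm(200, 0), rnorm(200, 8))
#' fit <- fit_two_component_mixture(x, seed = 1)
#' fit$threshold
#' @export
fit_two_component_mixture <- function(values, max_iter = 2000L, tol = 1e-8,
                                      seed = 1L) {
  x <- values[is.finite(values)]
  if (length(x) < 20L)
    stop_data("need at least 20 finite values (got ", length(x), ")")
  if (sd(x) == 0) stop_data("values have zero variance")
  n <- length(x)

  # start 1: deterministic median split
  med <- median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) { lo <- x[x < med]; hi <- x[x >= med] }
  init1 <- list(w = c(length(lo), length(hi)) / n,
                m = c(mean(lo), mean(hi)),
                s = pmax(c(sd(lo), sd(hi)), 1e-3 * sd(x), na.rm = TRUE))
  init1$s[!is.finite(init1$s)] <- sd(x)

  fits <- with_seed(seed, {
    f1 <- run_em(x, init1$w, init1$m, init1$s, max_iter, tol)
    # start 2: random restart — means at two random data points
    m2 <- sort(sample(x, 2L))
    if (diff(m2) == 0) m2 <- m2 + c(-0.5, 0.5) * sd(x)
    f2 <- run_em(x, c(0.5, 0.5), m2, rep(sd(x), 2L), max_iter, tol)
    list(f1, f2)
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]

  ord <- order(best$m)
  w <- best$w[ord]; m <- best$m[ord]; s <- best$s[ord]

  # single-Gaussian reference (MLE variance)
  s1hat <- sqrt(mean((x - mean(x))^2))
  ll1 <- sum(dnorm(x, mean(x), s1hat, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * best$loglik + 5 * log(n)

  threshold <- NA_real_
  if (bic2 < bic1 && best$converged)
    threshold <- posterior_boundary(w, m, s)
  if (!best$converged)
    warning("EM did not converge within ", max_iter,
            " iterations; threshold withheld", call. = FALSE)

  structure(list(means = m, sds = s, weights = w,
                 log_likelihood = best$loglik,
                 loglik_trace = best$trace,
                 bic_one_component = bic1, bic_two_component = bic2,
                 threshold = threshold, converged = best$converged,
                 n_iterations = best$iter, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit (n =", x$n, ")\n")
  cat(sprintf("  means   %.4g / %.4g\n", x$means[1], x$means[2]))
  cat(sprintf("  sds     %.4g / %.4g\n", x$sds[1], x$sds[2]))
  cat(sprintf("  weights %.3f / %.3f\n", x$weights[1], x$weights[2]))
  cat(sprintf("  BIC one/two components: %.2f / %.2f\n",
              x$bic_one_component, x$bic_two_component))
  if (is.na(x$threshold)) cat("  no low/high threshold (not bimodal or not converged)\n")
  else cat(sprintf("  low/high threshold: %.4g\n", x$threshold))
  invisible(x)
}

#' Classify values as low or high against a mixture fit
#'
#' A value is `high` iff it exceeds the fitted threshold; ties at the
#' threshold are assigned `low` (conservative positivity calling; the
#' IHC side uses `>=` on its rounded cut-offs instead, see
#' [call_marker_status()]).
#'
#' @param values Numeric vector.
#' @param fit A `mixture_fit` with a present threshold.
#' @return Factor with levels `low`, `high`, same length as `values`.
#' @export
classify_low_high <- function(values, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.na(fit$threshold))
    stop_data("mixture fit has no threshold: the distribution is not ",
              "bimodal (or the fit did not converge), so no low/high ",
              "classes can be derived")
  factor(ifelse(values > fit$threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Trough-based cut-off for composite IHC scores
#'
#' Estimates a kernel density on the score range \[0,8\] (Silverman's
#' rule bandwidth by default), takes the two highest local maxima, and
#' returns the deepest local minimum between them rounded **up** to the
#' nearest score increment — e.g. a trough at 3.4 with increment 0.5
#' yields 3.5, matching positivity rules of the form "score >= cut-off".
#'
#' @param scores Numeric vector of scores in \[0,8\]; at least 20
#'   values spanning at least 2 distinct values.
#' @param bandwidth `"auto"` (Silverman's rule, [stats::bw.nrd0()]) or
#'   a positive number.
#' @param increment Representable score step for the rounding (default
#'   0.5).
#' @return The cut-off (single numeric).
#' @export
trough_cutoff_from_scores <- function(scores, bandwidth = "auto",
                                      increment = 0.5) {
  x <- scores[is.finite(scores)]
  if (length(x) < 20L) stop_data("need at least 20 scores")
  if (length(unique(x)) < 2L)
    stop_data("scores span fewer than 2 distinct values")
  if (any(x < 0 | x > 8)) stop_data("scores must lie in [0,8]")
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(x) else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  d <- density(x, bw = bw, from = 0, to = 8, n = 513L)
  y <- d$y
  i <- 2:(length(y) - 1L)
  is_max <- c(FALSE, y[i] > y[i - 1L] & y[i] >= y[i + 1L], FALSE)
  is_min <- c(FALSE, y[i] < y[i - 1L] & y[i] <= y[i + 1L], FALSE)
  # numerical wiggles in the density tails are not modes: ignore local
  # maxima below 1% of the main peak
  is_max <- is_max & y >= 0.01 * max(y)
  maxima <- which(is_max)
  if (length(maxima) < 2L)
    stop_data("density is unimodal on [0,8]: no interior trough; ",
              "use a fixed cut-off instead")
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)[1:2]])
  between <- which(is_min)
  between <- between[between > top2[1] & between < top2[2]]
  if (!length(between))
    stop_data("no local minimum between the two main modes; ",
              "use a fixed cut-off instead")
  trough_x <- d$x[between[which.min(y[between])]]
  ceiling(trough_x / increment - 1e-9) * increment
}
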