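#' Kernel density estimate of marker scores
#'
#' Gaussian-kernel density on a fixed 512-point grid spanning
#' `[min - 3h, max + 3h]`, where `h` is the bandwidth (Silverman's
#' rule-of-thumb by default). For activity scores the grid is clipped to
#' \[0,1\] and the curve renormalized so the trapezoid integral is 1.
#'
#' @param scores numeric vector, at least 10 finite values.
#' @param bandwidth optional positive kernel bandwidth.
#' @param activity logical; clip the grid to the legal \[0,1\] score range.
#' @return A `density_curve`: list with ascending `grid` and non-negative
#'   `density` integrating to 1, plus the bandwidth used.
#' @export
estimate_density <- function(scores, bandwidth = NULL, activity = FALSE) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 10) stop("need at least 10 finite scores")
  if (stats::var(scores) == 0) stop("zero variance: all scores equal")
  h <- if (is.null(bandwidth)) stats::bw.nrd0(scores) else bandwidth
  if (h <= 0) stop("bandwidth must be positive")
  from <- min(scores) - 3 * h
  to <- max(scores) + 3 * h
  if (activity) {
    from <- max(0, from)
    to <- min(1, to)
  }
  d <- stats::density(scores, bw = h, kernel = "gaussian", n = 512,
                      from = from, to = to)
  y <- d$y
  # renormalize (clipping to [0,1] can shave boundary mass)
  integral <- sum(diff(d$x) * (y[-1] + y[-length(y)]) / 2)
  y <- y / integral
  structure(list(grid = d$x, density = y, bandwidth = h),
            class = "density_curve")
}

# Indices of strict interior local maxima of y.
local_maxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

#' Locate the valley between the two main peaks of a density
#'
#' Finds the grid point of minimum density strictly between the two tallest
#' strict local maxima. When more than two maxima tie for the top heights,
#' the two most separated are used. A unimodal curve is an explicit error;
#' callers may fall back to the mixture method.
#'
#' @param curve a `density_curve` from [estimate_density()].
#' @return The valley location on the score scale.
#' @export
find_valley <- function(curve) {
  stopifnot(inherits(curve, "density_curve"))
  y <- curve$density
  peaks <- local_maxima(y)
  if (length(peaks) < 2)
    stop("density is unimodal: no valley between two peaks")
  ord <- peaks[order(y[peaks], decreasing = TRUE)]
  if (length(ord) > 2 && y[ord[2]] == y[ord[3]]) {
    tied <- ord[y[ord] >= y[ord[2]]]
    two <- range(tied)
  } else {
    two <- sort(ord[1:2])
  }
  inner <- (two[1] + 1):(two[2] - 1)
  curve$grid[inner[which.min(y[inner])]]
}

#' Pool per-cohort valley thresholds by sample size
#'
#' The pooled cut-point is the sample-size-weighted mean of the per-cohort
#' local minima: `sum(min_i * N_i) / sum(N_i)`.
#'
#' @param minima numeric vector of per-cohort valley locations.
#' @param sizes positive integer cohort sizes, same length.
#' @return A `threshold_estimate` with method `"pooled_valley"` (or
#'   `"valley"` for a single cohort).
#' @export
pool_thresholds <- function(minima, sizes) {
  if (length(minima) == 0 || length(minima) != length(sizes))
    stop("minima and sizes must be non-empty and of equal length")
  if (any(sizes <= 0)) stop("cohort sizes must be positive")
  value <- sum(minima * sizes) / sum(sizes)
  threshold_estimate(value,
                     method = if (length(minima) > 1) "pooled_valley"
                              else "valley",
                     per_cohort_minima = minima, weights = sizes)
}

#' Threshold estimate container
#'
#' @param value cut-point on the score scale.
#' @param method provenance: `"valley"`, `"pooled_valley"`,
#'   `"mixture_equal"`, `"mixture_ratio"`, `"median"`, or `"fixed"`.
#' @param per_cohort_minima,weights optional per-cohort valleys and sizes.
#' @return A `threshold_estimate` object.
#' @export
threshold_estimate <- function(value, method = "fixed",
                               per_cohort_minima = NULL, weights = NULL) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(value = value, method = method,
                 per_cohort_minima = per_cohort_minima, weights = weights),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %.6g (%s)\n", x$value, x$method))
  invisible(x)
}

#' Dichotomize samples at a threshold
#'
#' The boundary is inclusive on the high side: a score equal to the
#' threshold is classified "high". Samples with missing scores are excluded
#' with a logged count.
#'
#' @param scores named numeric vector (names = sample ids).
#' @param threshold a [threshold_estimate()] or a bare numeric cut-point.
#' @return A `sample_strata`: list with `labels` (named character vector of
#'   `"high"`/`"low"`), `threshold`, and `missing` (excluded sample ids).
#' @export
classify <- function(scores, threshold) {
  if (is.numeric(threshold)) threshold <- threshold_estimate(threshold)
  stopifnot(inherits(threshold, "threshold_estimate"))
  if (is.null(names(scores)))
    names(scores) <- sprintf("S%d", seq_along(scores))
  miss <- names(scores)[!is.finite(scores)]
  if (length(miss))
    message(length(miss), " sample(s) with missing scores excluded")
  ok <- scores[is.finite(scores)]
  labels <- ifelse(ok >= threshold$value, "high", "low")
  structure(list(labels = labels, threshold = threshold, missing = miss),
            class = "sample_strata")
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Components are initialized at the 25th/75th percentiles with the pooled
#' standard deviation and equal weights. The log-likelihood is
#' non-decreasing across iterations; convergence is declared when its
#' relative change falls below `tol`. Degenerate fits (a component's sd
#' collapsing) trigger a jittered restart, with an error after 5 restarts.
#' Components are relabeled after fitting so `mu1 < mu2`.
#'
#' @param values numeric vector, at least 20 finite values.
#' @param init optional list with `w`, `mu`, `sigma` (each length 2).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return A `mixture_fit`: `w`, `mu`, `sigma` (each length 2, mu
#'   ascending), `log_likelihood` (per-iteration trace), `n_iter`,
#'   `converged`.
#' @export
fit_mixture_1d <- function(values, init = NULL, tol = 1e-8, max_iter = 500) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20) stop("need at least 20 finite values")
  sd_floor <- 1e-6 * max(stats::sd(x), .Machine$double.eps)

  start <- if (!is.null(init)) init else {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    list(w = c(0.5, 0.5), mu = q, sigma = rep(stats::sd(x), 2))
  }

  run_em <- function(w, mu, sigma) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E-step in log space for stability
      la <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE),
                  log(w[2]) + stats::dnorm(x, mu[2], sigma[2], log = TRUE))
      mx <- pmax(la[, 1], la[, 2])
      lse <- mx + log(exp(la[, 1] - mx) + exp(la[, 2] - mx))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      r1 <- exp(la[, 1] - lse)
      # M-step
      n1 <- sum(r1); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) return(list(degenerate = TRUE))
      w <- c(n1, n2) / n
      mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
      sigma <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                      sum((1 - r1) * (x - mu[2])^2) / n2))
      if (any(sigma < sd_floor)) return(list(degenerate = TRUE))
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
        return(list(degenerate = FALSE, w = w, mu = mu, sigma = sigma,
                    ll = ll_trace, n_iter = it, converged = TRUE))
      }
      ll_old <- ll
    }
    list(degenerate = FALSE, w = w, mu = mu, sigma = sigma, ll = ll_trace,
         n_iter = max_iter, converged = FALSE)
  }

  fit <- run_em(start$w, start$mu, start$sigma)
  restarts <- 0
  while (isTRUE(fit$degenerate) && restarts < 5) {
    restarts <- restarts + 1
    jit <- stats::sd(x) * stats::runif(2, 0.1, 0.5)
    q <- stats::quantile(x, stats::runif(2, c(0.05, 0.55), c(0.45, 0.95)),
                         names = FALSE)
    fit <- run_em(c(0.5, 0.5), sort(q), rep(stats::sd(x), 2) + jit)
  }
  if (isTRUE(fit$degenerate))
    stop("degenerate mixture component after 5 restarts")
  ord <- order(fit$mu)
  structure(list(w = fit$w[ord], mu = fit$mu[ord], sigma = fit$sigma[ord],
                 log_likelihood = fit$ll, n_iter = fit$n_iter,
                 converged = fit$converged),
            class = "mixture_fit")
}

#' Threshold where the two mixture components reach a density ratio
#'
#' Returns the smallest x in `[mu1, mu2]` where
#' `w1 * dnorm(x, mu1, s1) / (w2 * dnorm(x, mu2, s2)) == ratio`, located by
#' bisection to 1e-8 after a sign-change scan. `ratio = 1` is the
#' equal-density crossing; `ratio = 0.10` implements the 10 percent rule.
#'
#' @param fit a converged [fit_mixture_1d()] result.
#' @param ratio positive target ratio of low-component to high-component
#'   weighted density.
#' @return A [threshold_estimate()] with method `"mixture_equal"` when
#'   `ratio == 1`, else `"mixture_ratio"`.
#' @export
mixture_ratio_threshold <- function(fit, ratio = 1) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  if (ratio <= 0) stop("ratio must be positive")
  g <- function(x) {
    log(fit$w[1]) + stats::dnorm(x, fit$mu[1], fit$sigma[1], log = TRUE) -
      log(fit$w[2]) - stats::dnorm(x, fit$mu[2], fit$sigma[2], log = TRUE) -
      log(ratio)
  }
  lo <- fit$mu[1]; hi <- fit$mu[2]
  grid <- seq(lo, hi, length.out = 1024)
  gv <- g(grid)
  if (any(gv == 0)) {
    x0 <- grid[which(gv == 0)[1]]
  } else {
    flips <- which(gv[-1] * gv[-length(gv)] < 0)
    if (!length(flips))
      stop("no density-ratio crossing in [mu1, mu2]; components ",
           "overlap too strongly for ratio = ", ratio)
    a <- grid[flips[1]]; b <- grid[flips[1] + 1]
    fa <- g(a)
    while (b - a > 1e-8) {
      mid <- (a + b) / 2
      fm <- g(mid)
      if (fm == 0) { a <- mid; b <- mid; break }
      if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
    }
    x0 <- (a + b) / 2
  }
  threshold_estimate(x0, method = if (ratio == 1) "mixture_equal"
                                  else "mixture_ratio")
}

#' Valley threshold pooled across cohorts
#'
#' Convenience wrapper: estimates a density per cohort, finds each valley,
#' and pools the valleys by sample size.
#'
#' @param score_list list of per-cohort marker score vectors.
#' @param activity logical; scores live on the \[0,1\] activity scale.
#' @param bandwidth optional shared kernel bandwidth.
#' @return A [threshold_estimate()].
#' @export
pooled_valley_threshold <- function(score_list, activity = TRUE,
                                    bandwidth = NULL) {
  minima <- vapply(score_list, function(s) {
    find_valley(estimate_density(s, bandwidth = bandwidth,
                                 activity = activity))
  }, numeric(1))
  pool_thresholds(minima, vapply(score_list, length, numeric(1)))
}
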