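#' Probability mass function over degrees 0..k_max
#'
#' A pmf is stored as a plain numeric vector whose i-th element is the
#' probability of degree `i - 1`; `pmf()` validates and normalizes.
#'
#' @param x nonnegative numeric vector of weights over degrees `0, 1, ...`.
#' @return Normalized numeric vector of class `pmf`.
#' @export
pmf <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || sum(x) <= 0) stop("invalid pmf weights", call. = FALSE)
  structure(x / sum(x), class = "pmf")
}

#' Truncated geometric pmf with a given mean
#'
#' The discrete analogue of the exponential law `p(k) ~ exp(-k/k0)`,
#' supported on `k_min..k_max` with ratio chosen (by root finding) so the
#' truncated mean equals `mean`.
#'
#' @param mean target mean degree, strictly between `k_min` and
#'   `(k_min + k_max)/2`.
#' @param k_min,k_max support bounds.
#' @return A [pmf()] of length `k_max + 1`.
#' @export
geometric_pmf <- function(mean, k_min = 0, k_max = 256) {
  stopifnot(k_min >= 0, k_max > k_min)
  if (mean <= k_min || mean >= (k_min + k_max) / 2)
    stop("mean must lie in (k_min, (k_min + k_max)/2)", call. = FALSE)
  ks <- k_min:k_max
  mean_of <- function(r) {
    w <- r^(ks - k_min)
    sum(ks * w) / sum(w)
  }
  r <- uniroot(function(r) mean_of(r) - mean, c(1e-12, 1 - 1e-12),
               tol = 1e-12)$root
  p <- numeric(k_max + 1)
  p[ks + 1] <- r^(ks - k_min)
  pmf(p)
}

#' Draw degrees from a pmf
#'
#' @param n number of draws.
#' @param p a [pmf()].
#' @return Integer vector of degrees.
#' @export
sample_pmf <- function(n, p) {
  sample(seq_along(p) - 1L, n, replace = TRUE, prob = as.numeric(p))
}

#' Cumulative degree distribution
#'
#' `P(k) = sum_{k' >= k} p(k')`, computed either from an empirical vector of
#' degrees (evaluated at the observed degree values) or from a [pmf()]
#' (evaluated at every degree of its support). `P` is non-increasing and
#' equals 1 at the smallest degree.
#'
#' @param x integer degree vector, or a [pmf()].
#' @return data.frame with columns `k` and `P`.
#' @export
#' @examples
#' cumulative_dist(c(1, 1, 2))  # P(1) = 1, P(2) = 1/3
cumulative_dist <- function(x) {
  if (inherits(x, "pmf")) {
    k <- seq_along(x) - 1L
    P <- rev(cumsum(rev(as.numeric(x))))
    keep <- P > 0 & k >= k[which(x > 0)[1]]   # within the support
    return(data.frame(k = k[keep], P = P[keep]))
  }
  if (length(x) == 0) stop("empty degree vector", call. = FALSE)
  ks <- sort(unique(as.integer(x)))
  P <- vapply(ks, function(k) mean(x >= k), numeric(1))
  data.frame(k = ks, P = P)
}

#' Fit an exponential or power-law form to a cumulative distribution
#'
#' Least squares on the log-transformed cumulative values: for the
#' exponential family `log P(k)` is regressed on `k` (scale
#' `k0 = -1/slope`), for the power law `log P(k)` on `log k` (exponent
#' `-slope`; the point `k = 0` is excluded). The goodness is the residual
#' sum of squares on the log scale, comparable across families on the same
#' input. `tail_cut` optionally drops points with `k` above it, the usual
#' guard against the finite-size tail.
#'
#' @param cum data.frame (k, P) as from [cumulative_dist()].
#' @param family `"exponential"` or `"power_law"`.
#' @param tail_cut optional maximum k retained in the fit.
#' @return Object of class `fit_result`: list with `family`, `k0` or
#'   `exponent`, `intercept`, `goodness` (RSS), and `fitted` samples.
#' @export
fit_cumulative <- function(cum, family = c("exponential", "power_law"),
                           tail_cut = NULL) {
  family <- match.arg(family)
  d <- cum[cum$P > 0, , drop = FALSE]
  if (!is.null(tail_cut)) d <- d[d$k <= tail_cut, , drop = FALSE]
  if (family == "power_law") d <- d[d$k > 0, , drop = FALSE]
  if (length(unique(d$k)) < 3)
    stop("need at least 3 distinct degree values to fit", call. = FALSE)
  y <- log(d$P)
  xv <- if (family == "exponential") d$k else log(d$k)
  fit <- stats::lm.fit(cbind(1, xv), y)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  res <- structure(list(family = family, intercept = unname(a),
                        goodness = sum(fit$residuals^2),
                        fitted = data.frame(k = d$k,
                                            P = exp(a + b * xv))),
                   class = "fit_result")
  if (family == "exponential") res$k0 <- unname(-1 / b)
  else res$exponent <- unname(-b)
  res
}

#' @export
print.fit_result <- function(x, ...) {
  par <- if (x$family == "exponential") paste0("k0 = ", signif(x$k0, 4))
         else paste0("exponent = ", signif(x$exponent, 4))
  cat(x$family, "fit:", par, "| RSS(log) =", signif(x$goodness, 4), "\n")
  invisible(x)
}

#' Compare exponential and power-law fits
#'
#' @inheritParams fit_cumulative
#' @return List with both [fit_cumulative()] results and `better`, the
#'   family with the smaller residual sum of squares.
#' @export
compare_fits <- function(cum, tail_cut = NULL) {
  fe <- fit_cumulative(cum, "exponential", tail_cut)
  fp <- fit_cumulative(cum, "power_law", tail_cut)
  list(exponential = fe, power_law = fp,
       better = if (fe$goodness <= fp$goodness) "exponential" else
         "power_law")
}

#' Projected degree pmf by generating functions
#'
#' For an uncorrelated bipartite complex-protein network, the degree of a
#' protein in the one-mode protein projection is (ignoring the rare repeated
#' partners) the sum, over its memberships, of the sizes-minus-one of the
#' complexes it joins, where complex sizes at the end of a random membership
#' follow the size-biased distribution. In generating-function terms the
#' projected distribution is the composition `G_protein(G_excess(x))`, with
#' `G_excess` generating the size-biased excess complex size. Here the
#' composition is evaluated by repeated convolution truncated at `k_max`,
#' then renormalized.
#'
#' @param p_protein [pmf()] of protein membership degrees.
#' @param p_complex [pmf()] of complex sizes.
#' @param k_max truncation degree for the result.
#' @return A [pmf()] of the projected protein degree, length `k_max + 1`.
#'   A warning reports the retained mass if truncation loses more than
#'   1e-6 of it.
#' @export
project_degree_pmf <- function(p_protein, p_complex, k_max = 512) {
  p_protein <- pmf(p_protein); p_complex <- pmf(p_complex)
  sizes <- seq_along(p_complex) - 1L
  wb <- sizes * as.numeric(p_complex)
  if (sum(wb) <= 0) stop("complex size pmf has mean 0", call. = FALSE)
  # size-biased excess: q(e) prop. to (e+1) * p_complex(e+1), e = size - 1
  q <- wb[-1] / sum(wb)
  limit <- k_max + 1L
  res <- numeric(limit)
  cur <- c(1, numeric(limit - 1))            # delta at 0 = zero memberships
  res[1] <- res[1] + p_protein[1]
  dmax <- length(p_protein) - 1L
  if (dmax >= 1) {
    for (d in seq_len(dmax)) {
      cur <- convolve(cur, rev(q), type = "open")[seq_len(limit)]
      cur[cur < 0] <- 0
      if (d + 1L <= length(p_protein))
        res <- res + p_protein[d + 1L] * cur
    }
  }
  kept <- sum(res)
  if (kept < 1 - 1e-6)
    warning(sprintf(
      "k_max = %d truncates the projected pmf: retained mass %.8f", k_max,
      kept), call. = FALSE)
  pmf(res)
}

#' Total variation distance between two pmfs
#'
#' @param p,q numeric probability vectors (padded with zeros to a common
#'   length).
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(as.numeric(p), numeric(n - length(p)))
  q <- c(as.numeric(q), numeric(n - length(q)))
  0.5 * sum(abs(p - q))
}

#' Log-linearity of a pmf's upper tail
#'
#' Fits `log p(k)` against `k` over the upper tail (degrees above the given
#' mass quantile, with `p(k)` above a floor) and returns the R-squared of the
#' straight-line fit -- the package's check that a distribution's tail is
#' exponential-like.
#'
#' @param p a [pmf()].
#' @param lower_q mass quantile where the tail starts.
#' @param floor smallest probability included.
#' @return R-squared of the linear fit of `log p(k)` on `k`.
#' @export
tail_loglinearity <- function(p, lower_q = 0.5, floor = 1e-12) {
  p <- as.numeric(p)
  k <- seq_along(p) - 1L
  cdf <- cumsum(p)
  keep <- cdf >= lower_q & p > floor
  if (sum(keep) < 3) stop("tail too short to assess", call. = FALSE)
  y <- log(p[keep]); x <- k[keep]
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}
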