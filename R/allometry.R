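# Power-law allometry: nonlinear quantile envelopes by pinball loss,
# through-origin proportional fit, and the LPJ-family theoretical curves.

#' Nonlinear power-law quantile regression
#'
#' Fits the conditional quantile curve `y = a * x^b` at level `tau` by
#' minimizing the pinball (check) loss
#' `sum(rho_tau(y - a * x^b))`, `rho_tau(u) = u * (tau - (u < 0))`.
#' For fixed `b` the inner problem in `a` is solved exactly: with
#' `z = x^b`, the minimizer is the `tau`-weighted quantile of `y/z` with
#' weights `z` (a sort, no iteration — stable at extreme `tau`).  The
#' exponent is found by an 80-point grid over `bracket` refined by
#' golden-section search.
#'
#' @param x,y Positive numeric vectors (n >= 10).
#' @param tau Quantile level in (0, 1).
#' @param bracket Exponent search interval (default `c(0.05, 8)`, which
#'   covers allometric exponents with margin).
#' @return An object of class `power_law_fit`: list with `a`, `b`, `tau`,
#'   `loss`, `n`, `coverage` (fraction of points strictly below the
#'   curve).
#' @export
fit_power_quantile <- function(x, y, tau, bracket = c(0.05, 8)) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 10L) stopf("need n >= 10, got %d", n)
  if (any(x <= 0) || any(y <= 0)) stopf("x and y must be strictly positive")
  if (tau <= 0 || tau >= 1) stopf("tau must be in (0, 1)")
  if (length(unique(x)) < 2L) stopf("degenerate x: a single distinct value")
  lx <- log(x)
  inner <- function(b) {
    z <- exp(b * lx)
    t <- y / z
    o <- order(t)
    cw <- cumsum(z[o])
    a <- t[o][which(cw >= tau * cw[n])[1]]
    u <- y - a * z
    list(a = a, loss = sum(u * (tau - (u < 0))))
  }
  grid <- seq(bracket[1], bracket[2], length.out = 80L)
  losses <- vapply(grid, function(b) inner(b)$loss, 0)
  i <- which.min(losses)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement of the exponent
  gr <- (sqrt(5) - 1) / 2
  b1 <- hi - gr * (hi - lo); b2 <- lo + gr * (hi - lo)
  f1 <- inner(b1)$loss; f2 <- inner(b2)$loss
  while (hi - lo > 1e-7) {
    if (f1 <= f2) {
      hi <- b2; b2 <- b1; f2 <- f1
      b1 <- hi - gr * (hi - lo); f1 <- inner(b1)$loss
    } else {
      lo <- b1; b1 <- b2; f1 <- f2
      b2 <- lo + gr * (hi - lo); f2 <- inner(b2)$loss
    }
  }
  b <- (lo + hi) / 2
  fit <- inner(b)
  structure(list(a = fit$a, b = b, tau = tau, loss = fit$loss, n = n,
                 coverage = mean(y < fit$a * exp(b * lx))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  lab <- if (identical(x$tau, "ols-origin")) "through-origin"
         else sprintf("%g%% quantile", 100 * x$tau)
  cat(sprintf("<power_law_fit> %s: y = %.4g * x^%.4g (n = %d, loss = %.4g)\n",
              lab, x$a, x$b, x$n, x$loss))
  invisible(x)
}

#' Through-origin proportional fit
#'
#' Least-squares line through the origin, `y = b0 * x`: the slope is
#' `sum(x*y) / sum(x^2)` with a two-sided p-value from the t statistic of
#' the no-intercept regression (n - 1 df).
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return A `power_law_fit` with exponent fixed at 1, `tau =
#'   "ols-origin"`, plus `p_value` and `se`.
#' @export
fit_proportional <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stopf("need n >= 3, got %d", n)
  sxx <- sum(x^2)
  if (sxx == 0) stopf("sum(x^2) is zero; slope undefined")
  b0 <- sum(x * y) / sxx
  res <- y - b0 * x
  se <- sqrt(sum(res^2) / (n - 1) / sxx)
  tstat <- b0 / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  structure(list(a = b0, b = 1, tau = "ols-origin", loss = sum(res^2),
                 n = n, coverage = mean(y < b0 * x), se = se, p_value = p),
            class = "power_law_fit")
}

#' Combine the LPJ allometric equations into a CA-Height curve
#'
#' The DGVM allometric module relates height and canopy area to stem
#' diameter: `Height = k_h * DBH^p_h` and `CA = k_ca * DBH^p_ca` (LPJ
#' constants 40, 0.5, 100, 1.6, diameter in meters).  Eliminating DBH
#' gives the theoretical crown--height law `CA = k_c * Height^p_c` with
#' `p_c = p_ca / p_h` and `k_c = k_ca * k_h^(-p_c)`.
#'
#' @param k_h,p_h Height-DBH coefficient and exponent.
#' @param k_ca,p_ca CA-DBH coefficient and exponent.
#' @return Named numeric vector `c(k_c, p_c)`.
#' @export
combine_theoretical <- function(k_h = 40, p_h = 0.5, k_ca = 100, p_ca = 1.6) {
  if (any(c(k_h, k_ca) <= 0)) stopf("coefficients must be > 0")
  if (p_h == 0) stopf("p_h must be nonzero")
  p_c <- p_ca / p_h
  c(k_c = k_ca * k_h^(-p_c), p_c = p_c)
}

#' LPJ theoretical allometry constants
#'
#' @return List with the Height-DBH and CA-DBH power laws used in LPJ and
#'   descendants, and their combined CA-Height curve.
#' @export
lpj_allometry <- function() {
  comb <- combine_theoretical(40, 0.5, 100, 1.6)
  list(height_dbh = c(k = 40, p = 0.5),
       ca_dbh = c(k = 100, p = 1.6),
       ca_height = c(k = unname(comb["k_c"]), p = unname(comb["p_c"])))
}

#' Compare a fitted envelope with a theoretical power law
#'
#' Evaluates both curves on a grid, reports pointwise differences
#' (fitted minus theoretical), and locates the crossing point, if any, by
#' bisection on the log-difference.
#'
#' @param fit A `power_law_fit` (or list with `a`, `b`).
#' @param theory Numeric `c(k, p)` of the theoretical curve.
#' @param x_grid Positive evaluation grid.
#' @return A data frame `x`, `fitted`, `theoretical`, `difference`, with
#'   attribute `crossing` (x of equal curves, or `NA`).
#' @export
compare_envelopes <- function(fit, theory, x_grid) {
  if (any(x_grid <= 0)) stopf("x_grid must be positive")
  a <- fit$a; b <- fit$b
  k <- theory[[1]]; p <- theory[[2]]
  fitted <- a * x_grid^b
  theoretical <- k * x_grid^p
  ld <- function(x) (log(a) + b * log(x)) - (log(k) + p * log(x))
  crossing <- NA_real_
  if (abs(b - p) > 1e-12) {
    xc <- exp((log(k) - log(a)) / (b - p))
    if (xc >= min(x_grid) && xc <= max(x_grid)) {
      u <- stats::uniroot(ld, range(x_grid), tol = 1e-12)
      crossing <- u$root
    }
  }
  structure(data.frame(x = x_grid, fitted = fitted,
                       theoretical = theoretical,
                       difference = fitted - theoretical),
            crossing = crossing)
}
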