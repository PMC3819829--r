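#' Simple linear regression (one predictor)
#'
#' Ordinary least squares of `y` on an intercept and `x`, with the
#' residual-variance slope standard error on n - 2 degrees of freedom.
#' Pairs with a missing value in either variable are dropped.
#'
#' @param x numeric predictor (non-constant after missing removal).
#' @param y numeric response.
#' @return object of class `simple_fit`: list with `intercept`, `slope`,
#'   `slope_se`, `t`, `p_value`, `n_used`.
#' @export
#' @examples
#' f <- simple_regression(c(0, 1, 2, 1), c(0.1, 1.2, 1.9, 1.1))
#' f$slope
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- !(is.na(x) | is.na(y))
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  xm <- mean(x); ym <- mean(y)
  xc <- x - xm
  sxx <- sum(xc * xc)
  if (sxx == 0) stop("'x' is constant: zero variance, slope undefined")
  sxy <- sum(xc * (y - ym))
  slope <- sxy / sxx
  rss <- sum((y - ym - slope * xc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se > 0) slope / se else ifelse(slope == 0, 0, sign(slope) * Inf)
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(intercept = ym - slope * xm, slope = slope, slope_se = se,
                 t = tval, p_value = p, n_used = n),
            class = "simple_fit")
}

#' Two-predictor linear regression (mediator plus exposure)
#'
#' Ordinary least squares of `y` on an intercept, `m` and `x`, with
#' coefficient standard errors on n - 3 degrees of freedom. This is the
#' final Baron-Kenny step: the slope on `m` is the mediator-to-outcome
#' path adjusted for the exposure, the slope on `x` the direct effect.
#'
#' @param x numeric exposure (e.g. gene dose).
#' @param m numeric mediator (e.g. transcript level).
#' @param y numeric outcome.
#' @return object of class `two_predictor_fit`: list with `intercept`,
#'   `slope_m`, `slope_m_se`, `slope_x`, `slope_x_se`, `n_used`.
#' @export
two_predictor_regression <- function(x, m, y) {
  if (length(x) != length(m) || length(x) != length(y))
    stop("'x', 'm' and 'y' must have equal length")
  ok <- !(is.na(x) | is.na(m) | is.na(y))
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 complete triples")
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc * xc); smm <- sum(mc * mc); sxm <- sum(xc * mc)
  det <- sxx * smm - sxm * sxm
  if (sxx == 0 || smm == 0 || det <= 0 ||
      det < 1e-12 * sxx * smm)
    stop("design matrix rank-deficient: exposure and mediator are collinear")
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  b_m <- (sxx * smy - sxm * sxy) / det
  b_x <- (smm * sxy - sxm * smy) / det
  rss <- sum(yc * yc) - b_m * smy - b_x * sxy
  rss <- max(rss, 0)
  sigma2 <- rss / (n - 3)
  structure(list(intercept = mean(y) - b_m * mean(m) - b_x * mean(x),
                 slope_m = b_m, slope_m_se = sqrt(sigma2 * sxx / det),
                 slope_x = b_x, slope_x_se = sqrt(sigma2 * smm / det),
                 n_used = n),
            class = "two_predictor_fit")
}

#' Sobel test of the indirect (mediated) effect
#'
#' The indirect effect is the product of the exposure-to-mediator slope
#' (`b2`) and the mediator-to-outcome slope adjusted for the exposure
#' (`b4`). Its delta-method standard error is
#' `sqrt(b2^2 * se4^2 + b4^2 * se2^2)`; the statistic z = indirect / se
#' is referred to the standard normal, two-sided.
#'
#' @param b2 exposure-to-mediator slope.
#' @param se2 its standard error.
#' @param b4 adjusted mediator-to-outcome slope.
#' @param se4 its standard error.
#' @return object of class `sobel_result`: list with `indirect`, `se`,
#'   `z`, `p_analytic`.
#' @export
#' @examples
#' sobel_statistic(2, 0.5, 3, 1)  # se 2.5, z 2.4
sobel_statistic <- function(b2, se2, b4, se4) {
  if (anyNA(c(b2, se2, b4, se4))) stop("Sobel inputs must be non-missing")
  if (se2 < 0 || se4 < 0) stop("standard errors must be >= 0")
  indirect <- b2 * b4
  se <- sqrt(b2^2 * se4^2 + b4^2 * se2^2)
  if (se > 0) {
    z <- indirect / se
    p <- 2 * pnorm(-abs(z))
  } else if (indirect == 0) {
    z <- 0; p <- 1
  } else {
    z <- sign(indirect) * Inf; p <- 0
  }
  structure(list(indirect = indirect, se = se, z = z, p_analytic = p),
            class = "sobel_result")
}

#' Mediation test for a single trio
#'
#' Convenience wrapper running the exposure-to-mediator regression, the
#' two-predictor outcome regression and the Sobel test on one
#' (x, m, y) triple, optionally adding a permutation p-value for the
#' coefficient product.
#'
#' @inheritParams two_predictor_regression
#' @param B number of permutations (0 = analytic only).
#' @param seed seed for the permutation null.
#' @return list with `fit_xm` ([simple_regression()] of m on x),
#'   `fit_y` ([two_predictor_regression()]), `sobel`
#'   ([sobel_statistic()]), `beta5` (direct effect) and `p_permutation`
#'   (NA when `B = 0`).
#' @export
mediation_test <- function(x, m, y, B = 0L, seed = 1L) {
  fit_xm <- simple_regression(x, m)
  fit_y <- two_predictor_regression(x, m, y)
  sob <- sobel_statistic(fit_xm$slope, fit_xm$slope_se,
                         fit_y$slope_m, fit_y$slope_m_se)
  p_perm <- NA_real_
  if (B > 0L) {
    nul <- permutation_null(x, m, y, B = B, seed = seed)
    p_perm <- permutation_pvalue(sob$indirect, nul)
  }
  list(fit_xm = fit_xm, fit_y = fit_y, sobel = sob,
       beta5 = fit_y$slope_x, p_permutation = p_perm)
}
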