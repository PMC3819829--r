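#' Permutation null of the coefficient product
#'
#' Builds the null distribution of the product of permuted regression
#' coefficients. Per iteration, two independent permutations are drawn:
#' the outcome `y` is permuted and regressed on the unpermuted exposure
#' and mediator, giving the permuted adjusted mediator slope; the
#' mediator `m` is permuted and regressed on the unpermuted exposure,
#' giving the permuted exposure-to-mediator slope. The stored value is
#' their product. Deterministic for a fixed seed.
#'
#' Samples with a missing value in any of the three variables are
#' excluded before permuting, matching the complete-case policy of the
#' observed-data fits.
#'
#' @inheritParams two_predictor_regression
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @return object of class `permutation_null`: list with `products`
#'   (length-B numeric), `B`, `seed`.
#' @export
permutation_null <- function(x, m, y, B, seed = 1L) {
  if (B < 1L) stop("'B' must be >= 1")
  ok <- !(is.na(x) | is.na(m) | is.na(y))
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 complete triples")
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc * xc); smm <- sum(mc * mc); sxm <- sum(xc * mc)
  det <- sxx * smm - sxm * sxm
  if (sxx == 0 || det <= 0) stop("degenerate design for permutation")
  products <- numeric(B)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    yp <- yc[sample.int(n)]
    b4p <- (sxx * sum(mc * yp) - sxm * sum(xc * yp)) / det
    mp <- mc[sample.int(n)]
    b2p <- sum(xc * mp) / sxx
    products[b] <- b2p * b4p
  }
  structure(list(products = products, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' Permutation p-value of an observed coefficient product
#'
#' Two-sided add-one rule: p = (1 + #\{|null product| >= |observed|\}) /
#' (B + 1), so the smallest attainable p is 1/(B + 1) and p is never 0.
#'
#' @param observed the observed indirect-effect estimate (b2 * b4).
#' @param null a [permutation_null()] object.
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "permutation_null"))
  if (!length(null$products)) stop("empty permutation null")
  (1 + sum(abs(null$products) >= abs(observed))) / (null$B + 1)
}
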