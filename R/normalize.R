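#' Residualize a trait on age and sex
#'
#' Ordinary least-squares regression of `y` on an intercept, age and sex;
#' the residuals are returned in the original sample order, with NA where
#' the response or a covariate was missing (those samples are dropped from
#' the fit and logged). If a covariate is constant (or collinear) in the
#' complete cases it is dropped from the design with a warning rather
#' than failing.
#'
#' @param y numeric response vector.
#' @param age numeric covariate.
#' @param sex 0/1 (or any two-level) covariate.
#' @return numeric vector of residuals, same length as `y`, with
#'   attribute `covariates_removed` naming the columns regressed out.
#' @export
covariate_adjust <- function(y, age, sex) {
  n <- length(y)
  if (length(age) != n || length(sex) != n)
    stop("'y', 'age' and 'sex' must have equal length")
  sex <- recode_sex(sex)
  keep <- !(is.na(y) | is.na(age) | is.na(sex))
  if (sum(keep) < 4L)
    stop("need at least 4 complete cases for covariate adjustment")
  if (any(!keep))
    .log_msg("covariate adjustment dropped %d incomplete sample(s)", sum(!keep))
  X <- cbind(intercept = 1, age = age[keep], sex = sex[keep])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    warning("collinear covariate(s) dropped: ", paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }
  fit <- lm.fit(X, y[keep])
  out <- rep(NA_real_, n)
  out[keep] <- fit$residuals
  attr(out, "covariates_removed") <- setdiff(colnames(X), "intercept")
  out
}

#' Rank-based inverse-normal transformation
#'
#' Maps the value with rank r among n non-missing observations to the
#' standard-normal quantile at (r - offset)/(n - 2*offset + 1), with the
#' default half-sample offset giving (r - 0.5)/n; ties receive the
#' average rank and missing values stay missing. This is the rank-based
#' normalization routinely applied to enzyme-activity and expression
#' traits before linear modelling.
#'
#' @param v numeric vector (>= 2 non-missing, non-constant values).
#' @param offset "half" for (r - 0.5)/n (default) or "blom" for
#'   (r - 3/8)/(n + 1/4).
#' @return numeric vector of normal scores, same length and order as `v`.
#' @export
#' @examples
#' inverse_normal_transform(c(10, 20, 30))
inverse_normal_transform <- function(v, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values")
  x <- v[ok]
  if (diff(range(x)) == 0)
    stop("constant vector: ranks carry no information to normalize")
  r <- rank(x, ties.method = "average")
  q <- switch(offset,
              half = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(v))
  out[ok] <- qnorm(q)
  out
}

#' Adjust and normalize a phenotype vector
#'
#' Applies [covariate_adjust()] then [inverse_normal_transform()], the
#' preprocessing order used for the liver-cohort enzyme activities
#' (corrected with age and gender, then rank-normalized).
#'
#' @param p a [phenotype_table()].
#' @param offset passed to [inverse_normal_transform()].
#' @return numeric vector of normalized trait values named by sample id.
#' @export
preprocess_phenotype <- function(p, offset = "half") {
  stopifnot(inherits(p, "phenotype_table"))
  adj <- covariate_adjust(p$trait, p$age, p$sex)
  out <- inverse_normal_transform(adj, offset = offset)
  names(out) <- p$sample_id
  out
}

#' Adjust and normalize every probe of an expression matrix
#'
#' Per probe: residualize on age and sex, then inverse-normal transform.
#'
#' @param e an [expression_matrix()].
#' @param p a [phenotype_table()] aligned to `e` (same samples, same order).
#' @param offset passed to [inverse_normal_transform()].
#' @return an [expression_matrix()] of normalized values.
#' @export
preprocess_expression <- function(e, p, offset = "half") {
  stopifnot(inherits(e, "expression_matrix"), inherits(p, "phenotype_table"))
  if (!identical(rownames(e$values), p$sample_id))
    stop("expression and phenotype samples are not aligned; run align_samples() first")
  vals <- apply(e$values, 2, function(col) {
    inverse_normal_transform(covariate_adjust(col, p$age, p$sex),
                             offset = offset)
  })
  rownames(vals) <- rownames(e$values)
  expression_matrix(vals, e$probe_chrom, e$probe_pos)
}
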