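#' Rank-based inverse normal transformation
#'
#' Maps a trait to i-normalized quantile scores: each value is replaced by
#' the standard-normal quantile of its (offset) fractional rank, giving a
#' distribution symmetric about its mean and median. Ties receive midranks.
#' Missing values stay missing and do not consume ranks.
#'
#' @param x numeric vector (names, if any, are preserved).
#' @param offset rank offset convention: `"mid"` uses (r - 1/2)/n, `"blom"`
#'   uses (r - 3/8)/(n + 1/4).
#' @return numeric vector of i-normalized scores.
#' @export
inverse_normal_transform <- function(x, offset = c("mid", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  if (length(unique(x[ok])) == 1L)
    stop("all values identical; inverse normal transform is degenerate")
  r <- rank(x[ok], ties.method = "average")
  p <- if (offset == "mid") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
  out <- x
  out[ok] <- stats::qnorm(p)
  out
}

#' Residualize a trait on covariates by ordinary least squares
#'
#' Returns the residuals of `x` regressed on an intercept plus the given
#' covariate columns (e.g. sex, age, optionally age x sex). Zero-variance
#' covariates are dropped; a rank-deficient design after dropping is an
#' error. Rows with a missing value in `x` or any covariate come back `NA`.
#'
#' @param x numeric vector.
#' @param covariates data.frame of covariate columns aligned with `x`
#'   (factors/characters are expanded via model.matrix).
#' @return numeric vector of residuals (same length/names as `x`).
#' @export
residualize <- function(x, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(x))
    stop("covariates must have one row per value of x")
  keep <- vapply(covariates, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) > 1L
  }, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  out <- rep(NA_real_, length(x))
  names(out) <- names(x)
  if (ncol(covariates) == 0L) {
    ok <- !is.na(x)
    out[ok] <- x[ok] - mean(x[ok])
    return(out)
  }
  dat <- cbind(.y = x, covariates)
  cc <- stats::complete.cases(dat)
  X <- stats::model.matrix(~ ., data = covariates[cc, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("collinear (rank-deficient) covariate design")
  fit <- stats::lm.fit(X, x[cc])
  out[cc] <- fit$residuals
  out
}

#' Telomere attrition between two time points
#'
#' Computes delta-LTL as baseline minus follow-up, so that telomere
#' shortening is positive. Inputs must be named vectors (ids as names) on a
#' common scale: either i-normalized LTL (`mode = "raw_inormal"`) or sex- and
#' age-adjusted residuals of i-normalized LTL (`mode = "adjusted_residual"`);
#' the mode is recorded on the result, the arithmetic is the same. Animals
#' missing either time point are dropped (count reported via attribute
#' `n_dropped`).
#'
#' @param t0 named numeric vector, baseline values.
#' @param t2 named numeric vector, follow-up values.
#' @param mode scale the inputs are on.
#' @return named numeric vector of differences over the id intersection.
#' @export
delta_ltl <- function(t0, t2, mode = c("raw_inormal", "adjusted_residual")) {
  mode <- match.arg(mode)
  if (is.null(names(t0)) || is.null(names(t2)))
    stop("t0 and t2 must be named by individual id")
  ids <- intersect(names(t0)[!is.na(t0)], names(t2)[!is.na(t2)])
  if (!length(ids)) stop("no individuals present at both time points")
  d <- t0[ids] - t2[ids]
  attr(d, "mode") <- mode
  attr(d, "n_dropped") <- length(union(names(t0), names(t2))) - length(ids)
  d
}
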