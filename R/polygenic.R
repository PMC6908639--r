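#' Maximum-likelihood polygenic variance decomposition
#'
#' Fits the quantitative-genetic mixed model
#' `y = X beta + g + e`, with `g ~ N(0, sigma2_g * 2 Phi)` (additive genetic
#' values, `Phi` the pedigree kinship matrix) and `e ~ N(0, sigma2_e * I)`,
#' by full maximum likelihood. The phenotypic covariance among relatives is
#' thereby decomposed into genetic and environmental components, and
#' heritability is `h2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' Implementation: the relationship matrix `K = 2 Phi` is eigendecomposed
#' once (`K = U D U'`), `y` and `X` are rotated into the eigenbasis where the
#' covariance is diagonal, `beta` and the total variance are profiled out
#' analytically (GLS and the mean weighted residual sum of squares), and the
#' scalar `h2` is maximized on [0, 1] by bounded search (tolerance 1e-8).
#' A likelihood flat in `h2` (e.g. all individuals unrelated, `K = I`) is
#' resolved to `h2 = 0` with an identifiability flag; estimates on the
#' boundary of the parameter space are returned as-is with a boundary flag.
#' Standard errors come from the observed information (numerical Hessian of
#' the joint log-likelihood in `(beta, sigma2_g, sigma2_e)`), with the
#' heritability SE by the delta method.
#'
#' @param data data.frame with an `id` column plus trait and covariate
#'   columns; one row per individual (subset to one time point first).
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (may include
#'   interaction terms like `"age:sex"`); the model always has an intercept.
#' @param kinship a `kinship_matrix` covering the phenotyped ids.
#' @param se compute standard errors (skippable for speed in simulations).
#' @return Object of class `polygenic_fit`: list with `beta` (data.frame of
#'   estimates and SEs), `sigma2_g`, `sigma2_e`, `h2`, `h2_se`, `loglik`,
#'   `n`, `flags`, and `p_values` (filled by the LRT helpers).
#' @seealso [lrt_covariate()], [lrt_heritability()], [covariate_association()]
#' @export
fit_polygenic <- function(data, trait, covariates = character(),
                          kinship, se = TRUE) {
  prep <- pg_prepare(data, trait, covariates, kinship)
  fit <- pg_fit_core(prep$yt, prep$Xt, prep$d)
  beta_se <- rep(NA_real_, length(fit$beta))
  h2_se <- NA_real_
  if (se) {
    ses <- pg_observed_se(fit, prep)
    beta_se <- ses$beta_se
    h2_se <- ses$h2_se
  }
  structure(list(
    beta = data.frame(term = colnames(prep$Xt), estimate = fit$beta,
                      se = beta_se, row.names = NULL),
    sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
    h2 = fit$h2, h2_se = h2_se, loglik = fit$loglik,
    n = length(prep$yt), ids = prep$ids, flags = fit$flags,
    trait = trait, covariates = covariates,
    p_values = list(), .prep = prep), class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("Polygenic ML fit: %s ~ %s  (n = %d)\n", x$trait,
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "1", x$n))
  print(transform(x$beta, estimate = signif(estimate, 4), se = signif(se, 3)))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f (SE %.3f)\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$h2_se))
  cat(sprintf("  loglik = %.4f%s\n", x$loglik,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# ---- internals ------------------------------------------------------------

# Align rows with the kinship matrix, listwise-delete missing values, build
# the design matrix, rotate into the eigenbasis of K = 2*Phi.
pg_prepare <- function(data, trait, covariates, kinship) {
  if (!"id" %in% names(data)) stop("data needs an `id` column")
  vars <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  miss <- setdiff(c(trait, vars), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  keep <- data$id %in% kinship$ids &
    stats::complete.cases(data[, c(trait, vars), drop = FALSE])
  d0 <- data[keep, , drop = FALSE]
  if (anyDuplicated(d0$id))
    stop("multiple rows per id; subset to a single time point first")
  if (nrow(d0) < 10) stop("need at least 10 phenotyped individuals")
  y <- d0[[trait]]
  if (stats::var(y) == 0) stop("trait is constant")
  form <- if (length(covariates))
    stats::as.formula(paste("~", paste(covariates, collapse = "+")))
  else ~1
  X <- stats::model.matrix(form, data = d0)
  K <- relationship_matrix(kinship, d0$id)
  eig <- eigen(K, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-8 * max(abs(d)))
    stop("2*Phi is not positive semi-definite")
  d <- pmax(d, 0)
  Ut <- t(eig$vectors)
  Xt <- Ut %*% X
  colnames(Xt) <- colnames(X)
  if (qr(Xt)$rank < ncol(Xt)) stop("collinear (rank-deficient) design")
  list(yt = drop(Ut %*% y), Xt = Xt, d = d, ids = d0$id,
       var_y = stats::var(y), data = d0)
}

# Profile log-likelihood at a given h2 (beta, total variance profiled out).
pg_profile <- function(h2, yt, Xt, d) {
  n <- length(yt)
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(list(ll = -Inf))
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xt / sw, yt / sw)
  rss <- sum(fit$residuals^2)
  s2p <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2p) + sum(log(w)) + n)
  list(ll = ll, beta = fit$coefficients, sigma2_p = s2p)
}

pg_fit_core <- function(yt, Xt, d) {
  f <- function(h2) pg_profile(h2, yt, Xt, d)$ll
  flags <- character()
  hi <- if (min(d) > 1e-12) 1 else 1 - 1e-9
  opt <- stats::optimize(f, c(0, hi), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, hi)
  lls <- vapply(cand, f, numeric(1))
  # flat-ridge tie break: prefer h2 = 0 when it is within numerical noise
  best <- if (lls[1] >= max(lls) - 1e-9) 1L else which.max(lls)
  h2 <- cand[best]
  ll <- lls[best]
  if (abs(f(0.5) - lls[1]) < 1e-9 && abs(lls[3] - lls[1]) < 1e-9)
    flags <- c(flags, "h2_unidentifiable")
  if (h2 < 1e-8 || h2 > 1 - 1e-8) flags <- c(flags, "h2_boundary")
  pr <- pg_profile(h2, yt, Xt, d)
  list(h2 = h2, beta = pr$beta, sigma2_g = h2 * pr$sigma2_p,
       sigma2_e = (1 - h2) * pr$sigma2_p, loglik = pr$ll, flags = flags)
}

# Joint log-likelihood in theta = (beta, sigma2_g, sigma2_e); used only for
# the observed-information standard errors.
pg_joint_ll <- function(theta, yt, Xt, d) {
  p <- ncol(Xt)
  beta <- theta[seq_len(p)]
  s2g <- theta[p + 1L]; s2e <- theta[p + 2L]
  w <- s2g * d + s2e
  if (any(w <= 0)) return(-Inf)
  r <- yt - drop(Xt %*% beta)
  -0.5 * (length(yt) * log(2 * pi) + sum(log(w)) + sum(r^2 / w))
}

pg_observed_se <- function(fit, prep) {
  p <- ncol(prep$Xt)
  theta <- c(fit$beta, fit$sigma2_g, fit$sigma2_e)
  on_boundary <- fit$sigma2_g <= 1e-8 || fit$sigma2_e <= 1e-8
  # GLS covariance for beta is exact given the variance components
  w <- fit$sigma2_g * prep$d + fit$sigma2_e
  XtWX <- crossprod(prep$Xt / sqrt(w))
  beta_se <- sqrt(diag(solve(XtWX)))
  h2_se <- NA_real_
  if (!on_boundary) {
    H <- try(pracma::hessian(function(th) pg_joint_ll(th, prep$yt, prep$Xt, prep$d),
                             theta), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(-H), silent = TRUE)
      if (!inherits(V, "try-error") && all(is.finite(diag(V)))) {
        g <- fit$sigma2_g; e <- fit$sigma2_e
        grad <- c(e, -g) / (g + e)^2
        v <- drop(t(grad) %*% V[p + 1:2, p + 1:2] %*% grad)
        if (is.finite(v) && v >= 0) h2_se <- sqrt(v)
        vb <- diag(V)[seq_len(p)]
        if (all(is.finite(vb) & vb >= 0)) beta_se <- sqrt(vb)
      }
    }
  }
  list(beta_se = beta_se, h2_se = h2_se)
}

# ---- likelihood-ratio tests ----------------------------------------------

#' Likelihood-ratio test for a covariate's mean effect
#'
#' Compares the maximized likelihood of the full polygenic model to that of
#' the nested model in which the covariate's regression coefficient is
#' constrained to zero. Both fits use exactly the same rows (listwise
#' deletion on the full covariate set happens before either fit) and the
#' same kinship rotation. The p-value is the upper chi-square(1) tail of
#' `2 * (loglik_full - loglik_null)` (interior parameter).
#'
#' @inheritParams fit_polygenic
#' @param covariate the tested covariate (must be in `covariates`).
#' @return list with `p_value`, `lambda`, `loglik_full`, `loglik_null`,
#'   `fit_full`.
#' @export
lrt_covariate <- function(data, trait, covariates, kinship, covariate) {
  if (!covariate %in% covariates) stop("covariate not in model: ", covariate)
  # a covariate that is identically zero contributes nothing: Lambda = 0
  if (covariate %in% names(data) && is.numeric(data[[covariate]]) &&
      all(data[[covariate]] == 0, na.rm = TRUE)) {
    fit <- pg_prepare(data, trait, setdiff(covariates, covariate), kinship)
    null <- pg_fit_core(fit$yt, fit$Xt, fit$d)
    return(list(p_value = 1, lambda = 0, loglik_full = null$loglik,
                loglik_null = null$loglik, fit_full = null))
  }
  prep <- pg_prepare(data, trait, covariates, kinship)
  full <- pg_fit_core(prep$yt, prep$Xt, prep$d)
  form <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
  labels <- attr(stats::terms(form), "term.labels")
  # match the tested term ignoring the order of interaction components
  canon <- function(s) paste(sort(strsplit(s, ":", fixed = TRUE)[[1]]),
                             collapse = ":")
  hit <- match(canon(covariate), vapply(labels, canon, character(1)))
  if (is.na(hit)) stop("term not found in model: ", covariate)
  # columns of the design matrix generated by the tested term
  asg <- attr(stats::model.matrix(form, data = prep$data), "assign")
  keep <- asg != hit
  Xt0 <- prep$Xt[, keep, drop = FALSE]
  null <- pg_fit_core(prep$yt, Xt0, prep$d)
  lam <- 2 * (full$loglik - null$loglik)
  if (lam < -1e-6) stop("nested model out-likelihooded full model (optimizer failure)")
  lam <- max(lam, 0)
  list(p_value = stats::pchisq(lam, df = 1, lower.tail = FALSE),
       lambda = lam, loglik_full = full$loglik, loglik_null = null$loglik,
       fit_full = full)
}

#' Likelihood-ratio test for heritability on the boundary
#'
#' Tests `h2 = 0` against `h2 > 0`. Because the null pins a variance
#' component to the boundary of its parameter space, the test statistic is
#' referred to the mixture `1/2 chi2_0 + 1/2 chi2_1`:
#' `p = 0.5 * P(chi2_1 >= Lambda)`, and `Lambda = 0` gives p = 0.5.
#'
#' @inheritParams fit_polygenic
#' @return list with `p_value`, `lambda`, `h2`, `loglik_full`, `loglik_null`.
#' @export
lrt_heritability <- function(data, trait, covariates = character(), kinship) {
  prep <- pg_prepare(data, trait, covariates, kinship)
  full <- pg_fit_core(prep$yt, prep$Xt, prep$d)
  null <- pg_profile(0, prep$yt, prep$Xt, prep$d)
  lam <- 2 * (full$loglik - null$ll)
  if (lam < -1e-6) stop("h2 = 0 out-likelihooded full model (optimizer failure)")
  lam <- max(lam, 0)
  p <- if (lam <= 0) 0.5 else 0.5 * stats::pchisq(lam, 1, lower.tail = FALSE)
  list(p_value = p, lambda = lam, h2 = full$h2,
       loglik_full = full$loglik, loglik_null = null$ll)
}

#' Kinship-aware association between a trait and a predictor
#'
#' Adds the predictor as a covariate of the polygenic model for the trait
#' and summarizes its effect the way epidemiological association tables do:
#' `R2 = beta^2 * Var(predictor) / Var(trait)` (the proportion of trait
#' variance attributable to the predictor), `r = sign(beta) * sqrt(R2)`, and
#' `p` from the covariate likelihood-ratio test — so P(r = 0) equals
#' P(beta = 0) in the model.
#'
#' @inheritParams fit_polygenic
#' @param predictor column tested for association.
#' @param covariates additional adjustment covariates kept in both models.
#' @return one-row data.frame: predictor, r2, r, p, beta, n.
#' @export
covariate_association <- function(data, trait, predictor,
                                  covariates = character(), kinship) {
  covs <- c(covariates, predictor)
  test <- lrt_covariate(data, trait, covs, kinship, predictor)
  prep <- pg_prepare(data, trait, covs, kinship)
  beta <- test$fit_full$beta[[match(predictor, colnames(prep$Xt))]]
  vx <- stats::var(prep$data[[predictor]])
  vy <- stats::var(prep$data[[trait]])
  r2 <- beta^2 * vx / vy
  data.frame(predictor = predictor, r2 = r2, r = sign(beta) * sqrt(r2),
             p = test$p_value, beta = beta, n = length(prep$yt),
             row.names = NULL)
}
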