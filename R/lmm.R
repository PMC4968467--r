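#' Orthogonal polynomial basis
#'
#' Orthonormal polynomial coding (via [stats::poly()]) used to fit set size
#' as a linear or quadratic trend.  Model log-likelihoods are invariant to
#' raw vs orthogonal coding; the orthogonal basis is numerically stable and
#' makes the linear model nested in the quadratic one by construction.
#'
#' @param x numeric predictor values.
#' @param degree polynomial degree (>= 1; at least `degree + 1` distinct
#'   values of `x` required).
#' @return A matrix with `degree` mutually orthogonal, unit-norm columns.
#' @export
orthogonal_poly <- function(x, degree) {
  stopifnot(is.numeric(x), degree >= 1)
  if (length(unique(x)) <= degree) {
    stop("need more than ", degree, " distinct values for degree ", degree)
  }
  unclass(stats::poly(x, degree = degree))
}

## Profiled ML machinery for the random-intercept Gaussian LMM
##   y = X beta + Z b + e,  b ~ N(0, s2_b I),  e ~ N(0, s2_e I)
## With lambda = s2_b / s2_e and V = I + lambda Z Z', beta and s2_e have
## closed forms given lambda, so the deviance is profiled down to a 1-D
## search.  Group structure makes V block diagonal; Woodbury gives
##   V_i^{-1} = I - lambda/(1 + lambda n_i) J,  log|V| = sum log(1+lambda n_i)
## so everything reduces to per-group column sums.
profile_pieces <- function(X, y, g, lambda) {
  n <- length(y)
  M <- cbind(X, y)
  S <- rowsum(M, g)                      # group sums
  ni <- as.vector(rowsum(rep(1, n), g))
  w <- lambda / (1 + lambda * ni)
  A <- crossprod(M) - crossprod(S * sqrt(w))
  p <- ncol(X)
  XtVX <- A[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- A[seq_len(p), p + 1L]
  ytVy <- A[p + 1L, p + 1L]
  beta <- solve(XtVX, XtVy)
  rss <- as.numeric(ytVy - crossprod(XtVy, beta))
  sigma2 <- rss / n
  ldetV <- sum(log1p(lambda * ni))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n + ldetV)
  list(beta = beta, sigma2 = sigma2, ll = ll, XtVX = XtVX)
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Gaussian linear mixed model with fixed effects from `formula` and a
#' random intercept per level of `group`, fitted by maximum likelihood (not
#' REML, so nested fits are comparable by deviance and AIC).  The deviance
#' is profiled analytically over the fixed effects and residual variance,
#' leaving a one-dimensional optimisation over the variance ratio
#' `lambda = sigma2_group / sigma2_resid`, solved deterministically by
#' golden-section/parabolic search on `log(lambda)` with the boundary
#' `lambda = 0` (an ordinary linear model) checked explicitly.  Boundary
#' fits are flagged `singular`.
#'
#' @param formula fixed-effects formula, e.g.
#'   `log_error ~ poly(set_size, 2) * coloration * contrast`.
#' @param data data.frame containing the response, predictors and `group`.
#' @param group name of the grouping column (default `"participant"`).
#' @return An object of class `lmm_fit`: coefficients and their
#'   standard errors, `vcov` of the fixed effects, variance components
#'   `sigma2_group` and `sigma2_resid`, `loglik`, `AIC` (`= -2 loglik +
#'   2 n_params`), `n_params` (fixed effects + 2 variances), `converged`
#'   and `singular` flags.
#' @examples
#' set.seed(1)
#' d <- data.frame(participant = rep(1:6, each = 5), x = rnorm(30))
#' d$y <- 1 + 0.5 * d$x + rep(rnorm(6, 0, 0.4), each = 5) + rnorm(30, 0, 0.3)
#' fit_lmm(y ~ x, d)
#' @export
fit_lmm <- function(formula, data, group = "participant") {
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  mf <- model.frame(formula, data, na.action = stats::na.fail)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups to fit a random intercept")
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design is rank deficient")
  n <- length(y)

  obj <- function(u) -2 * profile_pieces(X, y, g, exp(u))$ll
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-8)
  dev0 <- -2 * profile_pieces(X, y, g, 0)$ll
  singular <- FALSE
  if (dev0 <= opt$objective + 1e-8 || opt$minimum < -13.5) {
    lambda <- 0
    singular <- TRUE
  } else {
    lambda <- exp(opt$minimum)
  }
  pp <- profile_pieces(X, y, g, lambda)
  vcov_beta <- pp$sigma2 * solve(pp$XtVX)
  se <- sqrt(diag(vcov_beta))
  n_params <- ncol(X) + 2L
  structure(list(
    coefficients = setNames(as.numeric(pp$beta), colnames(X)),
    se = setNames(se, colnames(X)),
    vcov = vcov_beta,
    sigma2_group = lambda * pp$sigma2,
    sigma2_resid = pp$sigma2,
    lambda = lambda,
    loglik = pp$ll,
    AIC = -2 * pp$ll + 2 * n_params,
    n_params = n_params,
    df_fixed = ncol(X),
    n = n,
    converged = TRUE,
    singular = singular,
    formula = formula,
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    contrasts = attr(X, "contrasts"),
    group = group,
    X = X,
    y = y,
    g = g
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (ML)\n")
  cat("  fixed:", deparse(x$formula), "\n")
  cat(sprintf("  logLik %.4f  AIC %.4f  (n = %d, %d fixed effects)\n",
              x$loglik, x$AIC, x$n, x$df_fixed))
  cat(sprintf("  var(%s) = %.6g  var(resid) = %.6g%s\n", x$group,
              x$sigma2_group, x$sigma2_resid,
              if (x$singular) "  [singular: boundary fit]" else ""))
  ct <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
              z = x$coefficients / x$se)
  print(round(ct, 4))
  invisible(x)
}

#' Fixed-effect predictions from an `lmm_fit`
#'
#' Population-level predictions (random intercepts set to zero).
#'
#' @param object an [fit_lmm()] result.
#' @param newdata data.frame of predictor values; defaults to the fitted
#'   data.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lmm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.numeric(object$X %*% object$coefficients))
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, newdata, xlev = object$xlevels)
  X <- model.matrix(tt, mf, contrasts.arg = object$contrasts)
  as.numeric(X %*% object$coefficients)
}

#' Likelihood-ratio test between nested ML fits
#'
#' Twice the log-likelihood difference referred to a chi-squared distribution
#' with degrees of freedom equal to the difference in parameter counts.
#' Both fits must be ML fits to identical rows, with the reduced
#' fixed-effects design spanned by the full one (checked numerically).
#'
#' @param full,reduced `lmm_fit` objects.
#' @return A one-row data.frame: `chi2`, `df`, `p`, `AIC_full`,
#'   `AIC_reduced`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n != reduced$n) stop("fits use different numbers of rows")
  if (max(abs(full$y - reduced$y)) > 0) {
    stop("fits use different response values")
  }
  if (reduced$df_fixed > full$df_fixed) {
    stop("'reduced' must not have more fixed-effect parameters than 'full'")
  }
  proj <- stats::lm.fit(full$X, reduced$X)
  if (max(abs(proj$residuals)) > 1e-6) {
    stop("models are not nested: reduced design not spanned by full design")
  }
  chi2 <- 2 * (full$loglik - reduced$loglik)
  df <- full$n_params - reduced$n_params
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  data.frame(chi2 = chi2, df = df, p = p,
             AIC_full = full$AIC, AIC_reduced = reduced$AIC)
}
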