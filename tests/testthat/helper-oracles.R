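# Independent oracles and small data generators used across the test files.

# Closed-form ML solution for the balanced one-way random-effects model
# y_ij = mu + b_i + e_ij (g groups of m): with SSW = sum (y_ij - ybar_i)^2
# and SSB = m sum (ybar_i - ybar)^2, minimising the deviance in (sigma2_e, T)
# with T = sigma2_e + m sigma2_b separates into
#   sigma2_e = SSW / (N - g),  T = SSB / g  (T truncated below at sigma2_e).
balanced_oneway_ml <- function(y, g) {
  g <- factor(g)
  stopifnot(length(unique(table(g))) == 1)
  m <- unname(table(g)[1])
  N <- length(y)
  k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssw <- sum((y - gm[g])^2)
  ssb <- m * sum((gm - mean(y))^2)
  s2e <- ssw / (N - k)
  Tt <- max(ssb / k, s2e)
  s2b <- (Tt - s2e) / m
  ll <- -0.5 * (N * log(2 * pi) + (N - k) * log(s2e) + k * log(Tt) +
                  ssw / s2e + ssb / Tt)
  list(sigma2_resid = s2e, sigma2_group = s2b, loglik = ll)
}

# Brute-force ML: directly maximise the joint Gaussian log-likelihood with a
# dense covariance matrix, profiling beta by GLS at each variance point.
# Independent of the package's Woodbury/profiled-ratio path.
brute_force_ml <- function(X, y, g) {
  g <- factor(g)
  Z <- model.matrix(~ g - 1)
  n <- length(y)
  negll <- function(par) {
    V <- exp(par[1]) * tcrossprod(Z) + exp(par[2]) * diag(n)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    0.5 * (n * log(2 * pi) + determinant(V)$modulus +
             t(r) %*% Vi %*% r)[1]
  }
  v0 <- var(as.numeric(y))
  opt <- optim(log(c(v0 / 2, v0 / 2)), negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(loglik = -opt$value, sigma2_group = exp(opt$par[1]),
       sigma2_resid = exp(opt$par[2]))
}

# Balanced one-way dataset generator.
make_oneway <- function(g, m, mu = 0, sd_b = 0.3, sd_e = 0.5) {
  data.frame(participant = rep(seq_len(g), each = m),
             y = mu + rep(rnorm(g, 0, sd_b), each = m) + rnorm(g * m, 0, sd_e))
}

# Small dataset from a known random-intercept LMM with continuous and factor
# predictors.
make_lmm_data <- function(g = 6, m = 8, sd_b = 0.3, sd_e = 0.4) {
  d <- data.frame(participant = rep(seq_len(g), each = m),
                  x = rnorm(g * m),
                  f = factor(sample(c("a", "b"), g * m, replace = TRUE)))
  d$y <- 1 + 0.5 * d$x + 0.3 * (d$f == "b") +
    rep(rnorm(g, 0, sd_b), each = m) + rnorm(g * m, 0, sd_e)
  d
}

# Cell-level dataset in the experiment's layout, generated directly from a
# random-intercept linear model (no physics), with configurable condition
# effects on the log-error scale.
make_cell_data <- function(n_participants = 8,
                           col_eff = c(parallel = 0.2, orthogonal = 0.1,
                                       binary = 0),
                           con_eff = c(high = 0, low = 0),
                           size_slope = 0.02, sd_b = 0.2, sd_e = 0.3) {
  cells <- expand.grid(participant = sprintf("P%02d", seq_len(n_participants)),
                       coloration = c("parallel", "orthogonal", "binary"),
                       contrast = c("high", "low"),
                       set_size = c(1, 10, 20, 30, 40, 50, 60),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- rnorm(n_participants, 0, sd_b)
  names(b) <- sprintf("P%02d", seq_len(n_participants))
  cells$log_error <- 3 + size_slope * cells$set_size +
    col_eff[cells$coloration] + con_eff[cells$contrast] +
    b[cells$participant] + rnorm(nrow(cells), 0, sd_e)
  cells$mean_error_px <- exp(cells$log_error)
  cells
}

# Circular SD estimator: sqrt(-2 log Rbar) of the mean resultant length.
circular_sd <- function(a) {
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sqrt(-2 * log(rbar))
}

# Signed smallest angular difference.
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Fast motion params for tests that only need a short trial.
short_motion <- function(...) {
  motion_params(highlight_ms = 100, track_ms = 500, ...)
}
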