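ladder_formulas <- function() {
  list(
    full_quad   = log_error ~ poly(set_size, 2) * coloration * contrast,
    full_linear = log_error ~ poly(set_size, 1) * coloration * contrast,
    two_way     = log_error ~ (poly(set_size, 2) + coloration + contrast)^2,
    no_col_con  = log_error ~ poly(set_size, 2) * coloration +
      poly(set_size, 2):contrast + contrast,
    no_con_num  = log_error ~ poly(set_size, 2) * coloration + contrast,
    main        = log_error ~ poly(set_size, 2) + coloration + contrast,
    no_col      = log_error ~ poly(set_size, 2) + contrast,
    no_num      = log_error ~ coloration + contrast,
    no_con      = log_error ~ poly(set_size, 2) + coloration
  )
}

#' Ladder of likelihood-ratio model comparisons
#'
#' Fits the standard sequence of random-intercept models for log tracking
#' error and reports each deviance comparison: (1) quadratic vs linear trend
#' in set size, within the model containing all interactions; then
#' sequential deletion of (2) the three-way number x coloration x contrast
#' interaction, (3) coloration x contrast, (4) contrast x number,
#' (5) coloration x number; and finally each main effect — (6) coloration,
#' (7) number, (8) contrast — tested by deletion from the main-effects
#' model.  Set size enters as an orthogonal polynomial; factors use
#' treatment contrasts with alphabetical level order.
#'
#' @param data a cell-mean table from [aggregate_cells()] (default
#'   granularity) or a trial table (set `granularity = "trial"`, in which
#'   case each trial's `log(mean_error_px)` is modelled).
#' @param granularity `"cell"` (participant x condition means, the default)
#'   or `"trial"`.
#' @param group grouping column for the random intercept.
#' @return A data.frame with one row per comparison (`term`, `chi2`, `df`,
#'   `p`, `AIC_full`, `AIC_reduced`), with the list of fitted models in
#'   `attr(, "fits")`.
#' @examples
#' \donttest{
#' set.seed(1)
#' trials <- generate_dataset(session_design(reps_per_cell = 2),
#'                            n_participants = 6)
#' model_ladder(aggregate_cells(trials))
#' }
#' @export
model_ladder <- function(data, granularity = c("cell", "trial"),
                         group = "participant") {
  granularity <- match.arg(granularity)
  if (granularity == "trial") {
    if ("is_practice" %in% names(data)) {
      data <- data[!data$is_practice, , drop = FALSE]
    }
    data$log_error <- log(data$mean_error_px)
  } else if (!"log_error" %in% names(data)) {
    stop("cell-level data must contain 'log_error'; see aggregate_cells()")
  }
  data$coloration <- factor(data$coloration)
  data$contrast <- factor(data$contrast)
  fml <- ladder_formulas()
  fits <- lapply(fml, fit_lmm, data = data, group = group)
  steps <- list(
    c("number quadratic vs linear", "full_quad", "full_linear"),
    c("number:coloration:contrast", "full_quad", "two_way"),
    c("coloration:contrast",        "two_way", "no_col_con"),
    c("contrast:number",            "no_col_con", "no_con_num"),
    c("coloration:number",          "no_con_num", "main"),
    c("coloration",                 "main", "no_col"),
    c("number",                     "main", "no_num"),
    c("contrast",                   "main", "no_con")
  )
  rows <- lapply(steps, function(s) {
    cbind(term = s[1], lrt(fits[[s[2]]], fits[[s[3]]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Tukey-type post hoc contrasts of a factor's levels
#'
#' All pairwise differences between the levels of a factor that enters the
#' fit as a main effect.  Each contrast's z statistic is its estimate over
#' its standard error from the fixed-effects covariance; family-wise
#' adjusted p-values come from the joint multivariate-normal distribution of
#' the contrast statistics (single-step adjustment, quasi-Monte-Carlo
#' integration with a fixed internal seed so results are reproducible).
#'
#' @param fit an [fit_lmm()] result whose design contains the factor as a
#'   main effect (e.g. the main-effects model from [model_ladder()]).
#' @param factor_name name of the factor (default `"coloration"`).
#' @return A data.frame with one row per level pair: `contrast`, `estimate`,
#'   `se`, `z`, `p` (unadjusted, two-sided normal) and `p_adj`.
#' @export
tukey_posthoc <- function(fit, factor_name = "coloration") {
  stopifnot(inherits(fit, "lmm_fit"))
  labs <- attr(fit$terms, "term.labels")
  if (!factor_name %in% labs) {
    stop("'", factor_name, "' is not a main-effect term of the fit")
  }
  levs <- fit$xlevels[[factor_name]]
  if (is.null(levs) || length(levs) < 2) {
    stop("'", factor_name, "' is not a factor with >= 2 levels in the fit")
  }
  cn <- names(fit$coefficients)
  # column of the treatment-coded dummy for each non-reference level
  dummy_of <- setNames(rep(NA_integer_, length(levs)), levs)
  for (l in levs) {
    j <- match(paste0(factor_name, l), cn)
    if (!is.na(j)) dummy_of[l] <- j
  }
  pairs <- utils::combn(levs, 2)
  K <- matrix(0, ncol(pairs), length(cn),
              dimnames = list(NULL, cn))
  lab <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[2, k]; b <- pairs[1, k]      # a - b, later level minus earlier
    lab[k] <- paste(a, "-", b)
    if (!is.na(dummy_of[a])) K[k, dummy_of[a]] <- 1
    if (!is.na(dummy_of[b])) K[k, dummy_of[b]] <- K[k, dummy_of[b]] - 1
  }
  est <- as.numeric(K %*% fit$coefficients)
  V <- K %*% fit$vcov %*% t(K)
  se <- sqrt(diag(V))
  z <- est / se
  R <- stats::cov2cor(V)
  p_adj <- vapply(z, function(zi) {
    1 - mvn_box_prob(abs(zi), R)
  }, numeric(1))
  data.frame(contrast = lab, estimate = est, se = se, z = z,
             p = 2 * pnorm(-abs(z)), p_adj = pmin(pmax(p_adj, 0), 1))
}

# P(|Z_k| < b for all k), Z ~ N(0, R); fixed-seed quasi-Monte-Carlo so the
# adjusted p-values are reproducible.  R may be singular (pairwise contrasts
# of one factor are linearly dependent).
mvn_box_prob <- function(b, R) {
  m <- nrow(R)
  seed_keeper <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(seed_keeper)) assign(".Random.seed", seed_keeper,
                                      envir = globalenv())
  }, add = TRUE)
  set.seed(20160706L)
  as.numeric(mvtnorm::pmvnorm(
    lower = rep(-b, m), upper = rep(b, m), corr = R,
    algorithm = mvtnorm::GenzBretz(maxpts = 1e5, abseps = 1e-6)))
}

#' Within-subject confidence intervals for condition means
#'
#' Cousineau-Morey intervals for repeated-measures condition means: each
#' participant's grand mean is subtracted (and the global grand mean added
#' back) to remove between-subject level differences, per-condition standard
#' errors are computed on the normalised values, inflated by the Morey
#' correction `sqrt(C / (C - 1))` for `C` conditions, and scaled by the t
#' quantile.
#'
#' @param data data.frame with one row per participant per condition cell.
#' @param value_col response column name.
#' @param participant_col participant identifier column.
#' @param cell_cols columns jointly defining the condition cells.
#' @param level confidence level.
#' @return A data.frame with one row per condition: the cell columns,
#'   `mean`, and the interval half-width `ci_half`.
#' @export
within_subject_ci <- function(data, value_col = "mean_error_px",
                              participant_col = "participant",
                              cell_cols = c("coloration", "contrast",
                                            "set_size"),
                              level = 0.95) {
  stopifnot(all(c(value_col, participant_col, cell_cols) %in% names(data)),
            level > 0, level < 1)
  cell <- interaction(data[cell_cols], drop = TRUE, lex.order = TRUE)
  C <- nlevels(cell)
  if (C < 2) stop("need at least 2 condition cells for the Morey correction")
  pid <- factor(data[[participant_col]])
  tab <- table(pid, cell)
  if (any(tab != 1)) {
    stop("each participant must contribute exactly one value per cell; ",
         "aggregate first (see aggregate_cells)")
  }
  y <- data[[value_col]]
  y_adj <- y - ave(y, pid) + mean(y)
  morey <- sqrt(C / (C - 1))
  agg_in <- data[cell_cols]
  out <- aggregate(y_adj, by = agg_in, FUN = function(v) {
    c(mean = mean(v), half = morey * qt((1 + level) / 2, length(v) - 1) *
        sd(v) / sqrt(length(v)))
  })
  res <- cbind(out[cell_cols], mean = out$x[, "mean"],
               ci_half = out$x[, "half"])
  # cell means of the raw values (normalisation shifts only error bars)
  raw <- aggregate(y, by = agg_in, FUN = mean)
  res$mean <- raw$x
  ord <- do.call(order, res[cell_cols])
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
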