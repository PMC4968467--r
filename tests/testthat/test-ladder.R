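test_that("the comparison ladder has the canonical structure", {
  set.seed(81)
  cells <- make_cell_data(n_participants = 8)
  lad <- model_ladder(cells)
  expect_equal(lad$term,
               c("number quadratic vs linear", "number:coloration:contrast",
                 "coloration:contrast", "contrast:number",
                 "coloration:number", "coloration", "number", "contrast"))
  expect_equal(lad$df, c(6, 4, 2, 2, 4, 2, 2, 1))
  expect_true(all(lad$p >= 0 & lad$p <= 1))
  fits <- attr(lad, "fits")
  expect_length(fits, 9L)
  # AIC identity for every fit in the ladder
  for (f in fits) expect_equal(f$AIC, -2 * f$loglik + 2 * f$n_params)
  # fixed-effect counts of the two ends of the ladder
  expect_equal(fits$full_quad$df_fixed, 18L)
  expect_equal(fits$main$df_fixed, 6L)
})

test_that("injected effects are detected and absent effects are not", {
  set.seed(82)
  cells <- make_cell_data(n_participants = 10,
                          col_eff = c(parallel = 0.3, orthogonal = 0.15,
                                      binary = 0),
                          con_eff = c(high = 0, low = 0))
  lad <- model_ladder(cells)
  expect_lt(lad$p[lad$term == "coloration"], 0.001)
  expect_lt(lad$p[lad$term == "number"], 0.001)
  expect_gt(lad$p[lad$term == "contrast"], 0.01)
})

test_that("the contrast main-effect p-value is uniform under the null", {
  set.seed(83)
  pvals <- replicate(500, {
    d <- make_cell_data(n_participants = 4, size_slope = 0,
                        col_eff = c(parallel = 0, orthogonal = 0, binary = 0))
    full <- fit_lmm(log_error ~ coloration + contrast, d)
    red <- fit_lmm(log_error ~ coloration, d)
    lrt(full, red)$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("trial-level and cell-level responses give consistent answers", {
  set.seed(84)
  cells <- make_cell_data(n_participants = 8,
                          col_eff = c(parallel = 0.3, orthogonal = 0.15,
                                      binary = 0))
  # duplicate each cell into two pseudo-trials so granularities differ
  trials <- rbind(cells, cells)
  trials$mean_error_px <- trials$mean_error_px * exp(rnorm(nrow(trials), 0,
                                                           0.05))
  trials$log_error <- NULL
  lad_cell <- model_ladder(aggregate_cells(trials))
  lad_trial <- model_ladder(trials, granularity = "trial")
  expect_lt(lad_cell$p[lad_cell$term == "coloration"], 0.01)
  expect_lt(lad_trial$p[lad_trial$term == "coloration"], 0.01)
})

test_that("Tukey contrasts match the reference multiple-testing stack", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("multcomp")
  set.seed(85)
  cells <- make_cell_data(n_participants = 10,
                          col_eff = c(parallel = 0.25, orthogonal = 0.1,
                                      binary = 0))
  cells$coloration <- factor(cells$coloration)
  cells$contrast <- factor(cells$contrast)
  lad <- model_ladder(cells)
  ours <- tukey_posthoc(attr(lad, "fits")$main, "coloration")

  ref_fit <- lme4::lmer(
    log_error ~ poly(set_size, 2) + coloration + contrast + (1 | participant),
    data = cells, REML = FALSE)
  ref <- summary(multcomp::glht(ref_fit,
                                linfct = multcomp::mcp(coloration = "Tukey")))
  expect_equal(unname(ours$estimate), unname(ref$test$coefficients),
               tolerance = 1e-5)
  expect_equal(unname(ours$z), unname(ref$test$tstat), tolerance = 1e-4)
  # multcomp's own quasi-random integration differs by up to its abseps
  expect_lt(max(abs(ours$p_adj - as.numeric(ref$test$pvalues))), 2e-3)
  expect_true(all(ours$p_adj >= ours$p - 1e-10))
})

test_that("null simulated factors rarely produce extreme contrast z", {
  set.seed(86)
  n_extreme <- sum(replicate(50, {
    d <- make_cell_data(n_participants = 6, size_slope = 0,
                        col_eff = c(parallel = 0, orthogonal = 0, binary = 0))
    fit <- fit_lmm(log_error ~ coloration + contrast, d)
    any(abs(tukey_posthoc(fit, "coloration")$z) >= 3)
  }))
  expect_lte(n_extreme, 2)
})

test_that("tukey_posthoc validates its inputs and is deterministic", {
  set.seed(87)
  cells <- make_cell_data(n_participants = 6)
  cells$coloration <- factor(cells$coloration)
  cells$contrast <- factor(cells$contrast)
  fit <- fit_lmm(log_error ~ poly(set_size, 2) + coloration + contrast, cells)
  expect_error(tukey_posthoc(fit, "set_size"), "main-effect")
  a <- tukey_posthoc(fit, "coloration")
  b <- tukey_posthoc(fit, "coloration")
  expect_identical(a, b)
  expect_equal(a$contrast, c("orthogonal - binary", "parallel - binary",
                             "parallel - orthogonal"))
  expect_equal(a$z, a$estimate / a$se)
})

test_that("within-subject intervals remove between-subject offsets", {
  base <- expand.grid(participant = sprintf("P%d", 1:8),
                      coloration = c("parallel", "orthogonal", "binary"),
                      contrast = c("high", "low"),
                      set_size = c(1, 30, 60),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pattern <- with(base, 20 + set_size / 2 +
                    5 * (coloration == "parallel"))
  # identical participants: zero-width intervals
  d0 <- base
  d0$mean_error_px <- pattern
  ci0 <- within_subject_ci(d0)
  expect_true(all(abs(ci0$ci_half) < 1e-12))
  expect_equal(ci0$mean, d0$mean_error_px[match(
    paste(ci0$coloration, ci0$contrast, ci0$set_size),
    paste(d0$coloration, d0$contrast, d0$set_size))])

  # additive participant offsets leave the interval widths unchanged
  set.seed(88)
  noise <- rnorm(nrow(base), 0, 2)
  d1 <- base
  d1$mean_error_px <- pattern + noise
  offs <- setNames(rnorm(8, 0, 50), sprintf("P%d", 1:8))
  d2 <- base
  d2$mean_error_px <- pattern + noise + offs[base$participant]
  expect_equal(within_subject_ci(d1)$ci_half, within_subject_ci(d2)$ci_half,
               tolerance = 1e-10)

  # degenerate and incomplete inputs are rejected
  expect_error(within_subject_ci(d1, cell_cols = character(0)))
  one_cell <- d1[d1$coloration == "parallel" & d1$contrast == "high" &
                   d1$set_size == 1, ]
  expect_error(within_subject_ci(one_cell), "at least 2")
  expect_error(within_subject_ci(d1[-1, ]), "exactly one value")
})
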