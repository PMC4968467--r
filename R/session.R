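#' Experimental session design
#'
#' The tracking experiment crosses three colorations with two contrast
#' levels, one block per combination (6 blocks in random order), and within
#' each block crosses seven set sizes with `reps_per_cell` repeats in random
#' order.  The default `reps_per_cell = 8` gives the standard session of
#' 6 x 7 x 8 = 336 analysed trials, preceded by 4 practice trials that are
#' flagged and excluded from analysis.
#'
#' @param colorations,contrasts,set_sizes factor levels of the design.
#' @param reps_per_cell trials per coloration x contrast x set-size cell.
#' @param n_practice number of practice trials prepended to the session.
#' @param highlight_ms,track_ms trial phase durations (ms).
#' @return An object of class `session_design`.
#' @export
session_design <- function(colorations = c("parallel", "orthogonal", "binary"),
                           contrasts = c("high", "low"),
                           set_sizes = c(1, 10, 20, 30, 40, 50, 60),
                           reps_per_cell = 8, n_practice = 4,
                           highlight_ms = 1000, track_ms = 5000) {
  stopifnot(length(colorations) >= 1, length(contrasts) >= 1,
            length(set_sizes) >= 1, reps_per_cell >= 1, n_practice >= 0,
            highlight_ms >= 0, track_ms > 0)
  structure(list(colorations = colorations, contrasts = contrasts,
                 set_sizes = set_sizes,
                 reps_per_cell = as.integer(reps_per_cell),
                 n_practice = as.integer(n_practice),
                 highlight_ms = highlight_ms, track_ms = track_ms),
            class = "session_design")
}

#' Build one participant's randomised trial list
#'
#' Blocks (one per coloration x contrast combination) are put in random
#' order; within each block the set-size x repeat trials are shuffled.
#' Practice trials use the first block's condition at set size 20 and are
#' flagged `is_practice`.
#'
#' @param design a [session_design()].
#' @return A data.frame of trial specifications in presentation order:
#'   `trial`, `block_index`, `coloration`, `contrast`, `set_size`,
#'   `is_practice`.
#' @examples
#' set.seed(1)
#' sess <- build_session(session_design())
#' sum(!sess$is_practice)  # 336
#' @export
build_session <- function(design = session_design()) {
  stopifnot(inherits(design, "session_design"))
  combos <- expand.grid(coloration = design$colorations,
                        contrast = design$contrasts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  blocks <- lapply(seq_len(nrow(combos)), function(b) {
    sizes <- rep(design$set_sizes, each = design$reps_per_cell)
    sizes <- sizes[sample.int(length(sizes))]
    data.frame(block_index = b,
               coloration = combos$coloration[b],
               contrast = combos$contrast[b],
               set_size = sizes,
               is_practice = FALSE)
  })
  main <- do.call(rbind, blocks)
  if (design$n_practice > 0) {
    practice <- data.frame(block_index = 1L,
                           coloration = combos$coloration[1],
                           contrast = combos$contrast[1],
                           set_size = practice_set_size(design),
                           is_practice = TRUE)
    practice <- practice[rep(1L, design$n_practice), , drop = FALSE]
    main <- rbind(practice, main)
  }
  main$trial <- seq_len(nrow(main))
  rownames(main) <- NULL
  main[, c("trial", "block_index", "coloration", "contrast", "set_size",
           "is_practice")]
}

practice_set_size <- function(design) {
  if (20 %in% design$set_sizes) 20 else design$set_sizes[[1L]]
}

#' Run a single trial
#'
#' Simulates square motion for the highlight plus tracking phases, simulates
#' the observer's cursor, and computes the mean tracking error over the final
#' 4000 ms ([tracking_error()]).
#'
#' @param spec one row of a [build_session()] table (or any list with
#'   `coloration`, `contrast`, `set_size`, and optionally `is_practice`).
#' @param motion a [motion_params()]; its `highlight_ms`/`track_ms` set the
#'   trial phase durations.
#' @param obs participant-level [observer_params()].
#' @param win an [error_window()].
#' @return A one-row data.frame trial record with `mean_error_px` appended.
#' @export
run_trial <- function(spec, motion = motion_params(), obs = observer_params(),
                      win = error_window()) {
  traj <- simulate_trial_motion(spec$set_size, motion)
  sim <- simulate_cursor(traj, obs, coloration = spec$coloration)
  err <- tracking_error(sim$target_path, sim$cursor, win,
                        sample_interval_ms = 1000 / motion$frame_rate)
  data.frame(coloration = spec$coloration, contrast = spec$contrast,
             set_size = spec$set_size,
             is_practice = isTRUE(spec$is_practice),
             mean_error_px = err)
}

#' Stimulus patterns for one trial
#'
#' Draws the per-square pattern specifications used to render a trial's
#' stimuli: gratings get an independent random phase (0 or 180 degrees with
#' probability 1/2) per square; binary noise is resampled per square unless
#' `shared_noise` is set, in which case a single noise image is reused for
#' all squares in the trial.
#'
#' @param coloration,contrast condition labels.
#' @param n number of squares.
#' @param shared_noise share one binary-noise image across the trial's
#'   squares.
#' @return A list of `n` rendered luminance matrices.
#' @export
build_stimuli <- function(coloration, contrast, n, shared_noise = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (coloration == "binary") {
    if (shared_noise) {
      img <- render_binary_noise(pattern_spec("binary", contrast))
      return(rep(list(img), n))
    }
    return(lapply(seq_len(n), function(i)
      render_binary_noise(pattern_spec("binary", contrast))))
  }
  phases <- sample(c(0, 180), n, replace = TRUE)
  lapply(phases, function(ph)
    render_grating(pattern_spec(coloration, contrast, phase = ph)))
}
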