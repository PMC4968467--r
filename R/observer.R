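#' Synthetic observer parameters
#'
#' A deliberately simple, explicitly synthetic stand-in for a human
#' participant tracking one square among identical distractors.  The cursor
#' follows a "believed" target with a perceptual lag and isotropic motor
#' noise; on every tracking frame the belief may switch to the nearest
#' distractor with probability proportional to the local crowding around the
#' believed square.  Crowding-driven swaps produce the confusion effect
#' (error growing with set size), and the per-coloration `similarity`
#' multipliers produce the condition ordering (parallel hardest, binary
#' easiest).  None of these parameters are estimates of human behaviour.
#'
#' @param motor_sd SD (px) of isotropic Gaussian positional noise added to
#'   the cursor each 10 ms sample.
#' @param lag_ms tracking delay: the cursor aims at the believed square's
#'   position `lag_ms` earlier.
#' @param swap_base per-frame probability scale of switching the believed
#'   target; multiplied by `similarity[coloration]` and by the number of
#'   distractors within `swap_radius` px of the believed square.
#' @param swap_radius crowding radius in px.
#' @param similarity named multipliers (> 0) per coloration condition; the
#'   defaults order tracking difficulty parallel > orthogonal > binary.
#' @param participant_sd SD of the between-participant lognormal scale
#'   applied (independently) to `motor_sd` and `swap_base`.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(motor_sd = 10, lag_ms = 100, swap_base = 5e-4,
                            swap_radius = 60,
                            similarity = c(parallel = 1.6, orthogonal = 1.25,
                                           binary = 1.0),
                            participant_sd = 0.25) {
  stopifnot(motor_sd >= 0, lag_ms >= 0, swap_base >= 0, swap_radius >= 0,
            participant_sd >= 0)
  if (!all(c("parallel", "orthogonal", "binary") %in% names(similarity))) {
    stop("'similarity' must name all of parallel, orthogonal, binary")
  }
  if (any(similarity <= 0)) stop("similarity multipliers must be positive")
  structure(list(motor_sd = motor_sd, lag_ms = lag_ms, swap_base = swap_base,
                 swap_radius = swap_radius, similarity = similarity,
                 participant_sd = participant_sd),
            class = "observer_params")
}

#' Draw one participant's observer parameters
#'
#' Applies independent lognormal multipliers `exp(N(0, participant_sd))` to
#' `motor_sd` and `swap_base`; with `participant_sd = 0` all participants are
#' exchangeable.
#'
#' @param obs an [observer_params()].
#' @return An `observer_params` with `participant_sd = 0` and scaled
#'   `motor_sd`, `swap_base`.
#' @export
participant_draw <- function(obs) {
  stopifnot(inherits(obs, "observer_params"))
  out <- obs
  out$motor_sd <- obs$motor_sd * exp(rnorm(1, 0, obs$participant_sd))
  out$swap_base <- obs$swap_base * exp(rnorm(1, 0, obs$participant_sd))
  out$participant_sd <- 0
  out
}

#' Simulate the observer's cursor for one trial
#'
#' The cursor is sampled on the same 10 ms time base as the square positions,
#' starts exactly on the true target at the end of the highlight period, and
#' thereafter follows the believed square with delay `lag_ms` plus isotropic
#' noise `motor_sd`.  Belief swaps are described under [observer_params()].
#'
#' @param traj a `trajectory_set` from [simulate_trial_motion()].
#' @param obs an [observer_params()] (participant-level, i.e. after
#'   [participant_draw()] if heterogeneity is wanted).
#' @param coloration condition label selecting the similarity multiplier.
#' @return A list with `cursor` (tracking-frame x 2 matrix), `target_path`
#'   (same shape, true target positions) and `believed` (index per frame).
#' @export
simulate_cursor <- function(traj, obs, coloration = "binary") {
  stopifnot(inherits(traj, "trajectory_set"), inherits(obs, "observer_params"))
  p <- traj$params
  start_frame <- as.integer(round(p$highlight_ms / 1000 * p$frame_rate)) + 1L
  lag_frames <- as.integer(round(obs$lag_ms / 1000 * p$frame_rate))
  mult <- obs$similarity[[coloration]]
  sim <- sim_cursor_cpp(traj$x, traj$y, traj$target, start_frame,
                        obs$motor_sd, lag_frames, obs$swap_base,
                        obs$swap_radius, mult)
  rows <- start_frame:traj$n_frames
  target_path <- cbind(traj$x[rows, traj$target], traj$y[rows, traj$target])
  list(cursor = sim$cursor, target_path = target_path,
       believed = sim$believed)
}

#' Generate a synthetic multi-participant trial dataset
#'
#' Runs the full design for each synthetic participant: an independent
#' randomised session ([build_session()]), simulated square motion, the
#' synthetic observer's cursor, and the per-trial mean tracking error.  This
#' emulates the per-trial records of a human experiment (14 participants x
#' 336 analysed trials under the default design).
#'
#' @param design a [session_design()].
#' @param motion a [motion_params()].
#' @param obs an [observer_params()]; participant heterogeneity comes from
#'   `participant_sd` via [participant_draw()].
#' @param n_participants number of synthetic participants.
#' @param keep_practice keep practice trials (flagged, default) or drop them.
#' @return A data.frame of trial records: `participant`, `block_index`,
#'   `coloration`, `contrast`, `set_size`, `mean_error_px`, `is_practice`.
#' @examples
#' \donttest{
#' set.seed(1)
#' d <- generate_dataset(session_design(reps_per_cell = 1), n_participants = 2)
#' table(d$participant, d$is_practice)
#' }
#' @export
generate_dataset <- function(design = session_design(),
                             motion = motion_params(),
                             obs = observer_params(),
                             n_participants = 14,
                             keep_practice = TRUE) {
  stopifnot(inherits(design, "session_design"), n_participants >= 1)
  motion$highlight_ms <- design$highlight_ms
  motion$track_ms <- design$track_ms
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    obs_i <- participant_draw(obs)
    sess <- build_session(design)
    err <- vapply(seq_len(nrow(sess)), function(k) {
      run_trial(sess[k, ], motion, obs_i)$mean_error_px
    }, numeric(1))
    sess$mean_error_px <- err
    sess$participant <- sprintf("P%02d", i)
    out[[i]] <- sess
  }
  res <- do.call(rbind, out)
  if (!keep_practice) res <- res[!res$is_practice, , drop = FALSE]
  rownames(res) <- NULL
  res[, c("participant", "block_index", "coloration", "contrast",
          "set_size", "mean_error_px", "is_practice")]
}
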