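#' Motion parameters for the confined correlated random walk
#'
#' Defaults reproduce the display conditions of the tracking task: squares of
#' 32 px move at 200 px/s on a 100 Hz display (2 px per frame), headings
#' evolve by circular-Gaussian increments with SD pi/8 rad, and square
#' centres are confined to a 268 x 268 px arena centred on the origin.  A
#' trial lasts 6000 ms: a 1000 ms target highlight followed by 5000 ms of
#' tracking.
#'
#' @param speed px per second.
#' @param frame_rate display frames per second (also the 10 ms sample rate of
#'   the recorded positions at the default 100 Hz).
#' @param sigma SD (radians) of the wrapped-normal per-frame heading change.
#' @param arena_px side of the square confinement region, in px.
#' @param square_px side of each moving square, in px (used when
#'   `confine_mode = "square"`).
#' @param highlight_ms,track_ms durations of the highlight and tracking
#'   phases.
#' @param confine_mode `"centre"` (default) confines the square's centre to
#'   the arena; `"square"` confines the whole square (centre stays
#'   `square_px/2` inside the walls).
#' @param max_redraw attempts to redraw an arena-exiting heading increment
#'   before reflecting the heading about the violated wall.
#' @return An object of class `motion_params`.
#' @examples
#' p <- motion_params()
#' p$speed / p$frame_rate  # px per frame
#' @export
motion_params <- function(speed = 200, frame_rate = 100, sigma = pi / 8,
                          arena_px = 268, square_px = 32,
                          highlight_ms = 1000, track_ms = 5000,
                          confine_mode = c("centre", "square"),
                          max_redraw = 20L) {
  confine_mode <- match.arg(confine_mode)
  stopifnot(speed > 0, frame_rate > 0, sigma >= 0, sigma < pi,
            arena_px >= square_px, highlight_ms >= 0, track_ms > 0,
            max_redraw >= 0)
  structure(list(speed = speed, frame_rate = frame_rate, sigma = sigma,
                 arena_px = arena_px, square_px = square_px,
                 highlight_ms = highlight_ms, track_ms = track_ms,
                 confine_mode = confine_mode,
                 max_redraw = as.integer(max_redraw)),
            class = "motion_params")
}

arena_bounds <- function(params) {
  half <- params$arena_px / 2
  if (params$confine_mode == "square") half <- half - params$square_px / 2
  c(-half, half)
}

n_frames_of <- function(params) {
  as.integer(round((params$highlight_ms + params$track_ms) / 1000 *
                     params$frame_rate))
}

wrap_angle <- function(theta) theta %% (2 * pi)

#' One heading update of the correlated random walk
#'
#' Adds a wrapped-normal increment (mean 0, SD `sigma`) to the heading, so
#' continuing straight is always the most probable direction.  Vectorised
#' over `theta`.
#'
#' @param theta current heading(s), radians.
#' @param sigma increment SD, radians (`sigma = 0` leaves headings unchanged).
#' @return New heading(s) in `[0, 2*pi)`.
#' @export
step_heading <- function(theta, sigma) {
  stopifnot(sigma >= 0)
  wrap_angle(theta + rnorm(length(theta), 0, sigma))
}

#' One movement step of a single square
#'
#' Reference single-step implementation of the walk used by
#' [simulate_trial_motion()]: update the heading via [step_heading()], move
#' `speed / frame_rate` px along it, and keep the centre inside the arena by
#' redrawing an exiting increment up to `max_redraw` times, then reflecting
#' the heading about the violated wall.
#'
#' @param state list with `position` (length-2 numeric) and `heading`.
#' @param params a [motion_params()].
#' @return Updated state (same shape as `state`).
#' @export
advance <- function(state, params) {
  stopifnot(inherits(params, "motion_params"),
            length(state$position) == 2L)
  b <- arena_bounds(params)
  step <- params$speed / params$frame_rate
  th <- NA_real_
  pos <- c(NA_real_, NA_real_)
  for (a in seq_len(params$max_redraw + 1L)) {
    th <- step_heading(state$heading, params$sigma)
    pos <- state$position + step * c(cos(th), sin(th))
    if (all(pos >= b[1] & pos <= b[2])) {
      return(list(position = pos, heading = th))
    }
  }
  if (pos[1] < b[1] || pos[1] > b[2]) th <- wrap_angle(pi - th)
  if (pos[2] < b[1] || pos[2] > b[2]) th <- wrap_angle(-th)
  pos <- pmin(pmax(state$position + step * c(cos(th), sin(th)), b[1]), b[2])
  list(position = pos, heading = th)
}

#' Simulate the motion of one trial
#'
#' Generates confined correlated random walks for `n` squares over the whole
#' trial (highlight plus tracking phases).  Initial positions are uniform in
#' the arena and initial headings uniform on the circle; one square is chosen
#' uniformly as the target.  Each square's drawn orientation equals its
#' heading, so oriented patterns stay locked to the direction of motion.
#'
#' @param n number of squares; the experimental set sizes are
#'   1, 10, 20, 30, 40, 50, 60 (other positive values are allowed with a
#'   warning).
#' @param params a [motion_params()].
#' @param target optional 1-based target index (default: drawn uniformly).
#' @return An object of class `trajectory_set`: list with frame-by-square
#'   matrices `x`, `y`, `heading` (row 1 = initial state), `target`,
#'   `n_frames` and `params`.  Successive rows are `speed / frame_rate` px
#'   apart for every square.
#' @export
simulate_trial_motion <- function(n, params = motion_params(), target = NULL) {
  stopifnot(inherits(params, "motion_params"))
  if (n < 1) stop("need at least one square")
  n <- as.integer(n)
  if (!n %in% c(1L, 10L, 20L, 30L, 40L, 50L, 60L)) {
    warning("set size ", n, " is outside the standard design {1,10,...,60}")
  }
  if (is.null(target)) target <- sample.int(n, 1L)
  stopifnot(target >= 1L, target <= n)
  b <- arena_bounds(params)
  nf <- n_frames_of(params)
  sim <- sim_motion_cpp(n, nf, params$speed / params$frame_rate,
                        params$sigma, b[1], b[2], b[1], b[2],
                        params$max_redraw)
  structure(list(x = sim$x, y = sim$y, heading = sim$heading,
                 target = as.integer(target), n_frames = nf, params = params),
            class = "trajectory_set")
}

#' Export a trajectory set as a long-format table
#'
#' @param traj a `trajectory_set` from [simulate_trial_motion()].
#' @return A data.frame with columns `frame`, `square`, `x`, `y`, `heading`,
#'   `is_target`, one row per square per frame.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- ncol(traj$x)
  data.frame(
    frame = rep(seq_len(traj$n_frames), times = n),
    square = rep(seq_len(n), each = traj$n_frames),
    x = as.vector(traj$x),
    y = as.vector(traj$y),
    heading = as.vector(traj$heading),
    is_target = rep(seq_len(n) == traj$target, each = traj$n_frames)
  )
}
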