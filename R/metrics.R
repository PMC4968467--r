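#' Error-window definition
#'
#' The response variable is the mean cursor-target distance over the final
#' portion of the tracking period, taken as the half-open interval
#' `(track_ms - window_ms, track_ms]` sampled every `sample_interval_ms`:
#' with the defaults, exactly 400 of the 500 recorded samples.
#'
#' @param window_ms length of the scored window (ms).
#' @param sample_interval_ms position sampling interval (ms).
#' @return An object of class `error_window`.
#' @export
error_window <- function(window_ms = 4000, sample_interval_ms = 10) {
  stopifnot(window_ms > 0, sample_interval_ms > 0,
            window_ms %% sample_interval_ms == 0)
  structure(list(window_ms = window_ms,
                 sample_interval_ms = sample_interval_ms),
            class = "error_window")
}

#' Mean tracking error of one trial
#'
#' Mean Euclidean distance (px) between cursor and target centre over the
#' final `window_ms` of the tracking period.  Both paths must be sampled on
#' the same time base and cover the whole tracking period; the window keeps
#' the last `window_ms / sample_interval_ms` samples.
#'
#' @param target_path,cursor_path n x 2 matrices of positions on a common
#'   10 ms time base.
#' @param win an [error_window()].
#' @param sample_interval_ms sampling interval of the supplied paths; must
#'   match `win$sample_interval_ms`.
#' @return Mean distance in px.
#' @examples
#' tp <- matrix(0, 500, 2)
#' tracking_error(tp, tp + rep(c(3, 4), each = 500))  # 5
#' @export
tracking_error <- function(target_path, cursor_path, win = error_window(),
                           sample_interval_ms = win$sample_interval_ms) {
  target_path <- as.matrix(target_path)
  cursor_path <- as.matrix(cursor_path)
  stopifnot(inherits(win, "error_window"),
            ncol(target_path) == 2L, ncol(cursor_path) == 2L)
  if (nrow(target_path) != nrow(cursor_path)) {
    stop("target and cursor paths have unequal lengths (",
         nrow(target_path), " vs ", nrow(cursor_path), ")")
  }
  if (sample_interval_ms != win$sample_interval_ms) {
    stop("path sampling interval does not match the error window")
  }
  k <- win$window_ms / win$sample_interval_ms
  n <- nrow(target_path)
  if (n < k) stop("paths shorter than the scoring window")
  rows <- (n - k + 1):n
  d <- target_path[rows, , drop = FALSE] - cursor_path[rows, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Aggregate trials into per-participant cell means
#'
#' Averages trial errors within each participant x coloration x contrast x
#' set-size cell and log-transforms the cell mean (`log_error =
#' log(mean_error_px)`), the scale on which the mixed models are fitted;
#' tracking errors are approximately lognormal.  Practice trials are dropped
#' first.  The standard design yields 14 x 6 x 7 = 588 rows.
#'
#' @param trials trial table from [generate_dataset()] or [read_trials()].
#' @param check_complete error on empty design cells (any participant x
#'   condition combination with no trials).
#' @return A data.frame with one row per cell: `participant`, `coloration`,
#'   `contrast`, `set_size`, `mean_error_px` (cell mean), `log_error`.
#' @export
aggregate_cells <- function(trials, check_complete = TRUE) {
  required <- c("participant", "coloration", "contrast", "set_size",
                "mean_error_px")
  miss <- setdiff(required, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if ("is_practice" %in% names(trials)) {
    trials <- trials[!trials$is_practice, , drop = FALSE]
  }
  if (!nrow(trials)) stop("no analysable trials")
  cells <- aggregate(mean_error_px ~ participant + coloration + contrast +
                       set_size, data = trials, FUN = mean)
  if (check_complete) {
    expected <- length(unique(trials$participant)) *
      length(unique(trials$coloration)) * length(unique(trials$contrast)) *
      length(unique(trials$set_size))
    if (nrow(cells) != expected) {
      full <- expand.grid(participant = unique(trials$participant),
                          coloration = unique(trials$coloration),
                          contrast = unique(trials$contrast),
                          set_size = unique(trials$set_size),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      key <- function(d) paste(d$participant, d$coloration, d$contrast,
                               d$set_size, sep = "/")
      missing_cells <- setdiff(key(full), key(cells))
      stop("empty design cells: ",
           paste(utils::head(missing_cells, 5), collapse = "; "),
           if (length(missing_cells) > 5) " ...")
    }
  }
  cells$log_error <- log(cells$mean_error_px)
  ord <- order(cells$participant, cells$coloration, cells$contrast,
               cells$set_size)
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  cells
}
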