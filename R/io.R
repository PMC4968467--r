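#' Column map for external trial tables
#'
#' Declares how an external delimited trial table maps onto the canonical
#' schema (`participant`, `coloration`, `contrast`, `set_size`,
#' `mean_error_px`, optional `is_practice`), including factor-level
#' recodings.  Nothing is guessed silently: unmapped columns and unknown
#' factor levels are errors.
#'
#' @param participant,coloration,contrast,set_size,mean_error_px source
#'   column names for the required canonical fields.
#' @param is_practice source column flagging practice trials, or `NULL` if
#'   the table has none.
#' @param recode named list of named character vectors mapping source
#'   factor labels to canonical ones, e.g.
#'   `list(coloration = c(par = "parallel", orth = "orthogonal",
#'   bin = "binary"))`.
#' @return An object of class `column_map`.
#' @export
column_map <- function(participant = "participant",
                       coloration = "coloration",
                       contrast = "contrast",
                       set_size = "set_size",
                       mean_error_px = "mean_error_px",
                       is_practice = "is_practice",
                       recode = list()) {
  structure(list(participant = participant, coloration = coloration,
                 contrast = contrast, set_size = set_size,
                 mean_error_px = mean_error_px, is_practice = is_practice,
                 recode = recode),
            class = "column_map")
}

canonical_levels <- list(coloration = c("parallel", "orthogonal", "binary"),
                         contrast = c("high", "low"))

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a trial table from a delimited text file
#'
#' Reads a per-trial dataset (e.g. an experiment export or the output of
#' [write_trials()]), applies a [column_map()], validates factor levels and
#' numeric fields with row numbers in every error message, and drops flagged
#' practice trials.
#'
#' @param path file path; delimiter auto-sniffed (tab, comma or whitespace)
#'   unless `delim` is given.
#' @param map a [column_map()].
#' @param delim field delimiter override.
#' @param drop_practice drop rows flagged as practice (default `TRUE`).
#' @return Canonical trial data.frame (schema of [generate_dataset()]).
#' @export
read_trials <- function(path, map = column_map(), delim = NULL,
                        drop_practice = TRUE) {
  stopifnot(inherits(map, "column_map"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- sniff_delim(path)
  raw <- read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("participant", "coloration", "contrast", "set_size",
                "mean_error_px")
  src <- unlist(map[required])
  missing_cols <- src[!src %in% names(raw)]
  if (length(missing_cols)) {
    stop("mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(participant = as.character(raw[[map$participant]]),
                    coloration = as.character(raw[[map$coloration]]),
                    contrast = as.character(raw[[map$contrast]]),
                    set_size = raw[[map$set_size]],
                    mean_error_px = raw[[map$mean_error_px]],
                    stringsAsFactors = FALSE)
  for (f in names(map$recode)) {
    rec <- map$recode[[f]]
    hit <- out[[f]] %in% names(rec)
    out[[f]][hit] <- rec[out[[f]][hit]]
  }
  for (f in names(canonical_levels)) {
    bad <- which(!out[[f]] %in% canonical_levels[[f]])
    if (length(bad)) {
      stop("unknown ", f, " level(s) ",
           paste(unique(out[[f]][bad]), collapse = ", "),
           " in row(s) ", paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  for (f in c("set_size", "mean_error_px")) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", f, " in row(s) ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    out[[f]] <- v
  }
  if (!is.null(map$is_practice) && map$is_practice %in% names(raw)) {
    out$is_practice <- as.logical(raw[[map$is_practice]])
    if (anyNA(out$is_practice)) {
      stop("unparseable practice flag in row(s) ",
           paste(utils::head(which(is.na(out$is_practice)), 10),
                 collapse = ", "))
    }
    if (drop_practice) {
      out <- out[!out$is_practice, , drop = FALSE]
      out$is_practice <- NULL
    }
  }
  message("read ", nrow(out), " trials from ",
          length(unique(out$participant)), " participants")
  rownames(out) <- NULL
  out
}

#' Write a trial table as CSV
#'
#' Round-trips bit-identically through [read_trials()] with the default
#' column map: numeric columns are written with 17 significant digits, which
#' is lossless for doubles.
#'
#' @param trials canonical trial data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
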