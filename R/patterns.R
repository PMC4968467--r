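#' Luminance pair for a contrast level
#'
#' The two-level stimuli use fixed dark/light luminances: the maximal-contrast
#' ("high") condition pairs 0.5 with 132.5 cd/m^2 and the lower-contrast
#' ("low") condition pairs 38 with 103 cd/m^2.  The nominal 100%/50% labels
#' are conventional; [michelson_contrast()] of the pairs is about 0.99 and
#' 0.46, and the luminances themselves are authoritative.
#'
#' @param contrast_level `"high"` or `"low"`.
#' @return An object of class `lum_pair`: list with numeric scalars `dark`
#'   and `light` (cd/m^2), `dark < light`.
#' @examples
#' lum_pair_for("high")
#' michelson_contrast(lum_pair_for("low"))
#' @export
lum_pair_for <- function(contrast_level) {
  pairs <- list(high = c(0.5, 132.5), low = c(38, 103))
  if (!is.character(contrast_level) || length(contrast_level) != 1L ||
      !contrast_level %in% names(pairs)) {
    stop("unknown contrast level: ", deparse(contrast_level),
         "; must be one of ", paste(sQuote(names(pairs)), collapse = ", "))
  }
  p <- pairs[[contrast_level]]
  lum_pair(p[1], p[2])
}

#' Construct a luminance pair
#'
#' @param dark,light luminances in cd/m^2; both positive, `dark < light`.
#' @return An object of class `lum_pair`.
#' @export
lum_pair <- function(dark, light) {
  stopifnot(is.numeric(dark), is.numeric(light),
            length(dark) == 1L, length(light) == 1L)
  if (!(dark > 0 && light > 0)) stop("luminances must be positive")
  if (!(dark < light)) stop("'dark' must be less than 'light'")
  structure(list(dark = dark, light = light), class = "lum_pair")
}

#' Michelson contrast of a luminance pair
#'
#' `(L_max - L_min) / (L_max + L_min)`.
#'
#' @param pair a [lum_pair()].
#' @return numeric scalar in (0, 1).
#' @export
michelson_contrast <- function(pair) {
  stopifnot(inherits(pair, "lum_pair"))
  (pair$light - pair$dark) / (pair$light + pair$dark)
}

#' Specify a square's surface pattern
#'
#' A square stimulus carries one of three colorations: a square-wave grating
#' with stripes parallel to its heading, a grating with stripes orthogonal to
#' its heading, or binary block noise.  Patterns are defined in the square's
#' object frame: the +x axis of the image is the heading axis, so "parallel"
#' stripes are elongated along +x and modulate along +y.
#'
#' @param kind `"parallel"`, `"orthogonal"` or `"binary"`.
#' @param contrast_level `"high"` or `"low"`; ignored if `lum_pair` given.
#' @param lum_pair optional [lum_pair()] overriding `contrast_level`.
#' @param wavelength_px grating spatial period in pixels (default 8: 4 px
#'   dark, 4 px light).
#' @param block_px binary-noise block side in pixels (default 4).
#' @param phase grating phase in degrees, 0 or 180; phase 180 is the
#'   complement image of phase 0.
#' @param size_px side of the square in pixels (default 32).
#' @return An object of class `pattern_spec`.
#' @seealso [render_pattern()]
#' @export
pattern_spec <- function(kind = c("parallel", "orthogonal", "binary"),
                         contrast_level = "high", lum_pair = NULL,
                         wavelength_px = 8, block_px = 4, phase = 0,
                         size_px = 32) {
  kind <- match.arg(kind)
  if (is.null(lum_pair)) lum_pair <- lum_pair_for(contrast_level)
  stopifnot(inherits(lum_pair, "lum_pair"))
  if (!phase %in% c(0, 180)) stop("phase must be 0 or 180 degrees")
  if (kind != "binary") {
    stopifnot(wavelength_px > 0, wavelength_px %% 2 == 0,
              size_px %% wavelength_px == 0)
  } else {
    stopifnot(block_px > 0, size_px %% block_px == 0)
  }
  structure(list(kind = kind, lum_pair = lum_pair,
                 wavelength_px = wavelength_px, block_px = block_px,
                 phase = phase, size_px = size_px),
            class = "pattern_spec")
}

#' Render a square-wave grating pattern
#'
#' Two-level square wave with the stated period (half dark, half light).
#' `"parallel"` stripes run along the heading (+x) axis, so luminance
#' modulates along +y (matrix rows); `"orthogonal"` modulates along +x
#' (matrix columns).  Phase 180 yields the pixel-wise complement of phase 0.
#'
#' @param spec a [pattern_spec()] with `kind` `"parallel"` or `"orthogonal"`.
#' @return A `size_px` x `size_px` numeric matrix of luminances (cd/m^2);
#'   rows index +y, columns index +x.
#' @export
render_grating <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind == "binary") {
    stop("render_grating() requires a grating spec; use render_binary_noise()")
  }
  half <- spec$wavelength_px / 2
  idx <- seq_len(spec$size_px) - 1L
  stripe <- (idx %/% half) %% 2  # 0 = dark band at phase 0
  if (spec$phase == 180) stripe <- 1 - stripe
  lums <- c(spec$lum_pair$dark, spec$lum_pair$light)
  band <- lums[stripe + 1L]
  if (spec$kind == "parallel") {
    matrix(band, spec$size_px, spec$size_px, byrow = FALSE)
  } else {
    matrix(band, spec$size_px, spec$size_px, byrow = TRUE)
  }
}

#' Render a binary block-noise pattern
#'
#' Each `block_px` x `block_px` block is independently dark or light with
#' probability 1/2.  Reproducible under `set.seed()`.
#'
#' @param spec a [pattern_spec()] with `kind = "binary"`.
#' @return A `size_px` x `size_px` numeric matrix of luminances (cd/m^2).
#' @export
render_binary_noise <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "binary") {
    stop("render_binary_noise() requires kind = 'binary'")
  }
  nb <- spec$size_px / spec$block_px
  lums <- c(spec$lum_pair$dark, spec$lum_pair$light)
  blocks <- matrix(lums[sample.int(2L, nb * nb, replace = TRUE)], nb, nb)
  kronecker(blocks, matrix(1, spec$block_px, spec$block_px))
}

#' Render any pattern spec
#'
#' Dispatches to [render_grating()] or [render_binary_noise()].
#'
#' @inheritParams render_grating
#' @return A luminance matrix; see the specific renderers.
#' @export
render_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind == "binary") render_binary_noise(spec) else render_grating(spec)
}

#' Export a pattern image
#'
#' Writes the luminance grid as plain CSV (no header, one row per +y index),
#' or as a greyscale PNG scaled by the maximum display luminance 132.5 cd/m^2
#' (requires the `png` package).
#'
#' @param img luminance matrix from [render_pattern()].
#' @param path output file; format chosen by extension (`.csv` or `.png`).
#' @return `path`, invisibly.
#' @export
write_pattern <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG export requires the 'png' package")
    }
    png::writePNG(pmin(img / 132.5, 1), path)
  } else {
    stop("unsupported extension: ", ext)
  }
  invisible(path)
}
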