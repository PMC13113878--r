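#' Single-channel fluorescence image
#'
#' A `channel_image` bundles one 2D grid of non-negative fluorescence
#' intensities (arbitrary units) with its pixel geometry. Areas reported
#' anywhere in the package are `pixel count * pixel_size^2` in square
#' micrometres.
#'
#' @param pixels Numeric matrix of intensities, all values >= 0.
#' @param pixel_size Pixel side length in micrometres (> 0).
#' @param channel_label Channel role, one of `"DAPI"`, `"G3BP1"`,
#'   `"p-eIF2a"`, `"TIA1"`.
#' @return An object of class `channel_image` with fields `pixels`,
#'   `pixel_size` and `channel_label`.
#' @examples
#' ch <- channel_image(matrix(0, 8, 8), pixel_size = 0.1, channel_label = "DAPI")
#' dim(ch$pixels)
#' @export
channel_image <- function(pixels, pixel_size,
                          channel_label = c("DAPI", "G3BP1", "p-eIF2a", "TIA1")) {
  channel_label <- match.arg(channel_label)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("all pixel intensities must be finite and >= 0")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number (um per pixel)")
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         channel_label = channel_label),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px, %.3g um/px (%.1f x %.1f um)\n",
              x$channel_label, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              nrow(x$pixels) * x$pixel_size, ncol(x$pixels) * x$pixel_size))
  invisible(x)
}

#' Multi-channel region of interest
#'
#' One confocal field ("ROI"), treated throughout as one biological
#' sample: a named list of channels plus condition metadata (smoke-extract
#' concentration as percent of the 100% stock, exposure time in hours, and
#' optional pretreatment label).
#'
#' @param channels Named list of [channel_image] objects; names are channel
#'   roles. All channels must share dimensions and pixel size.
#' @param condition List with elements `extract_pct`, `exposure_h` and
#'   optionally `pretreatment`.
#' @param id Optional ROI identifier.
#' @return An object of class `roi_record`.
#' @export
roi_record <- function(channels, condition = list(), id = NULL) {
  if (!length(channels) || !all(vapply(channels, inherits, TRUE, "channel_image"))) {
    stop("'channels' must be a non-empty named list of channel_image objects")
  }
  dims <- lapply(channels, function(ch) dim(ch$pixels))
  ps <- vapply(channels, function(ch) ch$pixel_size, 0)
  if (length(unique(dims)) != 1L || length(unique(ps)) != 1L) {
    stop("all channels in an ROI must share dimensions and pixel size")
  }
  structure(list(channels = channels, condition = condition, id = id),
            class = "roi_record")
}

#' @export
print.roi_record <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("<roi_record>%s channels: %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(cond$extract_pct)) {
    cat(sprintf("  condition: %g%% extract, %g h%s\n", cond$extract_pct,
                cond$exposure_h %||% NA,
                if (is.null(cond$pretreatment)) "" else paste0(", ", cond$pretreatment)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared geometry check used by segmentation/quantification entry points
check_same_geometry <- function(a_pix, a_ps, b_pix, b_ps, what = "inputs") {
  if (!identical(dim(a_pix), dim(b_pix)) || !isTRUE(all.equal(a_ps, b_ps))) {
    stop(sprintf("%s do not share geometry (dims %s vs %s, pixel size %g vs %g)",
                 what, paste(dim(a_pix), collapse = "x"),
                 paste(dim(b_pix), collapse = "x"), a_ps, b_ps))
  }
  invisible(TRUE)
}
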