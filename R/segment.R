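#' @title Nucleus and granule segmentation
#' @name segmentation
#' @keywords internal
NULL

# Otsu threshold on an intensity vector/matrix in native units.
otsu_threshold <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(0)
  EBImage::otsu(EBImage::Image(as.numeric(x) / mx), range = c(0, 1)) * mx
}

# Drop labelled components whose pixel count is below min_px, relabel 1..n.
filter_small <- function(labels, min_px) {
  if (max(labels) == 0L) return(labels)
  counts <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(counts >= min_px)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

#' Segment nuclei from the DAPI channel
#'
#' Binary-thresholds the DAPI channel, fills holes, removes components
#' smaller than `min_nucleus_area`, and labels the remaining nuclei. A
#' constant image (zero dynamic range) carries no nuclear information and
#' yields zero nuclei with a warning.
#'
#' @param dapi A [channel_image] (DAPI role).
#' @param min_nucleus_area Minimum nucleus area in um^2 (default 10).
#' @param threshold `"otsu"` (default, computed on the whole frame) or an
#'   absolute intensity value.
#' @return An object of class `nucleus_mask`: `labels` (integer matrix,
#'   0 = non-nucleus), `nucleus_count`, `nuclear_area` (um^2), per-nucleus
#'   `areas` and the `pixel_size`.
#' @export
segment_nuclei <- function(dapi, min_nucleus_area = 10, threshold = "otsu") {
  stopifnot(inherits(dapi, "channel_image"))
  px <- dapi$pixels; ps <- dapi$pixel_size
  if (diff(range(px)) == 0) {
    warning("DAPI channel has zero dynamic range; returning 0 nuclei")
    labels <- matrix(0L, nrow(px), ncol(px))
    return(new_nucleus_mask(labels, ps))
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(px) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  mask <- px > thr
  mask <- EBImage::imageData(EBImage::fillHull(mask)) > 0
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  labels <- filter_small(labels, ceiling(min_nucleus_area / ps^2))
  new_nucleus_mask(labels, ps, threshold = thr)
}

new_nucleus_mask <- function(labels, pixel_size, threshold = NA_real_) {
  n <- max(labels)
  counts <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer()
  structure(
    list(labels = labels, nucleus_count = as.integer(n),
         nuclear_area = sum(counts) * pixel_size^2,
         areas = counts * pixel_size^2,
         pixel_size = pixel_size, threshold = threshold),
    class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d nuclei, %.1f um2 nuclear area (threshold %.4g)\n",
              x$nucleus_count, x$nuclear_area, x$threshold))
  invisible(x)
}

#' Segment granules from a marker channel
#'
#' Thresholds the marker channel, restricts the foreground to the
#' non-nuclear (cytoplasmic) area, removes components smaller than
#' `min_granule_area`, and optionally splits touching granules by a
#' watershed on the Euclidean distance transform.
#'
#' The default threshold is Otsu computed on the cytoplasmic pixels only,
#' with an additional robust floor: foreground must also exceed the
#' cytoplasmic `median + k_mad * MAD`. The floor makes vehicle-condition
#' images (diffuse signal only, no granules) yield zero granules instead
#' of splitting the noise distribution in half. A fixed absolute threshold
#' may be supplied instead to reproduce a manually chosen ("semi-
#' automated") cutoff; a threshold above the image maximum simply yields
#' zero granules.
#'
#' @param marker A [channel_image] for the granule marker (e.g. G3BP1).
#' @param nucleus_mask A `nucleus_mask` from [segment_nuclei()], or `NULL`
#'   to treat the whole frame as cytoplasm. Must share geometry with
#'   `marker`.
#' @param min_granule_area Minimum granule area in um^2 (default 0.04,
#'   i.e. 4 pixels at 0.1 um).
#' @param threshold `"otsu"` (default) or an absolute intensity value.
#' @param k_mad Robust-floor multiplier (default 5); only used with the
#'   Otsu method.
#' @param min_peak_separation Minimum separation of distance-transform
#'   peaks in um for the watershed (default 0.3, below the radius of the
#'   smallest condition-mean granules).
#' @param watershed Logical; `FALSE` labels plain connected components
#'   (touching granules merge).
#' @param ws_tolerance Watershed depth tolerance in distance-map pixels
#'   (default 0.5): neighbouring peaks shallower than this merge, which
#'   keeps single digitised disks intact.
#' @return An object of class `granule_labels`: `labels` (integer matrix,
#'   0 = background), `granule_count`, `border` flag per granule (touches
#'   the frame edge; border granules are kept), the applied `threshold`
#'   and the `pixel_size`.
#' @export
segment_granules <- function(marker, nucleus_mask = NULL,
                             min_granule_area = 0.04, threshold = "otsu",
                             k_mad = 5, min_peak_separation = 0.3,
                             watershed = TRUE, ws_tolerance = 0.5) {
  stopifnot(inherits(marker, "channel_image"))
  px <- marker$pixels; ps <- marker$pixel_size
  if (is.null(nucleus_mask)) {
    nuc <- matrix(0L, nrow(px), ncol(px))
  } else {
    stopifnot(inherits(nucleus_mask, "nucleus_mask"))
    check_same_geometry(px, ps, nucleus_mask$labels, nucleus_mask$pixel_size,
                        "marker channel and nucleus mask")
    nuc <- nucleus_mask$labels
  }
  cyto <- nuc == 0L
  cyto_px <- px[cyto]
  if (!length(cyto_px)) stop("no cytoplasmic pixels (all-nuclear mask)")

  thr <- if (identical(threshold, "otsu")) {
    max(otsu_threshold(cyto_px),
        stats::median(cyto_px) + k_mad * stats::mad(cyto_px))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }

  mask <- (px > thr) & cyto
  min_px <- ceiling(min_granule_area / ps^2)
  if (!any(mask)) {
    return(new_granule_labels(matrix(0L, nrow(px), ncol(px)), ps, thr))
  }
  if (watershed) {
    dm <- EBImage::distmap(mask)
    ext <- max(1L, as.integer(round(min_peak_separation / ps)))
    labels <- EBImage::imageData(
      EBImage::watershed(dm, tolerance = ws_tolerance, ext = ext))
  } else {
    labels <- EBImage::imageData(EBImage::bwlabel(mask))
  }
  storage.mode(labels) <- "integer"
  labels <- filter_small(labels, min_px)
  new_granule_labels(labels, ps, thr)
}

new_granule_labels <- function(labels, pixel_size, threshold = NA_real_) {
  n <- max(labels)
  border <- logical(n)
  if (n > 0) {
    edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)])
    border[unique(edge[edge > 0L])] <- TRUE
  }
  structure(
    list(labels = labels, granule_count = as.integer(n), border = border,
         pixel_size = pixel_size, threshold = threshold),
    class = "granule_labels")
}

#' @export
print.granule_labels <- function(x, ...) {
  cat(sprintf("<granule_labels> %d granules (%d at frame border), threshold %.4g\n",
              x$granule_count, sum(x$border), x$threshold))
  invisible(x)
}
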