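#' @title Synthetic confocal ROI generator
#' @description Internal helpers plus [generate_roi()], the entry point of
#'   the synthetic-imaging module.
#' @name simulate
#' @keywords internal
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Rasterise one ellipse into an integer label matrix (pixel centres at
# (i - 0.5) * ps). Returns updated matrix and the painted pixel count.
paint_ellipse <- function(labels, k, cx, cy, a, b, theta, ps) {
  nr <- nrow(labels); nc <- ncol(labels)
  r <- max(a, b)
  i0 <- max(1L, floor((cx - r) / ps)); i1 <- min(nr, ceiling((cx + r) / ps) + 1L)
  j0 <- max(1L, floor((cy - r) / ps)); j1 <- min(nc, ceiling((cy + r) / ps) + 1L)
  if (i0 > i1 || j0 > j1) return(list(labels = labels, n = 0L))
  ii <- i0:i1; jj <- j0:j1
  dx <- (ii - 0.5) * ps - cx
  dy <- (jj - 0.5) * ps - cy
  DX <- matrix(dx, length(ii), length(jj))
  DY <- matrix(dy, length(ii), length(jj), byrow = TRUE)
  rx <- DX * cos(theta) + DY * sin(theta)
  ry <- -DX * sin(theta) + DY * cos(theta)
  inside <- (rx / a)^2 + (ry / b)^2 <= 1
  sub <- labels[ii, jj, drop = FALSE]
  sub[inside] <- k
  labels[ii, jj] <- sub
  list(labels = labels, n = sum(inside))
}

paint_disk <- function(labels, k, cx, cy, r, ps) {
  paint_ellipse(labels, k, cx, cy, r, r, 0, ps)
}

#' Generate one synthetic confocal ROI with known ground truth
#'
#' Renders a two-channel region of interest emulating a confocal field
#' fully occupied by epithelial cells: a DAPI channel with bright,
#' non-overlapping elliptical nuclei on a dark background, and a marker
#' channel (e.g. G3BP1 or p-eIF2a) composed of a constant additive
#' background everywhere (autofluorescence plus nonspecific binding), a
#' diffuse cytoplasmic level restricted to the non-nuclear area, and
#' planted granules rendered as hard disks of uniform extra amplitude so
#' the planted area and intensity are exact. The number of granules is
#' drawn from a zero-truncated Poisson with the preset mean (or is zero
#' when the condition fails to form granules); the drawn count, every
#' planted object and all level parameters are recorded exactly in the
#' returned ground truth.
#'
#' Noise is photon-like Poisson on the total signal followed by additive
#' Gaussian read noise, after which intensities are rounded to integers
#' and clipped to the 16-bit range. An optional Gaussian point-spread blur
#' can be applied to the noise-free images first.
#'
#' @param preset A [condition_preset] (see [sg_preset()]).
#' @param seed Integer seed; fully determines the output.
#' @param width,height Image size in pixels (default 1024 x 1024).
#' @param pixel_size Pixel size in um (default 0.1; 0.06 emulates the
#'   higher-sampling instrument setting).
#' @param marker_label Role of the marker channel (`"G3BP1"` default).
#' @param diffuse_vehicle_level Diffuse cytoplasmic marker level under
#'   vehicle, arbitrary units (default 100). The condition's diffuse level
#'   is this times `preset$cyto_fold_vs_vehicle`.
#' @param background_fraction Fraction of the vehicle-condition mean
#'   cytoplasmic signal contributed by the constant background (default
#'   0.45, the measured autofluorescence + nonspecific-binding fraction).
#'   The background level solves `bg / (diffuse_vehicle + bg) = fraction`.
#' @param granule_contrast Granule amplitude as a multiple of the
#'   condition's diffuse cytoplasmic level (default 3; not constrained by
#'   any reported measurement, exposed as a free parameter).
#' @param granule_area_cv Coefficient of variation of the lognormal
#'   per-granule area distribution (default 0.25); the distribution mean
#'   equals the preset's `mean_granule_area`.
#' @param nucleus_axis_range Range of ellipse semi-axes in um (default
#'   `c(2.5, 4.5)`, epithelial-monolayer scale).
#' @param nucleus_fill_range Target range for the nuclear area fraction of
#'   the frame (default `c(0.15, 0.25)`).
#' @param dapi_amplitude Mean nuclear DAPI amplitude, a.u. (default 800);
#'   per-nucleus amplitudes vary uniformly within +/- 15%.
#' @param noise Logical; `FALSE` returns the noise-free images.
#' @param gaussian_sd Read-noise standard deviation in a.u.; default 2% of
#'   the channel's main signal level.
#' @param psf_sigma Gaussian point-spread sigma in um (default 0 = off).
#' @return A list with elements `roi` (an [roi_record] with `DAPI` and
#'   marker channels) and `truth` (a `ground_truth` object recording every
#'   planted nucleus and granule, the level and noise parameters, the seed
#'   and the nucleus/granule label images).
#' @examples
#' sim <- generate_roi(sg_preset(15, 2), seed = 1, width = 256, height = 256)
#' sim$truth$granule_count
#' @export
generate_roi <- function(preset, seed, width = 1024, height = width,
                         pixel_size = 0.1, marker_label = "G3BP1",
                         diffuse_vehicle_level = 100,
                         background_fraction = 0.45,
                         granule_contrast = 3, granule_area_cv = 0.25,
                         nucleus_axis_range = c(2.5, 4.5),
                         nucleus_fill_range = c(0.15, 0.25),
                         dapi_amplitude = 800,
                         noise = TRUE, gaussian_sd = NULL, psf_sigma = 0) {
  if (!inherits(preset, "condition_preset")) stop("'preset' must be a condition_preset")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' must be a single integer")
  }
  if (width <= 0 || height <= 0 || pixel_size <= 0) {
    stop("image size and pixel_size must be positive")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("'background_fraction' must lie in [0, 1)")
  }
  width <- as.integer(width); height <- as.integer(height)
  ps <- pixel_size
  W <- width * ps; H <- height * ps

  with_seed(seed, {
    ## ---- nuclei: non-overlapping ellipses tiling 15-25% of the frame ----
    nuc_labels <- matrix(0L, width, height)
    target_frac <- stats::runif(1, nucleus_fill_range[1], nucleus_fill_range[2])
    target_px <- target_frac * width * height
    nuc <- list(); painted <- 0; attempts <- 0L
    # a frame smaller than the smallest nucleus stays nucleus-free
    can_fit <- 2 * nucleus_axis_range[1] < min(W, H)
    while (can_fit && painted < target_px && attempts < 50000L) {
      attempts <- attempts + 1L
      a <- stats::runif(1, nucleus_axis_range[1], nucleus_axis_range[2])
      b <- stats::runif(1, nucleus_axis_range[1], nucleus_axis_range[2])
      th <- stats::runif(1, 0, pi)
      amax <- max(a, b)
      if (2 * amax >= min(W, H)) next
      cx <- stats::runif(1, amax, W - amax)
      cy <- stats::runif(1, amax, H - amax)
      if (length(nuc)) {
        prev <- do.call(rbind, lapply(nuc, function(n) c(n$cx, n$cy, max(n$a, n$b))))
        d <- sqrt((prev[, 1] - cx)^2 + (prev[, 2] - cy)^2)
        if (any(d < prev[, 3] + amax + 0.2)) next
      }
      k <- length(nuc) + 1L
      res <- paint_ellipse(nuc_labels, k, cx, cy, a, b, th, ps)
      nuc_labels <- res$labels
      amp <- dapi_amplitude * stats::runif(1, 0.85, 1.15)
      nuc[[k]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th,
                       amplitude = amp, pixel_count = res$n)
      painted <- painted + res$n
    }
    nuclei_df <- if (length(nuc)) {
      data.frame(id = seq_along(nuc),
                 cx_um = vapply(nuc, `[[`, 0, "cx"),
                 cy_um = vapply(nuc, `[[`, 0, "cy"),
                 semi_a_um = vapply(nuc, `[[`, 0, "a"),
                 semi_b_um = vapply(nuc, `[[`, 0, "b"),
                 theta = vapply(nuc, `[[`, 0, "theta"),
                 amplitude = vapply(nuc, `[[`, 0, "amplitude"),
                 pixel_count = vapply(nuc, function(n) as.numeric(n$pixel_count), 0))
    } else {
      data.frame(id = integer(), cx_um = numeric(), cy_um = numeric(),
                 semi_a_um = numeric(), semi_b_um = numeric(), theta = numeric(),
                 amplitude = numeric(), pixel_count = numeric())
    }

    ## ---- granule count and geometry ----
    diffuse <- diffuse_vehicle_level * preset$cyto_fold_vs_vehicle
    bg <- background_fraction / (1 - background_fraction) * diffuse_vehicle_level
    amp_gran <- granule_contrast * diffuse

    n_gran <- 0L
    if (preset$mean_granule_count > 0 &&
        stats::runif(1) < preset$formation_probability) {
      n_gran <- stats::rpois(1, preset$mean_granule_count)
      while (n_gran == 0L) n_gran <- stats::rpois(1, preset$mean_granule_count)
    }

    gran_labels <- matrix(0L, width, height)
    gran <- list()
    if (n_gran > 0L) {
      cv <- granule_area_cv
      areas <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        stats::rlnorm(n_gran, log(preset$mean_granule_area) - sdl^2 / 2, sdl)
      } else rep(preset$mean_granule_area, n_gran)
      radii <- pmax(sqrt(areas / pi), 1.5 * ps)  # um
      placed_cx <- numeric(0); placed_cy <- numeric(0); placed_r <- numeric(0)
      for (g in seq_len(n_gran)) {
        r <- radii[g]; ok <- FALSE
        for (try in seq_len(10000L)) {
          cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
          # disk must stay clear of every nucleus (Minkowski-grown ellipse test)
          if (nrow(nuclei_df)) {
            dx <- cx - nuclei_df$cx_um; dy <- cy - nuclei_df$cy_um
            rx <- dx * cos(nuclei_df$theta) + dy * sin(nuclei_df$theta)
            ry <- -dx * sin(nuclei_df$theta) + dy * cos(nuclei_df$theta)
            if (any((rx / (nuclei_df$semi_a_um + r))^2 +
                    (ry / (nuclei_df$semi_b_um + r))^2 <= 1)) next
          }
          # keep centres one summed radius apart so planted disks never touch
          if (length(placed_cx)) {
            d <- sqrt((placed_cx - cx)^2 + (placed_cy - cy)^2)
            if (any(d < placed_r + r + 2 * ps)) next
          }
          ok <- TRUE; break
        }
        if (!ok) {
          warning(sprintf("could only place %d of %d granules; frame too crowded",
                          g - 1L, n_gran))
          break
        }
        k <- length(gran) + 1L
        res <- paint_disk(gran_labels, k, cx, cy, r, ps)
        gran_labels <- res$labels
        border <- (cx - r < ps) || (cy - r < ps) || (cx + r > W - ps) || (cy + r > H - ps)
        gran[[k]] <- list(cx = cx, cy = cy, r = r, amplitude = amp_gran,
                          pixel_count = res$n, border = border)
        placed_cx <- c(placed_cx, cx); placed_cy <- c(placed_cy, cy)
        placed_r <- c(placed_r, r)
      }
      n_gran <- length(gran)
    }
    granules_df <- if (length(gran)) {
      data.frame(id = seq_along(gran),
                 cx_um = vapply(gran, `[[`, 0, "cx"),
                 cy_um = vapply(gran, `[[`, 0, "cy"),
                 radius_um = vapply(gran, `[[`, 0, "r"),
                 amplitude = vapply(gran, `[[`, 0, "amplitude"),
                 pixel_count = vapply(gran, function(g) as.numeric(g$pixel_count), 0),
                 border = vapply(gran, `[[`, TRUE, "border"))
    } else {
      data.frame(id = integer(), cx_um = numeric(), cy_um = numeric(),
                 radius_um = numeric(), amplitude = numeric(),
                 pixel_count = numeric(), border = logical())
    }

    ## ---- render noise-free channels ----
    cyto <- nuc_labels == 0L
    marker <- matrix(bg, width, height)
    marker[cyto] <- marker[cyto] + diffuse
    in_gran <- gran_labels > 0L
    if (any(in_gran)) marker[in_gran] <- marker[in_gran] + amp_gran
    dapi <- matrix(0, width, height)
    for (k in seq_len(nrow(nuclei_df))) {
      dapi[nuc_labels == k] <- nuclei_df$amplitude[k]
    }

    if (psf_sigma > 0) {
      sp <- psf_sigma / ps
      marker <- EBImage::imageData(EBImage::gblur(marker, sigma = sp))
      dapi <- EBImage::imageData(EBImage::gblur(dapi, sigma = sp))
      marker[marker < 0] <- 0; dapi[dapi < 0] <- 0
    }

    sd_marker <- gaussian_sd %||% (0.02 * diffuse)
    sd_dapi <- gaussian_sd %||% (0.02 * dapi_amplitude)
    if (noise) {
      marker <- stats::rpois(length(marker), lambda = marker) +
        stats::rnorm(length(marker), 0, sd_marker)
      dapi <- stats::rpois(length(dapi), lambda = dapi) +
        stats::rnorm(length(dapi), 0, sd_dapi)
      marker <- matrix(pmin(pmax(round(marker), 0), 65535), width, height)
      dapi <- matrix(pmin(pmax(round(dapi), 0), 65535), width, height)
    }

    roi <- roi_record(
      channels = stats::setNames(
        list(channel_image(dapi, ps, "DAPI"),
             channel_image(marker, ps, marker_label)),
        c("DAPI", marker_label)),
      condition = list(extract_pct = preset$extract_pct,
                       exposure_h = preset$exposure_h),
      id = sprintf("sim_%g_%g_seed%d", preset$extract_pct, preset$exposure_h,
                   as.integer(seed)))

    truth <- structure(
      list(nuclei = nuclei_df, granules = granules_df,
           granule_count = n_gran,
           diffuse_cyto_level = diffuse,
           diffuse_vehicle_level = diffuse_vehicle_level,
           background_level = bg,
           granule_amplitude = amp_gran,
           noise = list(poisson_on = noise, gaussian_sd_marker = sd_marker,
                        gaussian_sd_dapi = sd_dapi),
           psf_sigma = psf_sigma, seed = as.integer(seed),
           pixel_size = ps, dim = c(width, height),
           nuclear_pixel_count = sum(!cyto),
           cyto_pixel_count = sum(cyto),
           nucleus_labels = nuc_labels, granule_labels = gran_labels,
           preset = preset),
      class = "ground_truth")

    list(roi = roi, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> seed %d: %d nuclei (%.1f%% of frame), %d granules, diffuse %.4g, background %.4g\n",
    x$seed, nrow(x$nuclei), 100 * x$nuclear_pixel_count / prod(x$dim),
    x$granule_count, x$diffuse_cyto_level, x$background_level))
  invisible(x)
}

#' Analytic integral of the noise-free marker channel
#'
#' Bookkeeping check for the generator: the sum of the noise-free marker
#' image equals background over the whole frame, plus the diffuse level
#' over the cytoplasmic pixels, plus each granule's amplitude times its
#' planted pixel count.
#'
#' @param truth A `ground_truth` from [generate_roi()].
#' @return The analytic total intensity (a.u.).
#' @export
truth_marker_integral <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$background_level * prod(truth$dim) +
    truth$diffuse_cyto_level * truth$cyto_pixel_count +
    sum(truth$granules$amplitude * truth$granules$pixel_count)
}
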