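#' @title Smoke-extract dose arithmetic
#' @description The exposure model: the biologically effective quantity is
#'   the volume of 100% smoke extract each cell receives. Comparable
#'   stress-granule formation across plating formats requires this
#'   dose per cell to remain constant.
#' @name dose_model
#' @keywords internal
NULL

#' Exposure specification
#'
#' @param extract_pct Percent of the 100% extract stock in the final
#'   medium, in `[0, 100]`.
#' @param total_volume_ul Final medium volume in uL (> 0).
#' @param n_cells Number of exposed cells (> 0).
#' @param od_320 Optional measured optical density of the stock at 320 nm.
#' @param reference_od Optical density defining the 100% stock (default
#'   0.65 at 320 nm).
#' @return Object of class `dose_spec`.
#' @examples
#' dose_spec(15, 1000, 1.5e5)
#' @export
dose_spec <- function(extract_pct, total_volume_ul, n_cells,
                      od_320 = NULL, reference_od = 0.65) {
  stopifnot(is.numeric(extract_pct), extract_pct >= 0, extract_pct <= 100,
            is.numeric(total_volume_ul), total_volume_ul > 0,
            is.numeric(n_cells), n_cells > 0)
  structure(list(extract_pct = extract_pct, total_volume_ul = total_volume_ul,
                 n_cells = n_cells, od_320 = od_320,
                 reference_od = reference_od),
            class = "dose_spec")
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf("<dose_spec> %g%% extract in %g uL over %.3g cells -> %.3g uL/cell\n",
              x$extract_pct, x$total_volume_ul, x$n_cells, dose_per_cell(x)))
  invisible(x)
}

#' Extract concentration from optical density
#'
#' The extract stock is calibrated spectrophotometrically: an optical
#' density of `reference_od` (default 0.65) at 320 nm defines 100%.
#' Stocks denser than the reference read above 100%.
#'
#' @param od_320 Measured optical density at 320 nm (>= 0).
#' @param reference_od Optical density defining 100% (> 0, default 0.65).
#' @return Concentration in percent of the reference stock.
#' @examples
#' concentration_from_od(0.65)        # 100
#' concentration_from_od(1.2)         # 184.6
#' @export
concentration_from_od <- function(od_320, reference_od = 0.65) {
  stopifnot(is.numeric(od_320), is.numeric(reference_od), reference_od > 0)
  if (any(od_320 < 0)) stop("optical density must be >= 0")
  od_320 / reference_od * 100
}

#' Volume of 100% extract per cell
#'
#' @param x A [dose_spec], or the extract concentration in percent if the
#'   remaining arguments are given.
#' @param total_volume_ul,n_cells Medium volume (uL) and cell count, used
#'   when `x` is a plain percentage.
#' @return Dose in uL of 100% extract per cell.
#' @examples
#' dose_per_cell(15, 1000, 1.5e5)   # 1e-3 uL/cell (in-dish exposure)
#' dose_per_cell(100, 1e4, 5e7)     # 2e-4 uL/cell (one smoked cigarette)
#' @export
dose_per_cell <- function(x, total_volume_ul = NULL, n_cells = NULL) {
  if (inherits(x, "dose_spec")) {
    spec <- x
  } else {
    spec <- dose_spec(x, total_volume_ul, n_cells)
  }
  (spec$extract_pct / 100) * spec$total_volume_ul / spec$n_cells
}

#' Ratio of two per-cell doses
#'
#' @param a,b [dose_spec] objects with positive doses.
#' @return Unitless fold `dose_per_cell(a) / dose_per_cell(b)`.
#' @examples
#' # cultured-dish exposure vs one cigarette over the airway epithelium: ~5x
#' dose_ratio(dose_spec(15, 1000, 1.5e5), dose_spec(100, 1e4, 5e7))
#' @export
dose_ratio <- function(a, b) {
  stopifnot(inherits(a, "dose_spec"), inherits(b, "dose_spec"))
  da <- dose_per_cell(a); db <- dose_per_cell(b)
  if (da <= 0 || db <= 0) stop("both doses must be positive")
  da / db
}

#' Rescale an exposure to a new cell count at constant dose per cell
#'
#' Solves the free variable (extract percentage or medium volume) so that
#' the per-cell dose of the reference exposure is preserved for a new cell
#' count. Doubling the cells at fixed volume doubles the required extract
#' percentage; at fixed percentage it doubles the required volume.
#'
#' @param reference A [dose_spec] with positive dose.
#' @param n_cells_new New cell count (> 0).
#' @param fix Which variable to hold fixed: `"volume"` solves for the
#'   extract percentage (error above 100%, where volume scaling is the
#'   only option), `"pct"` solves for the medium volume.
#' @return A new `dose_spec` with identical dose per cell.
#' @examples
#' m <- match_exposure(dose_spec(15, 1000, 1.5e5), 3e5, fix = "volume")
#' m$extract_pct  # 30
#' @export
match_exposure <- function(reference, n_cells_new, fix = c("volume", "pct")) {
  stopifnot(inherits(reference, "dose_spec"),
            is.numeric(n_cells_new), n_cells_new > 0)
  fix <- match.arg(fix)
  if (dose_per_cell(reference) <= 0) stop("reference dose must be positive")
  scale <- n_cells_new / reference$n_cells
  if (fix == "volume") {
    pct <- reference$extract_pct * scale
    if (pct > 100) {
      stop(sprintf(
        "matching would require %.1f%% extract (> 100%%); scale the medium volume instead (fix = \"pct\")",
        pct))
    }
    dose_spec(pct, reference$total_volume_ul, n_cells_new,
              reference$od_320, reference$reference_od)
  } else {
    dose_spec(reference$extract_pct, reference$total_volume_ul * scale,
              n_cells_new, reference$od_320, reference$reference_od)
  }
}

#' Exposure spec from an extract volume
#'
#' Convenience constructor when the pipetted volume of 100% extract is
#' known instead of the final percentage (e.g. 150 uL of stock into a
#' 1000 uL dish gives 15%).
#'
#' @param extract_ul Volume of 100% extract added (uL).
#' @param total_volume_ul Final medium volume (uL).
#' @param n_cells Number of exposed cells.
#' @return A [dose_spec].
#' @export
dose_spec_from_extract_volume <- function(extract_ul, total_volume_ul, n_cells) {
  stopifnot(extract_ul >= 0, extract_ul <= total_volume_ul)
  dose_spec(extract_ul / total_volume_ul * 100, total_volume_ul, n_cells)
}
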