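#' @title Per-granule, per-ROI and cytoplasmic fluorescence metrics
#' @name quantification
#' @keywords internal
NULL

#' Cluster analysis: per-granule table and ROI summary
#'
#' Computes, for every labelled granule, its pixel count, area in um^2,
#' mean and cumulative (integrated) marker fluorescence and centroid, and
#' aggregates them into the ROI-level cluster summary: granule count, mean
#' granule area, the mean marker fluorescence per granule averaged over
#' granules (unweighted mean of per-granule means), the mean cumulative
#' fluorescence per granule, and the total cumulative fluorescence over
#' all granules (the total marker signal sequestered in granules).
#'
#' @param marker A [channel_image].
#' @param granules A `granule_labels` from [segment_granules()]; must
#'   share geometry with `marker`.
#' @return A list with `table` (one row per granule: `id`, `pixel_count`,
#'   `area_um2`, `mean_intensity`, `cumulative_intensity`, `centroid_row`,
#'   `centroid_col`, `border`) and `summary` (one-row data frame:
#'   `sg_count`, `mean_sg_area`, `mean_of_mean_intensity`,
#'   `mean_cumulative_per_sg`, `total_cumulative_sg`). An empty label
#'   image yields a summary of zeros.
#' @export
cluster_metrics <- function(marker, granules) {
  stopifnot(inherits(marker, "channel_image"), inherits(granules, "granule_labels"))
  check_same_geometry(marker$pixels, marker$pixel_size,
                      granules$labels, granules$pixel_size,
                      "marker channel and granule labels")
  ps <- marker$pixel_size
  lab <- granules$labels
  n <- granules$granule_count
  if (n == 0L) {
    tab <- data.frame(id = integer(), pixel_count = numeric(),
                      area_um2 = numeric(), mean_intensity = numeric(),
                      cumulative_intensity = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      border = logical())
    summ <- data.frame(sg_count = 0L, mean_sg_area = 0,
                       mean_of_mean_intensity = 0, mean_cumulative_per_sg = 0,
                       total_cumulative_sg = 0)
    return(list(table = tab, summary = summ))
  }
  pos <- lab > 0L
  l <- lab[pos]
  v <- marker$pixels[pos]
  counts <- tabulate(l, nbins = n)
  sums <- as.numeric(rowsum(v, l, reorder = TRUE))
  rows <- as.numeric(rowsum(row(lab)[pos], l, reorder = TRUE)) / counts
  cols <- as.numeric(rowsum(col(lab)[pos], l, reorder = TRUE)) / counts
  tab <- data.frame(id = seq_len(n), pixel_count = counts,
                    area_um2 = counts * ps^2,
                    mean_intensity = sums / counts,
                    cumulative_intensity = sums,
                    centroid_row = rows, centroid_col = cols,
                    border = granules$border)
  summ <- data.frame(sg_count = n,
                     mean_sg_area = mean(tab$area_um2),
                     mean_of_mean_intensity = mean(tab$mean_intensity),
                     mean_cumulative_per_sg = mean(tab$cumulative_intensity),
                     total_cumulative_sg = sum(tab$cumulative_intensity))
  list(table = tab, summary = summ)
}

#' Nucleus-based analysis: nuclear/cytoplasmic intensity segregation
#'
#' Segregates the marker fluorescence of an ROI into nuclear and
#' cytoplasmic compartments using the nucleus mask: the cytoplasmic
#' cumulative intensity is the total cumulative intensity minus the summed
#' nuclear contribution (an exact identity), and the mean cytoplasmic
#' intensity is the cytoplasmic cumulative intensity divided by the
#' cytoplasmic area in um^2. The ROI is assumed fully occupied by cells,
#' so all non-nuclear area counts as cytoplasm.
#'
#' @param marker A [channel_image].
#' @param nuclei A `nucleus_mask`; must share geometry with `marker`. An
#'   all-nuclear mask (zero cytoplasmic area) is an error.
#' @return An object of class `cytoplasm_quant`: `total_cumulative`,
#'   `nuclear_cumulative`, `cytoplasmic_cumulative`, `cytoplasmic_area`
#'   (um^2) and `mean_cytoplasmic` (a.u. per um^2).
#' @export
nucleus_based_metrics <- function(marker, nuclei) {
  stopifnot(inherits(marker, "channel_image"), inherits(nuclei, "nucleus_mask"))
  check_same_geometry(marker$pixels, marker$pixel_size,
                      nuclei$labels, nuclei$pixel_size,
                      "marker channel and nucleus mask")
  ps <- marker$pixel_size
  nuc <- nuclei$labels > 0L
  n_cyto <- sum(!nuc)
  if (n_cyto == 0L) stop("cytoplasmic area is zero (all-nuclear mask)")
  total <- sum(marker$pixels)
  nuclear <- sum(marker$pixels[nuc])
  cyto <- total - nuclear
  area <- n_cyto * ps^2
  structure(
    list(total_cumulative = total, nuclear_cumulative = nuclear,
         cytoplasmic_cumulative = cyto, cytoplasmic_area = area,
         mean_cytoplasmic = cyto / area),
    class = "cytoplasm_quant")
}

#' @export
print.cytoplasm_quant <- function(x, ...) {
  cat(sprintf(
    "<cytoplasm_quant> total %.4g = nuclear %.4g + cytoplasmic %.4g; mean cytoplasmic %.4g a.u./um2 over %.0f um2\n",
    x$total_cumulative, x$nuclear_cumulative, x$cytoplasmic_cumulative,
    x$mean_cytoplasmic, x$cytoplasmic_area))
  invisible(x)
}

#' Normalize per-ROI metric values to the vehicle group
#'
#' Divides each value by the mean of the vehicle-control group, turning a
#' per-ROI metric into fold changes over vehicle.
#'
#' @param values Numeric vector of per-ROI metric values.
#' @param vehicle_values Numeric vector of the same metric in the vehicle
#'   group; must be non-empty with positive mean.
#' @return Numeric vector of fold changes, `values / mean(vehicle_values)`.
#' @examples
#' normalize_to_vehicle(c(2485), vehicle_values = c(700))  # ~3.55
#' @export
normalize_to_vehicle <- function(values, vehicle_values) {
  if (!length(vehicle_values)) stop("vehicle group is empty")
  m <- mean(vehicle_values)
  if (!is.finite(m) || m <= 0) stop("vehicle group mean must be positive")
  values / m
}
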