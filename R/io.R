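#' @title Formats, configuration and pipeline orchestration
#' @name io_cli
#' @keywords internal
NULL

#' Write an ROI as a multi-channel TIFF with sidecar metadata
#'
#' One 16-bit TIFF page per channel (intensities clipped at 65535), a
#' JSON sidecar (`<path>.json`) recording channel order, pixel size,
#' condition and, when ground truth is supplied, the generator seed, and
#' optionally a ground-truth CSV (`<path stem>_truth.csv`) with one row
#' per planted object.
#'
#' @param roi An [roi_record].
#' @param path Output TIFF path.
#' @param truth Optional `ground_truth` from [generate_roi()].
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path, truth = NULL) {
  stopifnot(inherits(roi, "roi_record"))
  pages <- lapply(roi$channels, function(ch) {
    pmin(pmax(round(ch$pixels), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  side <- list(
    channels = names(roi$channels),
    pixel_size = roi$channels[[1]]$pixel_size,
    condition = roi$condition,
    id = roi$id
  )
  if (!is.null(truth)) {
    side$seed <- truth$seed
    side$preset <- unclass(truth$preset)
    tcsv <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
    nuc <- truth$nuclei; gr <- truth$granules
    obj <- rbind(
      if (nrow(nuc)) data.frame(type = "nucleus", id = nuc$id,
                                cx_um = nuc$cx_um, cy_um = nuc$cy_um,
                                size1_um = nuc$semi_a_um, size2_um = nuc$semi_b_um,
                                theta = nuc$theta, amplitude = nuc$amplitude,
                                pixel_count = nuc$pixel_count, border = NA),
      if (nrow(gr)) data.frame(type = "granule", id = gr$id,
                               cx_um = gr$cx_um, cy_um = gr$cy_um,
                               size1_um = gr$radius_um, size2_um = gr$radius_um,
                               theta = 0, amplitude = gr$amplitude,
                               pixel_count = gr$pixel_count, border = gr$border)
    )
    utils::write.csv(obj, tcsv, row.names = FALSE)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-channel TIFF ROI
#'
#' Reads all pages bit-exactly (8/16-bit values are kept on their native
#' integer scale, not rescaled) and attaches pixel geometry and condition
#' metadata from the JSON sidecar when present.
#'
#' @param path TIFF path.
#' @param channel_map Named integer vector mapping channel roles to TIFF
#'   pages, e.g. `c(DAPI = 1, G3BP1 = 2)`. Defaults to the sidecar's
#'   channel list. A role mapped past the last page is an error naming
#'   the role.
#' @param pixel_size Pixel size in um; defaults to the sidecar value.
#' @return An [roi_record].
#' @export
read_roi <- function(path, channel_map = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  if (is.null(channel_map)) {
    chn <- unlist(side$channels)
    if (is.null(chn)) stop("no channel_map given and no sidecar for ", path)
    channel_map <- stats::setNames(seq_along(chn), chn)
  }
  pixel_size <- pixel_size %||% side$pixel_size
  if (is.null(pixel_size)) stop("pixel_size not given and not in sidecar")
  bad <- channel_map > length(pages) | channel_map < 1
  if (any(bad)) {
    stop(sprintf("channel role(s) %s map to missing TIFF pages (file has %d)",
                 paste(names(channel_map)[bad], collapse = ", "), length(pages)))
  }
  channels <- lapply(names(channel_map), function(role) {
    m <- pages[[channel_map[[role]]]]
    storage.mode(m) <- "double"
    channel_image(m, pixel_size,
                  if (role %in% c("DAPI", "G3BP1", "p-eIF2a", "TIA1")) role else "G3BP1")
  })
  names(channels) <- names(channel_map)
  cond <- side$condition %||% list()
  roi_record(channels, condition = cond, id = side$id %||% basename(path))
}

#' Write a label image as a 16-bit TIFF
#'
#' @param labels Integer label matrix (values 0..65535).
#' @param path Output path.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults; any can be
#' overridden by name. Used by [run_pipeline()] and the command-line
#' wrapper.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size = 0.1,               # um per pixel
    image_size = 1024,              # pixels per side
    marker_role = "G3BP1",
    channel_map = c(DAPI = 1, G3BP1 = 2),
    min_nucleus_area = 10,          # um^2
    min_granule_area = 0.04,        # um^2
    threshold = "otsu",
    k_mad = 5,
    min_peak_separation = 0.3,      # um
    watershed = TRUE,
    ws_tolerance = 0.5,
    diffuse_vehicle_level = 100,
    background_fraction = 0.45,
    granule_contrast = 3,
    stats_metric = "mean_cytoplasmic",
    rout_q = 1,
    out_dir = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$channel_map)) vals$channel_map <- unlist(vals$channel_map)
  do.call(run_config, vals)
}

#' Stable hash of a configuration
#'
#' @param config A `run_config`.
#' @return MD5 hex string of the canonical JSON form.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}

quantify_roi <- function(roi, config) {
  dapi <- roi$channels[["DAPI"]]
  if (is.null(dapi)) stop("ROI has no DAPI channel")
  marker <- roi$channels[[config$marker_role]] %||%
    roi$channels[[setdiff(names(roi$channels), "DAPI")[1]]]
  if (is.null(marker)) stop("ROI has no marker channel")
  nuc <- segment_nuclei(dapi, min_nucleus_area = config$min_nucleus_area,
                        threshold = config$threshold)
  gr <- segment_granules(marker, nuc,
                         min_granule_area = config$min_granule_area,
                         threshold = config$threshold, k_mad = config$k_mad,
                         min_peak_separation = config$min_peak_separation,
                         watershed = config$watershed,
                         ws_tolerance = config$ws_tolerance)
  cm <- cluster_metrics(marker, gr)
  nq <- nucleus_based_metrics(marker, nuc)
  row <- data.frame(
    id = roi$id %||% NA_character_,
    extract_pct = roi$condition$extract_pct %||% NA_real_,
    exposure_h = roi$condition$exposure_h %||% NA_real_,
    nucleus_count = nuc$nucleus_count,
    cm$summary,
    total_cumulative = nq$total_cumulative,
    nuclear_cumulative = nq$nuclear_cumulative,
    cytoplasmic_cumulative = nq$cytoplasmic_cumulative,
    cytoplasmic_area = nq$cytoplasmic_area,
    mean_cytoplasmic = nq$mean_cytoplasmic)
  gt <- cm$table
  if (nrow(gt)) gt <- cbind(id = row$id, gt)
  list(row = row, granules = gt)
}

#' Run the full analysis pipeline
#'
#' Either simulates ROIs for a set of exposure conditions (via
#' [generate_roi()]) or reads every TIFF in an input directory, then runs
#' nucleus segmentation, granule segmentation and both quantitative
#' analyses on each ROI, and, when two or more condition groups are
#' present, a Kruskal-Wallis/Dunn comparison of the configured metric
#' with per-group ROUT outlier removal. Per-ROI failures are logged and
#' the run continues. The run is deterministic given `seed` and the
#' configuration.
#'
#' @param conditions List of `c(extract_pct, exposure_h)` pairs to
#'   simulate (ignored when `input_dir` is given).
#' @param n_roi ROIs per simulated condition.
#' @param seed Base seed; ROI `j` of condition `i` uses
#'   `seed * 10000 + (i - 1) * 100 + j`.
#' @param input_dir Directory of TIFF ROIs (with sidecars) to analyse
#'   instead of simulating.
#' @param config A [run_config()].
#' @return A list with `roi_table` (one row per successfully analysed
#'   ROI), `granule_table` (per-granule rows), `test` (a `test_report` or
#'   `NULL`), and `log` (timestamped stage records, package version,
#'   config hash, seeds, per-ROI errors). When `config$out_dir` is set,
#'   CSVs, the test report JSON and the run log JSON are written there.
#' @export
run_pipeline <- function(conditions = NULL, n_roi = 3, seed = 1,
                         input_dir = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("sgquant")),
              config_hash = config_hash(config), seed = seed,
              stages = character(), errors = list())
  stage <- function(msg) {
    log$stages <<- c(log$stages,
                     sprintf("%s %s", format(Sys.time(), "%H:%M:%S"), msg))
  }

  tasks <- list()
  if (!is.null(input_dir)) {
    files <- list.files(input_dir, pattern = "\\.tiff?$", full.names = TRUE)
    if (!length(files)) stop("no TIFF files in ", input_dir)
    tasks <- lapply(files, function(f) list(kind = "file", path = f))
  } else {
    if (is.null(conditions) || !length(conditions)) {
      stop("give either 'conditions' to simulate or an 'input_dir'")
    }
    for (i in seq_along(conditions)) {
      cc <- conditions[[i]]
      for (j in seq_len(n_roi)) {
        tasks[[length(tasks) + 1L]] <- list(
          kind = "sim", pct = cc[1], hours = cc[2],
          seed = seed * 10000 + (i - 1) * 100 + j)
      }
    }
  }

  rows <- list(); gran <- list()
  for (t in tasks) {
    res <- tryCatch({
      roi <- if (t$kind == "file") {
        read_roi(t$path, pixel_size = config$pixel_size)
      } else {
        generate_roi(sg_preset(t$pct, t$hours), seed = t$seed,
                     width = config$image_size, pixel_size = config$pixel_size,
                     diffuse_vehicle_level = config$diffuse_vehicle_level,
                     background_fraction = config$background_fraction,
                     granule_contrast = config$granule_contrast)$roi
      }
      q <- quantify_roi(roi, config)
      if (t$kind == "sim") q$row$seed <- t$seed
      q
    }, error = function(e) e)
    if (inherits(res, "error")) {
      what <- if (t$kind == "file") t$path else sprintf("sim %g:%g seed %d",
                                                        t$pct, t$hours, t$seed)
      log$errors[[length(log$errors) + 1L]] <- list(roi = what,
                                                    message = conditionMessage(res))
      stage(sprintf("ERROR %s: %s", what, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$row
      if (nrow(res$granules)) gran[[length(gran) + 1L]] <- res$granules
      stage(sprintf("ok %s (%d granules)", res$row$id, res$row$sg_count))
    }
  }
  if (!length(rows)) stop("no ROI could be analysed")
  roi_table <- do.call(rbind, rows)
  granule_table <- if (length(gran)) do.call(rbind, gran) else NULL

  test <- NULL
  grp <- sprintf("%g:%g", roi_table$extract_pct, roi_table$exposure_h)
  metric <- roi_table[[config$stats_metric]]
  if (!is.null(metric) && length(unique(grp)) >= 2 &&
      all(table(grp) >= 2)) {
    test <- tryCatch(
      kruskal_wallis_dunn(split(metric, grp), rout_q = config$rout_q),
      error = function(e) NULL)
    stage(sprintf("stats on %s: %s", config$stats_metric,
                  if (is.null(test)) "skipped" else "kw-dunn"))
  }
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(roi_table, file.path(config$out_dir, "roi_table.csv"),
                     row.names = FALSE)
    if (!is.null(granule_table)) {
      utils::write.csv(granule_table,
                       file.path(config$out_dir, "granule_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(test)) {
      jsonlite::write_json(
        list(test_name = test$test_name, statistic = as.list(test$statistic),
             p_value = as.list(test$p_value), comparisons = test$comparisons,
             summaries = test$summaries),
        file.path(config$out_dir, "test_report.json"),
        auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
    }
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(roi_table = roi_table, granule_table = granule_table,
       test = test, log = log)
}
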