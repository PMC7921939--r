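# Readers/writers: multi-page TIFF volumes (TZYX page order) with a JSON
# metadata sidecar, ground-truth CSVs and YAML cohort schedules / pipeline
# configuration.

#' Write a volume series to a multi-page TIFF
#'
#' Pages are ordered TZYX (all z-sections of frame 1, then frame 2, ...).
#' Physical voxel sizes, timestamps and bit depth go to a JSON sidecar
#' (`<path>.json`). Integer-valued volumes round-trip bit-exactly.
#'
#' @param vs a [volume_series()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(vs, path) {
  bit <- vs$meta$bit_depth %||% 16L
  qmax <- 2^bit - 1
  pages <- list()
  for (f in seq_along(vs$frames)) {
    a <- vs$frames[[f]]
    for (z in seq_len(dim(a)[1]))
      pages[[length(pages) + 1]] <- pmin(pmax(a[z, , ] / qmax, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(n_frames = length(vs$frames), n_z = dim(vs$frames[[1]])[1],
               spacing = as.numeric(vs$spacing),
               timestamps = vs$timestamps, bit_depth = bit,
               axes = "TZYX")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume series from a multi-page TIFF
#'
#' Reads TZYX-ordered pages; voxel spacing and timestamps come from the JSON
#' sidecar when present, otherwise from the arguments (with a warning), which
#' mirrors falling back to configuration values when acquisition metadata is
#' missing.
#'
#' @param path TIFF path written by [write_volume_series()] or compatible.
#' @param spacing fallback voxel spacing `c(z, y, x)` micrometres.
#' @param frame_interval fallback frame interval, seconds.
#' @param n_z fallback number of z-sections per frame (required without a
#'   sidecar when the stack holds several frames).
#' @param bit_depth fallback camera bit depth.
#' @return a [volume_series()].
#' @export
read_volume_series <- function(path, spacing = c(1, 0.25, 0.25),
                               frame_interval = 20, n_z = NULL,
                               bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    n_z <- meta$n_z
    spacing <- meta$spacing
    timestamps <- meta$timestamps
    bit_depth <- meta$bit_depth
  } else {
    warning("no metadata sidecar for ", path,
            "; using configured spacing ", paste(spacing, collapse = "/"),
            " um and ", frame_interval, " s frame interval")
    if (is.null(n_z)) n_z <- length(pages)
    timestamps <- (seq_len(length(pages) / n_z) - 1) * frame_interval
  }
  if (length(pages) %% n_z != 0)
    stop("page count ", length(pages), " in ", path,
         " is not a multiple of n_z = ", n_z)
  qmax <- 2^bit_depth - 1
  nf <- length(pages) / n_z
  frames <- lapply(seq_len(nf), function(f) {
    zs <- pages[((f - 1) * n_z + 1):(f * n_z)]
    a <- array(0, c(n_z, dim(zs[[1]])))
    for (z in seq_len(n_z)) a[z, , ] <- round(zs[[z]] * qmax)
    a
  })
  volume_series(frames, spacing, timestamps, meta = list(bit_depth = bit_depth))
}

#' Write the ground-truth sidecar of a simulated couple
#'
#' @param sim a [simulate_couple()] result.
#' @param couple_id identifier written into the CSV.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, couple_id, path) {
  ts <- sim$volumes$timestamps
  df <- data.frame(couple_id = couple_id,
                   frame = seq_along(ts), time_s = ts,
                   pattern_label = sim$truth$patterns,
                   t0_frame = sim$truth$t0)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort schedule from YAML
#'
#' Expected structure: `condition`, `n_couples`, `seed` and `frequencies`, a
#' mapping from aligned time (seconds) to a named pattern->frequency table.
#' (Use `n_couples`, not a bare `n` key: YAML 1.1 parses `n` as a boolean.)
#'
#' @param path YAML file.
#' @return a [cohort_schedule()].
#' @export
read_cohort_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  times <- as.numeric(names(y$frequencies))
  freq <- t(vapply(y$frequencies, function(fv) {
    v <- stats::setNames(numeric(length(PATTERNS)), PATTERNS)
    v[normalize_pattern(names(fv))] <- as.numeric(unlist(fv))
    v
  }, numeric(length(PATTERNS))))
  cohort_schedule(y$condition, y$n_couples %||% y$n, times, freq,
                  seed = y$seed %||% 1L)
}

#' Pipeline configuration
#'
#' Assembles and validates the full configuration of a pipeline run: the
#' acquisition geometry, the couple geometry and noise, the classifier
#' thresholds (including the 35% enrichment rule), the morphometry threshold
#' (1.3 micrometre neck rule), the statistics mode and the cohort
#' conditions. Round-trips losslessly through YAML.
#'
#' @param seed master seed.
#' @param acquisition,couple,classifier,morphometry,stats named lists
#'   overriding individual defaults.
#' @param conditions list of conditions, each
#'   `list(name=, n_couples=, times=, freq=)` with `freq` a matrix (rows =
#'   times) or a single frequency vector recycled over times.
#' @param standardize_at aligned time (s) at which standardized maps and
#'   enrichment ratios are computed.
#' @param figures write SVG/PNG figures from [run_pipeline()].
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, acquisition = list(), couple = list(),
                            classifier = list(), morphometry = list(),
                            stats = list(), conditions = list(),
                            standardize_at = 20, figures = FALSE) {
  acq <- utils::modifyList(list(n_z = 21L, z_step = 1.0, xy_pixel = 0.25,
                                frame_interval = 20, n_frames = 8L,
                                n_y = 64L, n_x = 64L, bit_depth = 16L),
                           acquisition)
  cpl <- utils::modifyList(list(tcell_radius = 5, apc_radius = 4.5,
                                interface_radius = 3, contact_frame = 1L,
                                coupling_mode = "instant",
                                growth_time_s = 80, contrast = 2,
                                background = 100, offset = 10,
                                poisson_scale = 1, gauss_sigma = 5),
                           couple)
  cls <- utils::modifyList(classifier_params(), classifier)
  mor <- utils::modifyList(list(neck_min = 1.3), morphometry)
  sts <- utils::modifyList(list(se_mode = "binomial", continuity = 0.5),
                           stats)
  stopifnot(cls$enrichment_threshold >= 0, cls$enrichment_threshold < 10,
            cls$central_rel_radius > 0, cls$central_rel_radius <= 1,
            cls$invagination_depth_um > 0, mor$neck_min > 0,
            sts$continuity >= 0)
  structure(list(seed = as.integer(seed), acquisition = acq, couple = cpl,
                 classifier = cls, morphometry = mor, stats = sts,
                 conditions = conditions, standardize_at = standardize_at,
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(seed = y$seed, acquisition = y$acquisition,
                  couple = y$couple, classifier = y$classifier,
                  morphometry = y$morphometry, stats = y$stats,
                  conditions = y$conditions,
                  standardize_at = y$standardize_at, figures = y$figures)
}
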