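#' Acquisition geometry of a spinning-disk time series
#'
#' Describes the voxel grid and timing of a 4D (t, z, y, x) acquisition.
#' Defaults mirror a typical spinning-disk confocal protocol for T cell-APC
#' conjugates: 21 z-sections at 1 micrometre intervals every 20 s. The lateral
#' pixel size defaults to 0.25 micrometres so that the 1.3 micrometre neck
#' criterion of the morphometric analysis is resolved by at least 5 pixels.
#'
#' @param n_z number of z-sections per frame (>= 3).
#' @param z_step axial spacing in micrometres (> 0).
#' @param xy_pixel lateral pixel size in micrometres (> 0).
#' @param frame_interval time between frames in seconds (> 0).
#' @param n_frames number of frames.
#' @param n_y,n_x lateral field size in pixels.
#' @param bit_depth camera bit depth used when quantizing simulated images.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_z = 21L, z_step = 1.0, xy_pixel = 0.25,
                             frame_interval = 20, n_frames = 1L,
                             n_y = 64L, n_x = 64L, bit_depth = 16L) {
  stopifnot(n_z >= 3, z_step > 0, xy_pixel > 0, frame_interval > 0,
            n_frames >= 1, n_y >= 8, n_x >= 8, bit_depth %in% c(8L, 12L, 16L))
  structure(list(n_z = as.integer(n_z), z_step = z_step, xy_pixel = xy_pixel,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 n_y = as.integer(n_y), n_x = as.integer(n_x),
                 bit_depth = as.integer(bit_depth)),
            class = "acquisition_spec")
}

#' Specification of one synthetic T cell-APC couple
#'
#' Defines the geometry, sensor pattern schedule, optics and noise of a single
#' simulated cell couple. The T cell is a GFP-positive flattened sphere whose
#' contact disc faces the (non-fluorescent) APC; the APC is rendered only in a
#' separate label channel. Sensor accumulation follows `pattern_schedule`, a
#' step function over frames.
#'
#' @param seed integer seed; simulation is bit-reproducible given the spec.
#' @param acquisition an [acquisition_spec()].
#' @param tcell_radius,apc_radius cell radii in micrometres.
#' @param interface_radius full-width contact disc radius in micrometres.
#' @param contact_frame first frame at which the cells are in contact.
#' @param coupling_mode `"instant"` (interface at full width from contact) or
#'   `"grow_to_full_width"` (linear growth over `growth_time_s`).
#' @param growth_time_s time to reach full interface width in seconds.
#' @param pattern_schedule data.frame with columns `frame`, `pattern`; each row
#'   starts a new pattern that holds until the next row. Frames strictly
#'   increasing.
#' @param contrast peak accumulation intensity as a multiple of the cellular
#'   background (>= 0).
#' @param background mean GFP intensity inside the T cell (camera units).
#' @param offset intensity outside the T cell (media + camera offset).
#' @param poisson_scale photons per intensity unit for shot noise; 0 disables.
#' @param gauss_sigma read-noise standard deviation (intensity units).
#' @param axis interface normal pointing into the T cell, (z, y, x) order.
#' @param asym_angle_deg azimuth of the asymmetric sector centre.
#' @param shape_events list of shape deformations; each element a list with
#'   `type` in `"early_lamella"` (`length`), `"neck"` (`position`, `width`) or
#'   `"off_interface_protrusion"` (`frame`, `length`).
#' @return an object of class `synth_couple_spec`.
#' @export
synth_couple_spec <- function(seed = 1L,
                              acquisition = acquisition_spec(),
                              tcell_radius = 5, apc_radius = 4,
                              interface_radius = 3,
                              contact_frame = 1L,
                              coupling_mode = c("instant", "grow_to_full_width"),
                              growth_time_s = 80,
                              pattern_schedule = data.frame(frame = 1L,
                                                            pattern = "none"),
                              contrast = 2, background = 100, offset = 10,
                              poisson_scale = 1, gauss_sigma = 5,
                              axis = c(1, 0, 0), asym_angle_deg = 0,
                              shape_events = list()) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(inherits(acquisition, "acquisition_spec"),
            contrast >= 0, background > 0, offset >= 0,
            poisson_scale >= 0, gauss_sigma >= 0,
            tcell_radius > interface_radius, apc_radius > interface_radius,
            contact_frame >= 1)
  pattern_schedule$pattern <- normalize_pattern(pattern_schedule$pattern)
  if (is.unsorted(pattern_schedule$frame, strictly = TRUE))
    stop("pattern_schedule frames must be strictly increasing")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(seed = as.integer(seed), acquisition = acquisition,
                 tcell_radius = tcell_radius, apc_radius = apc_radius,
                 interface_radius = interface_radius,
                 contact_frame = as.integer(contact_frame),
                 coupling_mode = coupling_mode, growth_time_s = growth_time_s,
                 pattern_schedule = pattern_schedule, contrast = contrast,
                 background = background, offset = offset,
                 poisson_scale = poisson_scale, gauss_sigma = gauss_sigma,
                 axis = axis, asym_angle_deg = asym_angle_deg,
                 shape_events = shape_events),
            class = "synth_couple_spec")
}

#' Cohort schedule of pattern frequencies over aligned time
#'
#' Programs, for one experimental condition, the per-timepoint probabilities
#' of each interface pattern from which the individual couples' timelines are
#' drawn.
#'
#' @param condition condition name (e.g. `"Teff_pep"`).
#' @param n_couples number of cell couples to simulate (>= 0).
#' @param times aligned timepoints in seconds relative to tight coupling.
#' @param freq numeric matrix, `length(times)` rows and 7 columns named as
#'   [pattern_levels()]; every row must sum to 1 within 1e-9.
#' @param seed integer seed for the per-couple draws.
#' @return an object of class `cohort_schedule`.
#' @export
cohort_schedule <- function(condition, n_couples, times, freq, seed = 1L) {
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) colnames(freq) <- PATTERNS
  freq <- freq[, PATTERNS, drop = FALSE]
  stopifnot(n_couples >= 0, nrow(freq) == length(times), all(freq >= 0))
  bad <- abs(rowSums(freq) - 1) > 1e-9
  if (any(bad))
    stop("frequency vectors must sum to 1 (rows ",
         paste(which(bad), collapse = ", "), " do not)")
  structure(list(condition = condition, n_couples = as.integer(n_couples),
                 times = times, freq = freq, seed = as.integer(seed)),
            class = "cohort_schedule")
}

#' Default aligned time grid
#'
#' The analysis grid relative to tight cell coupling: -40 s to +420 s in
#' 20 s steps.
#' @return numeric vector of aligned times in seconds.
#' @export
alignment_grid <- function() seq(-40, 420, by = 20)
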