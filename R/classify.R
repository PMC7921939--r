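# Interface enrichment and six-pattern classification.
#
# The scalar gate is the 35% rule: interface enrichment below 35% of the
# cellular background is "none" (no accumulation).  Above the gate, a fixed
# precedence cascade of geometric criteria assigns exactly one of the six
# accumulation patterns.  The quantitative thresholds are reconstructions,
# exposed as named parameters.

#' Classifier thresholds
#'
#' @param enrichment_threshold scalar enrichment gate (0.35 = the 35% rule).
#' @param central_rel_radius relative radius of the central interface disc.
#' @param invagination_depth_um depth behind the interface (micrometres) above
#'   which a centre-seeded enriched component is an invagination.
#' @param invag_search_rel,invag_search_depth_um cylinder (relative radius,
#'   depth) searched for deep accumulation and excluded from the background.
#' @param central_mass_frac minimum fraction of enriched shell mass inside the
#'   central disc for the central pattern.
#' @param peripheral_mass_frac minimum fraction of enriched shell mass in the
#'   annulus for the peripheral pattern.
#' @param peripheral_min_angle_deg minimum angular coverage (degrees) of the
#'   enriched annulus for the peripheral pattern.
#' @param asymmetric_max_sector_deg maximum angular sector (degrees) confining
#'   the enriched shell mass for the asymmetric pattern.
#' @param lamellal_area_frac minimum interface-area coverage of the slab.
#' @param lamellal_depth_um `c(min, max)` extent of the slab behind the
#'   interface, micrometres.
#' @param diffuse_coverage_frac minimum coverage of both central disc and
#'   annulus for the (non-fallback) diffuse rule.
#' @param smooth_half in-plane half-width of the pre-threshold mean filter.
#' @return named list of classifier parameters.
#' @export
classifier_params <- function(enrichment_threshold = 0.35,
                              central_rel_radius = 0.5,
                              invagination_depth_um = 1.5,
                              invag_search_rel = 0.6,
                              invag_search_depth_um = 3.0,
                              central_mass_frac = 0.5,
                              peripheral_mass_frac = 0.75,
                              peripheral_min_angle_deg = 180,
                              asymmetric_max_sector_deg = 180,
                              lamellal_area_frac = 0.5,
                              lamellal_depth_um = c(0.5, 2.5),
                              diffuse_coverage_frac = 0.75,
                              smooth_half = 1L) {
  stopifnot(enrichment_threshold >= 0, central_rel_radius > 0,
            central_rel_radius <= 1, invagination_depth_um > 0,
            lamellal_depth_um[1] < lamellal_depth_um[2])
  as.list(environment())
}

# Relative interface coordinate fields of the T cell voxels.
interface_fields <- function(dims, spacing, interface) {
  cc <- coord_arrays(dims, spacing)
  n <- interface$normal / sqrt(sum(interface$normal^2))
  dz <- cc$z - interface$center[1]
  dy <- cc$y - interface$center[2]
  dx <- cc$x - interface$center[3]
  d <- dz * n[1] + dy * n[2] + dx * n[3]
  rho <- sqrt(pmax(dz^2 + dy^2 + dx^2 - d^2, 0))
  bas <- plane_basis(n)
  u <- dz * bas$e1[1] + dy * bas$e1[2] + dx * bas$e1[3]
  v <- dz * bas$e2[1] + dy * bas$e2[2] + dx * bas$e2[3]
  list(d = d, rho = rho, rel = rho / interface$radius,
       theta = atan2(v, u) * 180 / pi, u = u, v = v)
}

shell_mask <- function(tcell_mask, interface) {
  contact <- array(FALSE, dim(tcell_mask))
  contact[interface$contact_idx] <- TRUE
  dilate3d(contact, 1L, connectivity = 26) & tcell_mask
}

#' Measure interface enrichment against the cellular background
#'
#' The interface shell is the contact set dilated one voxel into the T cell;
#' the background is the mean intensity over T cell voxels excluding the shell
#' and the invagination search cylinder (so that deep accumulations do not
#' mask themselves).
#'
#' @param volume_frame 3D intensity array.
#' @param tcell_mask logical 3D array.
#' @param interface interface geometry as from [interface_geometry()]; must
#'   carry `contact_idx`.
#' @param spacing voxel spacing `c(z, y, x)` micrometres.
#' @param params [classifier_params()].
#' @return list(interface_mean, background_mean, enrichment_fraction).
#' @export
measure_enrichment <- function(volume_frame, tcell_mask, interface,
                               spacing = c(1, 0.25, 0.25),
                               params = classifier_params()) {
  if (is.null(interface) || !length(interface$contact_idx))
    stop("interface is empty")
  sh <- shell_mask(tcell_mask, interface)
  flds <- interface_fields(dim(tcell_mask), spacing, interface)
  search <- flds$rel <= params$invag_search_rel &
    flds$d >= 0 & flds$d <= params$invag_search_depth_um
  bg <- tcell_mask & !sh & !search
  if (!any(bg)) stop("empty background region")
  im <- mean(volume_frame[sh])
  bm <- mean(volume_frame[bg])
  list(interface_mean = im, background_mean = bm,
       enrichment_fraction = im / bm - 1)
}

#' Classify one frame into an interface pattern
#'
#' Applies the 35% gate, then a fixed precedence cascade
#' invagination > central > peripheral > asymmetric > lamellal > diffuse on
#' the set of enriched voxels (intensity at least
#' `(1 + enrichment_threshold) x background` after light in-plane smoothing).
#' Diffuse doubles as the terminal catch-all, so the classifier is total.
#'
#' @inheritParams measure_enrichment
#' @param enrichment result of [measure_enrichment()].
#' @return one of [pattern_levels()].
#' @export
classify_frame <- function(volume_frame, tcell_mask, interface, enrichment,
                           spacing = c(1, 0.25, 0.25),
                           params = classifier_params()) {
  if (enrichment$enrichment_fraction < params$enrichment_threshold)
    return("none")
  flds <- interface_fields(dim(tcell_mask), spacing, interface)
  sm <- smooth_xy(volume_frame, params$smooth_half)
  A <- tcell_mask &
    sm >= (1 + params$enrichment_threshold) * enrichment$background_mean
  sh <- shell_mask(tcell_mask, interface)
  Ash <- A & sh

  # invagination: enriched component seeded at the interface centre reaching
  # deep into the cell within the central search cylinder
  lab <- label_components_3d(as.logical(A), dim(A), 26L)
  seeds <- which(A & flds$rel <= 0.4 & flds$d >= 0 & flds$d <= 1.0)
  depth <- 0
  if (length(seeds)) {
    comp_ids <- unique(lab[seeds])
    in_comp <- array(lab %in% comp_ids, dim(A))
    deep <- in_comp & flds$rel <= params$invag_search_rel &
      flds$d <= params$invag_search_depth_um
    if (any(deep)) depth <- max(flds$d[deep])
  }
  if (depth > params$invagination_depth_um) return("invagination")
  if (!any(Ash)) return("diffuse")   # gate passed but shell flat

  # shell statistics
  rel_sh <- flds$rel[Ash]
  th_sh <- flds$theta[Ash]
  central_frac <- mean(rel_sh < params$central_rel_radius)
  centroid_rel <- sqrt(mean(flds$u[Ash])^2 + mean(flds$v[Ash])^2) /
    interface$radius
  if (central_frac >= params$central_mass_frac &&
      centroid_rel < params$central_rel_radius)
    return("central")

  contact <- array(FALSE, dim(tcell_mask))
  contact[interface$contact_idx] <- TRUE
  cen_zone <- contact & flds$rel < params$central_rel_radius
  ann_zone <- contact & flds$rel >= params$central_rel_radius
  cen_cov <- if (any(cen_zone)) mean(A[cen_zone]) else 0
  ann_cov <- if (any(ann_zone)) mean(A[ann_zone]) else 0

  ann_theta <- th_sh[rel_sh >= params$central_rel_radius]
  cov_deg <- occupied_coverage_deg(ann_theta)
  if ((1 - central_frac) >= params$peripheral_mass_frac &&
      cen_cov < 0.5 && cov_deg >= params$peripheral_min_angle_deg)
    return("peripheral")

  sector <- occupied_sector_deg(th_sh)
  if (sector < params$asymmetric_max_sector_deg)
    return("asymmetric")

  # lamellal: slab covering most of the interface area, reaching a bounded
  # depth behind it
  slab <- A & flds$rel <= 1 &
    flds$d >= -0.5 & flds$d <= params$lamellal_depth_um[2] + 0.1
  if (any(slab)) {
    px <- min(spacing[2], spacing[3])
    key <- function(m) unique(paste(round(flds$u[m] / px), round(flds$v[m] / px)))
    covered <- mean(key(contact) %in% key(slab))
    extent <- max(flds$d[slab])
    if (covered >= params$lamellal_area_frac &&
        extent >= params$lamellal_depth_um[1] &&
        extent <= params$lamellal_depth_um[2])
      return("lamellal")
  }
  "diffuse"
}

# Angular coverage / minimal sector on 15-degree bins, ignoring bins holding
# fewer than 1% of the voxels (noise robustness).
occupied_bins <- function(theta_deg, bin = 15) {
  if (!length(theta_deg)) return(integer())
  b <- floor((theta_deg %% 360) / bin)
  tb <- table(b)
  as.integer(names(tb)[tb >= max(2, 0.01 * length(theta_deg))])
}

occupied_coverage_deg <- function(theta_deg, bin = 15) {
  length(occupied_bins(theta_deg, bin)) * bin
}

occupied_sector_deg <- function(theta_deg, bin = 15) {
  bs <- occupied_bins(theta_deg, bin)
  if (!length(bs)) return(0)
  nb <- 360 / bin
  occ <- sort(bs)
  gaps <- diff(c(occ, occ[1] + nb))
  (nb - max(gaps) + 1) * bin
}

#' Classify a tracked couple into a time-aligned pattern timeline
#'
#' One label per aligned timepoint on the -40 s ... +420 s grid relative to
#' t0; frames outside the movie or flagged during segmentation are missing.
#'
#' @param track a [track_couple()] result (t0 must be defined).
#' @param vs the [volume_series()] the track was computed from.
#' @param grid aligned times in seconds (default [alignment_grid()]).
#' @param params [classifier_params()].
#' @return data.frame with columns `time_rel_s`, `frame`, `pattern`.
#' @export
classify_timeline <- function(track, vs, grid = alignment_grid(),
                              params = classifier_params()) {
  if (is.na(track$t0)) stop("t0 is undefined; couple excluded")
  t0_time <- track$timestamps[track$t0]
  out <- data.frame(time_rel_s = grid, frame = NA_integer_,
                    pattern = NA_character_)
  for (i in seq_along(grid)) {
    tt <- t0_time + grid[i]
    f <- which(abs(track$timestamps - tt) < 1e-6)
    if (!length(f)) next
    f <- f[1]
    if (track$flagged[f] || is.null(track$interfaces[[f]])) next
    enr <- measure_enrichment(vs$frames[[f]], track$tcell_masks[[f]],
                              track$interfaces[[f]], vs$spacing, params)
    out$frame[i] <- f
    out$pattern[i] <- classify_frame(vs$frames[[f]], track$tcell_masks[[f]],
                                     track$interfaces[[f]], enr,
                                     vs$spacing, params)
  }
  out[!is.na(out$pattern), , drop = FALSE]
}
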