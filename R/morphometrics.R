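# DIC-style shape measurements: interface diameter, cell width, neck and
# lamella scoring, cell length along a (possibly bent) midline, T cell shape
# factor and off-interface lamella detection.

#' Measure the cell axes along the midline
#'
#' The midline starts at the interface centre and marches into the cell along
#' the local mask centroid direction (so it may bend with the cell). At each
#' arc position the cell diameter is measured perpendicular to the local
#' direction; the cell width is the maximum of this profile, the cell length
#' the midline arc length from interface to the posterior pole.
#'
#' @param tcell_mask logical 3D array (z, y, x).
#' @param interface interface geometry (`center`, `normal`, `diameter`).
#' @param spacing voxel spacing `c(z, y, x)` micrometres.
#' @param step marching step in micrometres.
#' @return list(interface_diameter, cell_width, cell_length, profile) where
#'   `profile` is a data.frame with columns `arc` (micrometres from the
#'   interface) and `diameter`.
#' @export
measure_axes <- function(tcell_mask, interface, spacing, step = 0.15) {
  stopifnot(!is.null(interface))
  idx <- which(tcell_mask, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  p <- interface$center
  dir <- interface$normal / sqrt(sum(interface$normal^2))
  gate <- interface$diameter / 2
  arc <- 0
  # profile slab half-width: thick enough to catch at least one voxel plane
  # even along the coarse axial direction of an anisotropic grid
  half <- max(step, 0.6 * max(spacing * abs(dir)))
  look <- max(1.2, 2 * max(spacing))
  prof_arc <- numeric(0); prof_diam <- numeric(0)
  path <- matrix(p, nrow = 1)
  max_iter <- min(4000L, ceiling(2.5 * sum(dim(tcell_mask) * spacing) / step))
  for (it in seq_len(max_iter)) {
    rel <- sweep(pts, 2, p)
    proj <- as.numeric(rel %*% dir)
    perp2 <- pmax(rowSums(rel^2) - proj^2, 0)
    rad_gate <- gate * 1.8 + 1
    half <- max(step, 0.6 * max(spacing * abs(dir)))
    slab <- abs(proj) <= half & perp2 <= rad_gate^2
    if (sum(slab) >= 2) {
      dia <- 2 * sqrt(max(perp2[slab]))
      prof_arc <- c(prof_arc, arc)
      prof_diam <- c(prof_diam, dia)
      gate <- max(dia / 2, 0.5)
    }
    # advance within a narrow corridor around the local radius so the walk
    # terminates at the cell end instead of jumping to a bent neighbour
    # segment and turning around
    ahead_gate <- gate * 1.2 + 0.5
    ahead <- proj > 0 & proj <= look & perp2 <= ahead_gate^2
    # residual distance to the posterior end, read along the axis so cap-rim
    # voxels do not inflate it
    tail_arc <- function() {
      axial <- ahead & perp2 <= max(0.5, 0.35 * gate)^2
      tp <- proj[if (any(axial)) axial else ahead]
      if (length(tp)) max(tp) else 0
    }
    if (!any(ahead & proj > step / 2)) {
      arc <- arc + tail_arc()
      break
    }
    cen <- colMeans(pts[ahead, , drop = FALSE])
    stp <- cen - p
    stp_dir <- stp / sqrt(sum(stp^2))
    if (sum(stp_dir * dir) < 0.7) {
      # hairpin at the step scale: the cell ends about at the local centroid
      # and the centroid pull has curled around the cap
      arc <- arc + max(0, sum(stp * dir))
      break
    }
    dir <- 0.7 * dir + 0.3 * stp_dir
    dir <- dir / sqrt(sum(dir^2))
    p <- p + dir * step
    arc <- arc + step
    # safety: break (without tail) if the walk revisits earlier midline points
    if (nrow(path) > 8) {
      past <- path[seq_len(nrow(path) - 6), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(past, 2, p)^2))) < 2 * step) break
    }
    path <- rbind(path, p)
  }
  list(interface_diameter = interface$diameter,
       cell_width = if (length(prof_diam)) max(prof_diam) else 0,
       cell_length = arc,
       profile = data.frame(arc = prof_arc, diameter = prof_diam))
}

#' Score the lamella from the midline diameter profile
#'
#' A neck is a point strictly between the interface and the widest part of
#' the cell where the diameter is smaller than both the interface diameter
#' and the cell width. The lamella is scorable only when such a neck exists
#' and lies more than `neck_min` (default 1.3 micrometres) from the
#' interface; the lamellal length is then the interface-to-neck arc distance.
#'
#' @param profile data.frame (`arc`, `diameter`) from [measure_axes()].
#' @param interface_diameter interface diameter, micrometres.
#' @param neck_min minimum interface-to-neck distance, micrometres.
#' @return list(has_scorable_lamella, neck_distance, lamellal_length,
#'   cell_width).
#' @export
score_lamella <- function(profile, interface_diameter, neck_min = 1.3) {
  none <- list(has_scorable_lamella = FALSE, neck_distance = NA_real_,
               lamellal_length = NA_real_,
               cell_width = if (nrow(profile)) max(profile$diameter) else NA_real_)
  if (nrow(profile) < 3) return(none)
  m <- which.max(profile$diameter)
  if (m < 3) return(none)
  interior <- 2:(m - 1)
  nk <- interior[which.min(profile$diameter[interior])]
  neck_d <- profile$diameter[nk]
  if (!(neck_d < interface_diameter && neck_d < profile$diameter[m]))
    return(none)
  nd <- profile$arc[nk]
  list(has_scorable_lamella = nd > neck_min,
       neck_distance = nd,
       lamellal_length = if (nd > neck_min) nd else NA_real_,
       cell_width = profile$diameter[m])
}

#' T cell shape factor
#'
#' Lamellal length divided by interface diameter.
#'
#' @param lamellal_length,interface_diameter micrometres.
#' @return dimensionless non-negative scalar.
#' @export
shape_factor <- function(lamellal_length, interface_diameter) {
  if (interface_diameter <= 0) stop("interface diameter must be positive")
  stopifnot(lamellal_length >= 0)
  lamellal_length / interface_diameter
}

#' Detect an off-interface lamella
#'
#' A protrusion is a residual mask component left by a morphological opening
#' of the (isotropically resampled) cell body. It counts as an off-interface
#' lamella when it is longer than `min_length` and its base lies farther than
#' one interface radius from the interface centre, so interface lamellae do
#' not trigger it.
#'
#' @param tcell_mask logical 3D array (z, y, x).
#' @param interface interface geometry.
#' @param spacing voxel spacing `c(z, y, x)` micrometres.
#' @param min_length minimum protrusion length, micrometres.
#' @param open_voxels opening radius in output voxels.
#' @return logical.
#' @export
detect_off_interface_lamella <- function(tcell_mask, interface, spacing,
                                         min_length = 1.3, open_voxels = 3L) {
  reo <- reorient_interface_up(tcell_mask,
                               array(as.numeric(tcell_mask), dim(tcell_mask)),
                               interface, spacing)
  body <- dilate3d(erode3d(reo$mask, open_voxels), open_voxels)
  resid <- reo$mask & !body
  if (!any(resid)) return(FALSE)
  lab <- label_components_3d(as.logical(resid), dim(resid), 26L)
  s <- reo$spacing[1]
  o <- reo$origin_index
  near_body <- dilate3d(body, 1L)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (sum(comp) < 10) next
    base <- comp & near_body
    if (!any(base)) next
    bidx <- which(base, arr.ind = TRUE)
    bctr <- colMeans(sweep(bidx, 2, o, `-`)) * s
    base_dist <- sqrt(sum(bctr^2))
    if (base_dist <= interface$radius) next
    cidx <- which(comp, arr.ind = TRUE)
    cpts <- sweep(sweep(cidx, 2, o, `-`), 2, c(s, s, s), `*`)
    len <- max(sqrt(colSums((t(cpts) - bctr)^2)))
    if (len > min_length) return(TRUE)
  }
  FALSE
}

#' Morphometric measurements of one frame
#'
#' Convenience wrapper running [measure_axes()], [score_lamella()],
#' [shape_factor()] and [detect_off_interface_lamella()].
#'
#' @inheritParams measure_axes
#' @param neck_min minimum interface-to-neck distance, micrometres.
#' @return one-row data.frame with the MorphFrame columns.
#' @export
measure_morphometry <- function(tcell_mask, interface, spacing,
                                neck_min = 1.3) {
  ax <- measure_axes(tcell_mask, interface, spacing)
  lam <- score_lamella(ax$profile, ax$interface_diameter, neck_min)
  data.frame(
    interface_diameter = ax$interface_diameter,
    cell_width = ax$cell_width,
    neck_distance = lam$neck_distance,
    lamellal_length = lam$lamellal_length,
    cell_length = ax$cell_length,
    shape_factor = if (lam$has_scorable_lamella)
      shape_factor(lam$lamellal_length, ax$interface_diameter) else NA_real_,
    has_scorable_lamella = lam$has_scorable_lamella,
    has_off_interface_lamella =
      detect_off_interface_lamella(tcell_mask, interface, spacing,
                                   min_length = neck_min))
}

#' Morphometrics from manual line annotations
#'
#' Accepts up to four annotated lines per frame (as drawn on DIC images) and
#' assembles the same MorphFrame columns as the automatic path, overriding
#' measurement by hand-drawn geometry.
#'
#' @param annotations data.frame with columns `couple_id`, `time_rel_s`,
#'   `line_type` (one of `interface_diameter`, `cell_width`,
#'   `lamellal_length`, `cell_length`), `x1`, `y1`, `x2`, `y2` (micrometres).
#' @param neck_min minimum interface-to-neck distance, micrometres.
#' @return data.frame, one row per (couple_id, time_rel_s).
#' @export
measure_from_annotations <- function(annotations, neck_min = 1.3) {
  needed <- c("couple_id", "time_rel_s", "line_type", "x1", "y1", "x2", "y2")
  stopifnot(all(needed %in% names(annotations)))
  ok <- c("interface_diameter", "cell_width", "lamellal_length", "cell_length")
  bad <- setdiff(unique(annotations$line_type), ok)
  if (length(bad)) stop("unknown line_type: ", paste(bad, collapse = ", "))
  annotations$length <- sqrt((annotations$x2 - annotations$x1)^2 +
                               (annotations$y2 - annotations$y1)^2)
  keys <- unique(annotations[c("couple_id", "time_rel_s")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    a <- annotations[annotations$couple_id == keys$couple_id[i] &
                       annotations$time_rel_s == keys$time_rel_s[i], ]
    get <- function(tp) {
      v <- a$length[a$line_type == tp]
      if (length(v)) v[1] else NA_real_
    }
    id <- get("interface_diameter"); ll <- get("lamellal_length")
    scor <- !is.na(ll) && ll > neck_min
    data.frame(couple_id = keys$couple_id[i],
               time_rel_s = keys$time_rel_s[i],
               interface_diameter = id, cell_width = get("cell_width"),
               neck_distance = ll,
               lamellal_length = if (scor) ll else NA_real_,
               cell_length = get("cell_length"),
               shape_factor = if (scor && !is.na(id) && id > 0) ll / id
                              else NA_real_,
               has_scorable_lamella = scor)
  })
  do.call(rbind, rows)
}
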