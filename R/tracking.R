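# Couple tracking: segmentation, contact geometry and the tight-coupling
# reference frame t0.

#' Segment the T cell and the APC in one frame
#'
#' The T cell is the largest GFP-positive connected component (Otsu threshold
#' on the intensity volume). The APC is taken from the label channel when one
#' is provided, otherwise from the adjacent non-fluorescent component inferred
#' from a transmitted-light surrogate. Frames with zero or ambiguous
#' candidates are rejected.
#'
#' @param volume_frame 3D intensity array (z, y, x), GFP channel.
#' @param label_channel optional 3D array marking the APC (> 0 inside).
#' @param min_voxels minimum component size considered a cell.
#' @return list(tcell, apc) of disjoint logical arrays; `apc` may be all-FALSE
#'   when no label channel is given.
#' @export
segment_couple <- function(volume_frame, label_channel = NULL,
                           min_voxels = 200L) {
  stopifnot(length(dim(volume_frame)) == 3)
  thr <- otsu_threshold(as.numeric(volume_frame))
  fg <- volume_frame > thr
  if (!any(fg)) stop("no cells: empty foreground after thresholding")
  lab <- label_components_3d(as.logical(fg), dim(volume_frame), 26L)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= min_voxels)
  if (!length(big)) stop("no cells: no component above size threshold")
  if (length(big) > 2)
    stop("ambiguous frame: more than two candidate components")
  tcell <- array(lab == big[which.max(sizes[big])], dim(volume_frame))
  apc <- array(FALSE, dim(volume_frame))
  if (!is.null(label_channel)) {
    apc <- label_channel > max(label_channel) / 2
    if (!any(apc)) apc <- array(FALSE, dim(volume_frame))
    apc <- apc & !tcell
  }
  list(tcell = tcell, apc = apc)
}

#' Interface geometry between the segmented cells
#'
#' The contact set is the set of T cell boundary voxels within one voxel step
#' (18-connectivity, after one dilation of the APC) of the APC; face+edge
#' adjacency bridges the voxel-scale gap at any couple orientation without
#' inflating point contacts to a 3 x 3 patch the way corner adjacency would. The centre is
#' the physical centroid of the contact set, the normal the unit vector of the
#' contact-plane fit oriented into the T cell, and the diameter the maximum
#' pairwise distance among contact voxels projected onto the interface plane.
#'
#' @param tcell_mask,apc_mask disjoint logical 3D arrays.
#' @param spacing voxel spacing `c(z, y, x)` in micrometres.
#' @return list(center, normal, radius, diameter, contact_idx) or `NULL` when
#'   the cells do not touch.
#' @export
interface_geometry <- function(tcell_mask, apc_mask, spacing) {
  if (any(tcell_mask & apc_mask)) stop("masks must be disjoint")
  if (!any(apc_mask)) return(NULL)
  near_apc <- dilate3d(apc_mask, 1L, connectivity = 18)
  contact <- boundary3d(tcell_mask) & near_apc
  if (!any(contact)) return(NULL)
  idx <- which(contact, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)   # physical (z, y, x)
  ctr <- colMeans(pts)
  # normal: smallest principal axis of the contact set, oriented into the T cell
  if (nrow(pts) >= 10) {
    cv <- stats::cov(pts)
    n <- eigen(cv, symmetric = TRUE)$vectors[, 3]
  } else {
    n <- c(1, 0, 0)
  }
  tidx <- which(tcell_mask, arr.ind = TRUE)
  tcent <- colMeans(sweep(tidx - 1, 2, spacing, `*`))
  if (sum((tcent - ctr) * n) < 0) n <- -n
  n <- n / sqrt(sum(n^2))
  # diameter: max pairwise distance of plane-projected contact voxels
  rel <- sweep(pts, 2, ctr)
  dpth <- rel %*% n
  proj <- rel - dpth %*% t(n)
  bas <- plane_basis(n)
  uv <- cbind(proj %*% bas$e1, proj %*% bas$e2)
  hull <- unique(grDevices::chull(uv[, 1], uv[, 2]))
  huv <- uv[hull, , drop = FALSE]
  diam <- if (nrow(huv) >= 2) max(stats::dist(huv)) else 0
  list(center = ctr, normal = n, radius = diam / 2, diameter = diam,
       contact_idx = idx)
}

#' Detect the tight-coupling reference frame t0
#'
#' t0 is the earlier of (a) the first frame at which the interface has reached
#' its full width and (b) 40 s after first contact. Full width is
#' operationalized as the interface diameter reaching at least
#' `full_width_frac` (default 90%) of its running maximum over the following
#' `plateau_window_s` (default 120 s).
#'
#' @param diameters per-frame interface diameter in micrometres (`NA` where no
#'   contact).
#' @param frame_interval frame spacing in seconds.
#' @param full_width_frac,plateau_window_s plateau rule parameters.
#' @return frame index of t0, or `NA` when no frame has contact.
#' @export
detect_tight_coupling <- function(diameters, frame_interval = 20,
                                  full_width_frac = 0.9,
                                  plateau_window_s = 120) {
  contact <- which(!is.na(diameters) & diameters > 0)
  if (!length(contact)) return(NA_integer_)
  contact_start <- contact[1]
  w <- max(1L, ceiling(plateau_window_s / frame_interval))
  nf <- length(diameters)
  full <- NA_integer_
  for (f in contact_start:nf) {
    if (is.na(diameters[f])) next
    upto <- min(nf, f + w)
    future_max <- max(diameters[f:upto], na.rm = TRUE)
    if (diameters[f] >= full_width_frac * future_max) { full <- f; break }
  }
  forty <- contact_start + ceiling(40 / frame_interval)
  t0 <- min(c(full, forty), na.rm = TRUE)
  as.integer(min(t0, nf))
}

#' Track one couple through a volume series
#'
#' Segments every frame, derives per-frame interface geometry and detects t0.
#' Frames failing segmentation are carried by the nearest valid masks for
#' tracking continuity but flagged and excluded from classification counts.
#'
#' @param vs a [volume_series()], GFP channel.
#' @param label_channel optional [volume_series()] marking the APC.
#' @param ... passed to [detect_tight_coupling()].
#' @return an object of class `couple_track`: list(tcell_masks, apc_masks,
#'   interfaces, diameters, flagged, contact_start, t0, timestamps, spacing).
#' @export
track_couple <- function(vs, label_channel = NULL, ...) {
  nf <- length(vs$frames)
  tmasks <- vector("list", nf); amasks <- vector("list", nf)
  ifaces <- vector("list", nf)
  flagged <- logical(nf)
  for (f in seq_len(nf)) {
    seg <- tryCatch(
      segment_couple(vs$frames[[f]],
                     if (!is.null(label_channel)) label_channel$frames[[f]]),
      error = function(e) NULL)
    if (is.null(seg)) {
      flagged[f] <- TRUE
      prev <- if (f > 1) f - 1 else NA
      tmasks[[f]] <- if (!is.na(prev)) tmasks[[prev]] else NULL
      amasks[[f]] <- if (!is.na(prev)) amasks[[prev]] else NULL
    } else {
      tmasks[[f]] <- seg$tcell
      amasks[[f]] <- seg$apc
    }
    ifaces[[f]] <- if (!is.null(tmasks[[f]]) && !is.null(amasks[[f]]))
      interface_geometry(tmasks[[f]], amasks[[f]], vs$spacing) else NULL
  }
  diams <- vapply(ifaces, function(i) if (is.null(i)) NA_real_ else i$diameter,
                  numeric(1))
  dt <- if (nf > 1) diff(vs$timestamps)[1] else 20
  t0 <- detect_tight_coupling(diams, frame_interval = dt, ...)
  contact <- which(!is.na(diams) & diams > 0)
  structure(list(tcell_masks = tmasks, apc_masks = amasks,
                 interfaces = ifaces, diameters = diams, flagged = flagged,
                 contact_start = if (length(contact)) contact[1] else NA_integer_,
                 t0 = t0, timestamps = vs$timestamps, spacing = vs$spacing),
            class = "couple_track")
}

#' @export
print.couple_track <- function(x, ...) {
  cat(sprintf("couple_track: %d frames, contact at %s, t0 = %s\n",
              length(x$tcell_masks),
              ifelse(is.na(x$contact_start), "none", x$contact_start),
              ifelse(is.na(x$t0), "none", x$t0)))
  invisible(x)
}
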