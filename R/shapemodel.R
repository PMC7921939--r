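# Half-spheroid shape standardization and voxel enrichment ratios.
#
# Each T cell is reoriented with the interface facing "up" (depth axis), then
# mapped by (relative depth, relative radial position within the cross
# section at that depth, azimuth) onto a canonical half-spheroid template so
# that sensor distributions are comparable voxel-by-voxel across cells.

.template_cache <- new.env(parent = emptyenv())

#' Canonical half-spheroid template grid
#'
#' Template arrays are (depth, y, x); the interface plane is depth slice 1,
#' the pole the last slice. The equator radius corresponds to the interface
#' radius (relative radius 1).
#'
#' @param dims template dimensions `c(n_depth, n_y, n_x)`.
#' @return list(dims, inside, u, rel_r, theta, R_t, H, n_inside) where `u` is
#'   relative depth and `rel_r` the radius relative to the equator radius.
#' @export
half_spheroid_template <- function(dims = c(32L, 64L, 64L)) {
  key <- paste(dims, collapse = "x")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  nd <- dims[1]; ny <- dims[2]; nx <- dims[3]
  R_t <- (min(ny, nx) - 4) / 2
  H <- nd - 1
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  u <- array(rep((seq_len(nd) - 1) / H, times = ny * nx), dims)
  yy <- array(rep(rep(seq_len(ny) - cy, each = nd), times = nx), dims)
  xx <- array(rep(seq_len(nx) - cx, each = nd * ny), dims)
  rp <- sqrt(yy^2 + xx^2)
  a <- R_t * sqrt(pmax(1 - u^2, 0))
  inside <- rp <= a
  tpl <- list(dims = dims, inside = inside, u = u, rel_r = rp / R_t,
              local_v = ifelse(a > 0, rp / a, 0),
              theta = atan2(xx, yy), R_t = R_t, H = H,
              n_inside = sum(inside))
  .template_cache[[key]] <- tpl
  tpl
}

#' Reorient a cell with the interface facing up
#'
#' Resamples the masked cell onto an axis-aligned grid whose first axis is
#' depth behind the interface (the interface normal), with the interface
#' centre at a fixed reference point. Intensities are resampled by trilinear
#' interpolation, the mask by nearest neighbour. When the requested output
#' grid coincides with the input grid and the rotation is the identity, the
#' sampling points fall exactly on input voxel centres and the data are
#' returned unchanged.
#'
#' @param tcell_mask logical 3D array (z, y, x).
#' @param volume 3D intensity array.
#' @param interface interface geometry (`center`, `normal` required).
#' @param spacing input voxel spacing `c(z, y, x)` micrometres.
#' @param out_spacing isotropic output voxel size (micrometres); default the
#'   finest input spacing.
#' @param pad_um padding around the cell, micrometres.
#' @return list(volume, mask, spacing, origin_index) of class
#'   `reoriented_cell`; `origin_index` is the (depth, y, x) index of the
#'   interface centre in the output grid.
#' @export
reorient_interface_up <- function(tcell_mask, volume, interface, spacing,
                                  out_spacing = min(spacing), pad_um = 1) {
  n <- interface$normal
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn < 1e-9) stop("degenerate interface normal")
  n <- n / nn
  bas <- plane_basis(n)
  ctr <- interface$center

  identity_rot <- all(abs(n - c(1, 0, 0)) < 1e-9)
  if (identity_rot) ctr <- round(ctr / spacing) * spacing

  # extent of the mask in interface coordinates
  idx <- which(tcell_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  pts <- sweep(idx - 1, 2, spacing, `*`)
  rel <- sweep(pts, 2, ctr)
  d <- rel %*% n
  e1v <- rel %*% bas$e1
  e2v <- rel %*% bas$e2
  s <- out_spacing
  snap <- function(x) ceiling(x / s) * s
  d_lo <- -snap(pad_um); d_hi <- snap(max(d) + pad_um)
  l1 <- snap(max(abs(e1v)) + pad_um)
  l2 <- snap(max(abs(e2v)) + pad_um)
  dv <- seq(d_lo, d_hi, by = s)
  yv <- seq(-l1, l1, by = s)
  xv <- seq(-l2, l2, by = s)
  dims_out <- c(length(dv), length(yv), length(xv))
  g <- expand.grid(d = dv, y = yv, x = xv)
  src <- cbind(ctr[1] + g$d * n[1] + g$y * bas$e1[1] + g$x * bas$e2[1],
               ctr[2] + g$d * n[2] + g$y * bas$e1[2] + g$x * bas$e2[2],
               ctr[3] + g$d * n[3] + g$y * bas$e1[3] + g$x * bas$e2[3])
  si <- sweep(src, 2, spacing, `/`) + 1
  vol_out <- array(trilinear(volume, si, fill = 0), dims_out)
  msk_out <- array(trilinear(array(as.numeric(tcell_mask), dim(tcell_mask)),
                             si, fill = 0) >= 0.5, dims_out)
  structure(list(volume = vol_out, mask = msk_out,
                 spacing = c(s, s, s),
                 origin_index = c(which.min(abs(dv)), which.min(abs(yv)),
                                  which.min(abs(xv)))),
            class = "reoriented_cell")
}

# Boundary radius of the reoriented mask per (depth slice, azimuth bin).
boundary_radius_table <- function(reo, n_theta = 36) {
  dm <- dim(reo$mask)
  idx <- which(reo$mask, arr.ind = TRUE)
  s <- reo$spacing[1]
  o <- reo$origin_index
  d_um <- (idx[, 1] - o[1]) * s
  yv <- (idx[, 2] - o[2]) * s
  xv <- (idx[, 3] - o[3]) * s
  r <- sqrt(yv^2 + xv^2)
  th <- ((atan2(xv, yv) + 2 * pi) %% (2 * pi))
  tb <- pmin(floor(th / (2 * pi) * n_theta) + 1, n_theta)
  keep <- idx[, 1] >= o[1]
  agg <- tapply(r[keep],
                list(factor(idx[keep, 1], levels = seq_len(dm[1])),
                     factor(tb[keep], levels = seq_len(n_theta))),
                max)
  R <- matrix(ifelse(is.na(agg), 0, agg), dm[1], n_theta)
  # fill empty azimuth bins with the slice maximum (pole slices)
  slice_max <- apply(R, 1, max)
  for (i in seq_len(dm[1])) R[i, R[i, ] == 0] <- slice_max[i]
  # calibrate each slice's radius scale by its area-equivalent radius, which
  # is unbiased under rasterization; per-bin maxima carry an
  # orientation-dependent half-voxel bias that would break rotation
  # invariance of the mapping
  cnt <- tabulate(idx[keep, 1], nbins = dm[1])
  r_area <- sqrt(cnt * s^2 / pi)
  for (i in seq_len(dm[1])) {
    if (cnt[i] < 16 || slice_max[i] <= 0) next
    sc <- r_area[i] / sqrt(mean(R[i, ]^2))
    R[i, ] <- R[i, ] * min(max(sc, 0.8), 1.2)
  }
  depth_max <- max(d_um[idx[, 1] >= o[1]])
  list(R = R, depth_max = depth_max, n_theta = n_theta)
}

#' Standardize a reoriented cell onto the half-spheroid template
#'
#' Every template voxel samples the cell at the matching relative coordinate
#' (relative depth below the interface, relative radial position within the
#' cross section at that depth, azimuth); values are clipped at zero and
#' normalized to sum 1, yielding a sensor probability distribution on a grid
#' identical across all cells.
#'
#' @param reo a [reorient_interface_up()] result.
#' @param dims template dimensions `c(n_depth, n_y, n_x)`.
#' @param margin_voxels radial sampling pull-in from the cell boundary, in
#'   output voxels, so boundary template voxels do not average in
#'   extracellular signal.
#' @param depth_margin_um axial pull-in from the posterior pole
#'   (micrometres), keeping pole samples clear of the axial partial-volume
#'   zone of coarse z-sampling.
#' @param depth_inset_um axial pull-in below the interface plane
#'   (micrometres), so the top template slice samples strictly inside the
#'   cell rather than the boundary partial-volume zone.
#' @return object of class `standardized_map`: list(values, dims) with
#'   attribute `template`.
#' @export
standardize_half_spheroid <- function(reo, dims = c(32L, 64L, 64L),
                                      margin_voxels = 3,
                                      depth_margin_um = 0.75,
                                      depth_inset_um = 0.4) {
  if (!any(reo$mask)) stop("empty mask")
  tpl <- half_spheroid_template(dims)
  bt <- boundary_radius_table(reo)
  s <- reo$spacing[1]
  o <- reo$origin_index
  ins <- which(tpl$inside)
  u <- tpl$u[ins]
  v <- tpl$local_v[ins]
  th <- tpl$theta[ins]
  d_hi <- max(bt$depth_max - depth_margin_um, bt$depth_max * 0.5)
  d_um <- depth_inset_um + u * (d_hi - depth_inset_um)
  sl <- pmin(pmax(d_um / s + o[1], 1), nrow(bt$R))
  tb <- pmin(floor(((th + 2 * pi) %% (2 * pi)) / (2 * pi) * bt$n_theta) + 1,
             bt$n_theta)
  lo <- floor(sl); hi <- pmin(lo + 1, nrow(bt$R)); w <- sl - lo
  Rb <- bt$R[cbind(lo, tb)] * (1 - w) + bt$R[cbind(hi, tb)] * w
  r_um <- v * pmax(Rb - margin_voxels * s, 0)
  si <- cbind(d_um / s + o[1],
              r_um * cos(th) / s + o[2],
              r_um * sin(th) / s + o[3])
  vals <- trilinear(reo$volume, si, fill = 0)
  vals[vals < 0] <- 0
  total <- sum(vals)
  if (total <= 0) stop("no signal inside the cell")
  out <- array(0, dims)
  out[ins] <- vals / total
  structure(list(values = out, dims = dims), class = "standardized_map",
            template = tpl)
}

#' Average a cohort of standardized maps and mark the enrichment region
#'
#' The interface enrichment region is the 10% most fluorescent voxels of the
#' average probability distribution across all supplied maps; ties at the
#' cutoff are broken by fixed grid order.
#'
#' @param maps list of [standardize_half_spheroid()] results on one grid.
#' @param fraction region size as a fraction of template voxels.
#' @return list(mask, n_region, n_total, average) of class
#'   `enrichment_region`.
#' @export
build_enrichment_region <- function(maps, fraction = 0.10) {
  if (!length(maps)) stop("empty cohort")
  dims <- maps[[1]]$dims
  for (m in maps) stopifnot(identical(m$dims, dims))
  tpl <- half_spheroid_template(dims)
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  ins <- which(tpl$inside)
  k <- round(fraction * length(ins))
  ord <- order(avg[ins], decreasing = TRUE)   # stable: ties by grid order
  mask <- array(FALSE, dims)
  mask[ins[ord[seq_len(k)]]] <- TRUE
  structure(list(mask = mask, n_region = k, n_total = length(ins),
                 average = avg),
            class = "enrichment_region")
}

#' Enrichment ratio of a map over the interface enrichment region
#'
#' Mean probability within the enrichment region divided by the mean
#' probability over the entire (template) cell.
#'
#' @param map a [standardize_half_spheroid()] result.
#' @param region a [build_enrichment_region()] result on the same grid.
#' @return non-negative scalar; 1 for a uniform distribution.
#' @export
enrichment_ratio <- function(map, region) {
  tpl <- half_spheroid_template(map$dims)
  mean(map$values[region$mask]) / mean(map$values[tpl$inside])
}

#' Central-core enrichment ratio
#'
#' Mean probability within the central core cylinder (relative radius and
#' relative depth 0.5 by default, anchored at the interface centre) divided by
#' the mean over the whole template.
#'
#' @param map a [standardize_half_spheroid()] result.
#' @param rel_radius,rel_height cylinder size relative to the interface radius
#'   and the cell depth.
#' @return non-negative scalar; 1 for a uniform distribution.
#' @export
central_core_ratio <- function(map, rel_radius = 0.5, rel_height = 0.5) {
  stopifnot(rel_radius > 0, rel_radius <= 1, rel_height > 0, rel_height <= 1)
  tpl <- half_spheroid_template(map$dims)
  core <- tpl$inside & tpl$rel_r <= rel_radius & tpl$u <= rel_height
  mean(map$values[core]) / mean(map$values[tpl$inside])
}

#' Core cylinder voxel mask on the template grid
#' @inheritParams central_core_ratio
#' @param dims template dimensions.
#' @return logical array marking the core cylinder.
#' @export
core_cylinder_mask <- function(dims = c(32L, 64L, 64L), rel_radius = 0.5,
                               rel_height = 0.5) {
  tpl <- half_spheroid_template(dims)
  tpl$inside & tpl$rel_r <= rel_radius & tpl$u <= rel_height
}
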