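# Synthetic couple generator.
#
# Cells are solids of revolution about the interface normal: the T cell a
# sphere flattened by the contact disc (optionally deformed by lamella/neck
# events), the APC a flattened sphere facing it across a 1 um gap.  All
# geometry is evaluated in physical coordinates, so an arbitrary interface
# normal produces an exactly rendered rotated couple (no resampling).

# --- internal geometry -------------------------------------------------------

# Piecewise radius profile of the T cell as a function of depth d (um) behind
# the interface plane. Returns list(fun, length).
tcell_profile <- function(spec) {
  rt <- spec$tcell_radius
  rif <- spec$interface_radius
  ev <- Filter(function(e) e$type %in% c("neck", "early_lamella"),
               spec$shape_events)
  if (!length(ev)) {
    dc <- sqrt(rt^2 - rif^2)
    len <- dc + rt
    f <- function(d) {
      r2 <- rt^2 - (d - dc)^2
      sqrt(pmax(r2, 0))
    }
    return(list(fun = f, length = len))
  }
  e <- ev[[1]]
  if (e$type == "early_lamella") {
    p <- e$length
    w <- e$width %||% (1.4 * rif)   # neck diameter, < interface diameter
    plateau <- 0.8
  } else {
    p <- e$position
    w <- e$width
    plateau <- 0
  }
  stopifnot(p > 0, w > 0, w / 2 < rif, w / 2 < rt)
  dbc <- p + sqrt(rt^2 - (w / 2)^2)  # body sphere centre depth
  len <- dbc + rt
  f <- function(d) {
    r <- numeric(length(d))
    front <- d <= p
    dp <- pmax(d[front], 0)
    knee <- plateau * p
    r[front] <- ifelse(dp <= knee, rif,
                       rif + (w / 2 - rif) * (dp - knee) / max(p - knee, 1e-9))
    r2 <- rt^2 - (d[!front] - dbc)^2
    r[!front] <- sqrt(pmax(r2, 0))
    r
  }
  list(fun = f, length = len)
}

# Interface radius at a given frame under the coupling mode.
interface_radius_at <- function(spec, frame) {
  rif <- spec$interface_radius
  if (frame < spec$contact_frame) return(0)
  if (spec$coupling_mode == "instant") return(rif)
  g <- max(1L, round(spec$growth_time_s / spec$acquisition$frame_interval))
  k <- frame - spec$contact_frame
  if (k >= g) return(rif)
  rif * (0.3 + 0.7 * k / g)
}

# Geometry of the couple in one frame: interface centre/normal, coordinate
# fields d (depth behind the interface, into the T cell) and rho (radial
# distance from the interface axis).
couple_geometry <- function(spec, frame) {
  acq <- spec$acquisition
  dims <- c(acq$n_z, acq$n_y, acq$n_x)
  spacing <- c(acq$z_step, acq$xy_pixel, acq$xy_pixel)
  centre_idx <- floor(dims / 2) + 1
  centre <- (centre_idx - 1) * spacing
  n <- spec$axis
  cc <- coord_arrays(dims, spacing)
  dz <- cc$z - centre[1]; dy <- cc$y - centre[2]; dx <- cc$x - centre[3]
  d <- dz * n[1] + dy * n[2] + dx * n[3]
  rho2 <- pmax(dz^2 + dy^2 + dx^2 - d^2, 0)
  list(dims = dims, spacing = spacing, centre = centre, normal = n,
       d = d, rho = sqrt(rho2), dz = dz, dy = dy, dx = dx,
       r_if = interface_radius_at(spec, frame))
}

# Binary masks for one frame. Pre-contact frames displace the APC by an extra
# 2 um so no voxel adjacency exists.
couple_masks <- function(spec, frame, geom = couple_geometry(spec, frame)) {
  prof <- tcell_profile(spec)
  eps <- 1e-9
  tmask <- geom$d >= -eps & geom$d <= prof$length & geom$rho <= prof$fun(geom$d)

  # off-interface protrusions: cylinder of radius 0.5 um sticking out sideways
  # from the widest part of the body, active from their start frame
  for (e in spec$shape_events) {
    if (!identical(e$type, "off_interface_protrusion")) next
    if (frame < (e$frame %||% 1L)) next
    len <- e$length
    dc0 <- sqrt(spec$tcell_radius^2 - spec$interface_radius^2)
    base_depth <- e$depth %||% dc0
    bas <- plane_basis(geom$normal)
    # lateral coordinate along e2 from the cell surface at that depth
    s <- geom$dz * bas$e2[1] + geom$dy * bas$e2[2] + geom$dx * bas$e2[3]
    t2 <- geom$dz * bas$e1[1] + geom$dy * bas$e1[2] + geom$dx * bas$e1[3]
    r_surf <- tcell_profile(spec)$fun(base_depth)
    along <- s - r_surf
    perp <- sqrt((geom$d - base_depth)^2 + t2^2)
    tmask <- tmask | (along >= -0.25 & along <= len & perp <= 0.5)
  }

  # separation just under one voxel step along the normal, so the cells stay
  # disjoint but voxel-adjacent when in contact
  spc <- c(spec$acquisition$z_step, spec$acquisition$xy_pixel,
           spec$acquisition$xy_pixel)
  step_n <- max(abs(geom$normal) * spc)
  sep <- if (frame >= spec$contact_frame) 0.9 * step_n else 1.2
  ra <- spec$apc_radius
  rc <- max(geom$r_if, 0.5)             # APC top facet follows interface growth
  dca <- sqrt(ra^2 - min(rc, ra - 1e-6)^2)
  la <- dca + ra
  da <- -geom$d - sep
  r2a <- ra^2 - (da - dca)^2
  amask <- da >= -eps & da <= la & geom$rho <= sqrt(pmax(r2a, 0))
  amask <- amask & !tmask

  # reject geometry leaving the field of view
  border <- array(FALSE, geom$dims)
  border[c(1, geom$dims[1]), , ] <- TRUE
  border[, c(1, geom$dims[2]), ] <- TRUE
  border[, , c(1, geom$dims[3])] <- TRUE
  if (any(tmask & border) || any(amask & border))
    stop("simulated geometry exceeds the field of view")
  list(tcell = tmask, apc = amask, geom = geom)
}

# --- pattern templates -------------------------------------------------------

default_template_params <- function() {
  list(central_rel_radius = 0.5, central_depth = 1.0,
       invagination_tube_radius = 0.6, invagination_depth = 2.0,
       diffuse_depth = 0.45, lamellal_depth = 1.0,
       peripheral_rel = c(0.65, 1.1), asymmetric_rel = c(0.5, 1.1),
       asymmetric_half_angle = 60)
}

#' Render the additive accumulation component of one interface pattern
#'
#' Returns an intensity volume equal to the cellular background everywhere in
#' the T cell plus an additive accumulation component placed according to the
#' requested pattern, in units of the background (i.e. background = 1, the
#' pattern region = 1 + contrast). Voxels outside the T cell are 0.
#'
#' @param pattern one of [pattern_levels()] (`"none"` adds nothing).
#' @param tcell_mask logical 3D array (z, y, x).
#' @param interface list with `center` (z,y,x micrometres), `normal` (unit,
#'   into the T cell) and `radius` (micrometres).
#' @param contrast peak added intensity over background (>= 0).
#' @param spacing voxel spacing `c(z, y, x)` micrometres.
#' @param asym_angle_deg azimuth of the asymmetric sector centre.
#' @param params template geometry parameters; see
#'   `synapsemap:::default_template_params()`.
#' @return numeric array of relative intensities (background units).
#' @export
render_pattern_template <- function(pattern, tcell_mask, interface, contrast,
                                    spacing = c(1, 0.25, 0.25),
                                    asym_angle_deg = 0,
                                    params = default_template_params()) {
  pattern <- normalize_pattern(pattern)
  if (is.null(interface) || is.null(interface$center))
    stop("interface geometry is required to render a pattern")
  stopifnot(contrast >= 0)
  dims <- dim(tcell_mask)
  cc <- coord_arrays(dims, spacing)
  n <- interface$normal / sqrt(sum(interface$normal^2))
  dz <- cc$z - interface$center[1]
  dy <- cc$y - interface$center[2]
  dx <- cc$x - interface$center[3]
  d <- dz * n[1] + dy * n[2] + dx * n[3]
  rho <- sqrt(pmax(dz^2 + dy^2 + dx^2 - d^2, 0))
  rel <- rho / interface$radius
  eps <- 1e-9
  p <- params
  ind <- switch(pattern,
    none = array(FALSE, dims),
    central = rel <= p$central_rel_radius & d >= -eps & d <= p$central_depth,
    invagination = (rel <= p$central_rel_radius & d >= -eps & d <= p$central_depth) |
      (rho <= p$invagination_tube_radius & d >= -eps & d <= p$invagination_depth),
    diffuse = rel <= 1 & d >= -eps & d <= p$diffuse_depth,
    lamellal = rel <= 1 & d >= -eps & d <= p$lamellal_depth,
    peripheral = rel >= p$peripheral_rel[1] & rel <= p$peripheral_rel[2] &
      d >= -eps & d <= p$lamellal_depth,
    asymmetric = {
      bas <- plane_basis(n)
      u <- dz * bas$e1[1] + dy * bas$e1[2] + dx * bas$e1[3]
      v <- dz * bas$e2[1] + dy * bas$e2[2] + dx * bas$e2[3]
      ang <- atan2(v, u) * 180 / pi
      dd <- ((ang - asym_angle_deg + 180) %% 360) - 180
      rel >= p$asymmetric_rel[1] & rel <= p$asymmetric_rel[2] &
        d >= -eps & d <= p$lamellal_depth & abs(dd) <= p$asymmetric_half_angle
    })
  ind <- ind & tcell_mask
  out <- array(0, dims)
  out[tcell_mask] <- 1
  out[ind] <- 1 + contrast
  out
}

# --- couple simulation -------------------------------------------------------

schedule_labels <- function(schedule, n_frames) {
  lab <- rep(NA_character_, n_frames)
  for (i in seq_len(nrow(schedule))) {
    from <- schedule$frame[i]
    if (from > n_frames) break
    lab[from:n_frames] <- schedule$pattern[i]
  }
  lab[is.na(lab)] <- "none"
  lab
}

#' Simulate one T cell-APC couple
#'
#' Renders the full 4D acquisition of one synthetic couple, applies
#' shot + read noise (Poisson(poisson_scale x clean)/poisson_scale +
#' Gaussian(0, gauss_sigma)), quantizes to the camera bit depth, and returns
#' the image series together with the ground truth the downstream stages are
#' validated against.
#'
#' @param spec a [synth_couple_spec()].
#' @return list with components `volumes` ([volume_series()], GFP channel),
#'   `label_channel` (volume_series marking the APC), `truth` (list:
#'   `tcell_masks`, `apc_masks`, `interfaces` (per-frame list of
#'   center/normal/radius), `patterns` (per-frame label), `t0`,
#'   `contact_frame`).
#' @export
simulate_couple <- function(spec) {
  stopifnot(inherits(spec, "synth_couple_spec"))
  acq <- spec$acquisition
  set.seed(spec$seed)
  labels <- schedule_labels(spec$pattern_schedule, acq$n_frames)
  frames <- vector("list", acq$n_frames)
  lab_frames <- vector("list", acq$n_frames)
  tmasks <- vector("list", acq$n_frames)
  amasks <- vector("list", acq$n_frames)
  ifaces <- vector("list", acq$n_frames)
  qmax <- 2^acq$bit_depth - 1
  for (f in seq_len(acq$n_frames)) {
    geom <- couple_geometry(spec, f)
    mk <- couple_masks(spec, f, geom)
    iface <- if (geom$r_if > 0)
      list(center = geom$centre, normal = geom$normal, radius = geom$r_if)
    else NULL
    tmpl <- if (!is.null(iface))
      render_pattern_template(labels[f], mk$tcell, iface, spec$contrast,
                              geom$spacing, spec$asym_angle_deg)
    else { z <- array(0, geom$dims); z[mk$tcell] <- 1; z }
    clean <- spec$offset + (spec$background - spec$offset) * mk$tcell +
      spec$background * (tmpl - as.numeric(mk$tcell)) * (tmpl > 0)
    noisy <- clean
    if (spec$poisson_scale > 0)
      noisy <- rpois(length(clean), spec$poisson_scale * clean) /
        spec$poisson_scale
    if (spec$gauss_sigma > 0)
      noisy <- noisy + rnorm(length(clean), 0, spec$gauss_sigma)
    noisy <- array(pmin(pmax(round(noisy), 0), qmax), geom$dims)
    frames[[f]] <- noisy
    lab_frames[[f]] <- array(as.numeric(mk$apc) * qmax, geom$dims)
    tmasks[[f]] <- mk$tcell
    amasks[[f]] <- mk$apc
    ifaces[[f]] <- iface
  }
  ts <- (seq_len(acq$n_frames) - 1) * acq$frame_interval
  spacing <- c(acq$z_step, acq$xy_pixel, acq$xy_pixel)

  # ground-truth t0: whichever comes first of full interface width and
  # contact + 40 s
  full_frame <- spec$contact_frame +
    if (spec$coupling_mode == "instant") 0L else
      max(1L, round(spec$growth_time_s / acq$frame_interval))
  forty <- spec$contact_frame + ceiling(40 / acq$frame_interval)
  t0 <- min(min(full_frame, forty), acq$n_frames)

  list(volumes = volume_series(frames, spacing, ts,
                               meta = list(bit_depth = acq$bit_depth)),
       label_channel = volume_series(lab_frames, spacing, ts),
       truth = list(tcell_masks = tmasks, apc_masks = amasks,
                    interfaces = ifaces, patterns = labels, t0 = t0,
                    contact_frame = spec$contact_frame))
}

#' Simulate a cohort of couples with programmed pattern frequencies
#'
#' Draws each couple's per-timepoint pattern independently from the schedule's
#' frequency vector for that timepoint. Rendering the image volumes is
#' optional: frequency-level statistics only need the drawn ground-truth
#' timelines, which keeps large-n cohorts cheap.
#'
#' @param schedule a [cohort_schedule()].
#' @param base_spec a [synth_couple_spec()] used as the per-couple template
#'   when `render = TRUE` (its `pattern_schedule` and `seed` are replaced).
#' @param render if TRUE, also simulate the image volumes of every couple.
#' @return list with `condition`, `timelines` (data.frame: condition,
#'   couple_id, time_rel_s, pattern) and, when rendered, `couples` (list of
#'   [simulate_couple()] results).
#' @export
simulate_cohort <- function(schedule, base_spec = synth_couple_spec(),
                            render = FALSE) {
  stopifnot(inherits(schedule, "cohort_schedule"))
  n <- schedule$n_couples
  nt <- length(schedule$times)
  set.seed(schedule$seed)
  if (n == 0)
    return(list(condition = schedule$condition,
                timelines = data.frame(condition = character(),
                                       couple_id = integer(),
                                       time_rel_s = numeric(),
                                       pattern = character()),
                couples = list()))
  draws <- matrix("", n, nt)
  for (j in seq_len(nt))
    draws[, j] <- sample(PATTERNS, n, replace = TRUE,
                         prob = schedule$freq[j, ])
  couple_seeds <- sample.int(.Machine$integer.max - 1L, n)
  timelines <- data.frame(
    condition = schedule$condition,
    couple_id = rep(seq_len(n), each = nt),
    time_rel_s = rep(schedule$times, times = n),
    pattern = as.vector(t(draws)))
  couples <- NULL
  if (render) {
    couples <- vector("list", n)
    dt <- base_spec$acquisition$frame_interval
    for (i in seq_len(n)) {
      spec_i <- base_spec
      spec_i$seed <- couple_seeds[i]
      # map aligned times onto frames: t0 of the base spec is its ground truth
      probe <- spec_i
      probe$acquisition$n_frames <- 1L
      t0 <- min(spec_i$contact_frame +
                  (if (spec_i$coupling_mode == "instant") 0 else
                     max(1, round(spec_i$growth_time_s / dt))),
                spec_i$contact_frame + ceiling(40 / dt))
      fr <- t0 + schedule$times / dt
      keep <- fr >= 1 & fr <= spec_i$acquisition$n_frames &
        abs(fr - round(fr)) < 1e-9
      sched <- data.frame(frame = as.integer(round(fr[keep])),
                          pattern = draws[i, keep])
      if (!nrow(sched)) sched <- data.frame(frame = 1L, pattern = "none")
      spec_i$pattern_schedule <- sched
      couples[[i]] <- simulate_couple(spec_i)
    }
  }
  list(condition = schedule$condition, timelines = timelines,
       couples = couples)
}
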