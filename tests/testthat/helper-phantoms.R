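# Shared fixtures: all synthetic, generated at test time.

# One simulated couple frame plus its track, with ground truth.
sim_single <- function(pattern = "none", seed = 1, noise = TRUE,
                       axis = c(1, 0, 0), acq = acquisition_spec(n_frames = 1),
                       events = list(), contrast = 2, asym_angle_deg = 0) {
  spec <- synth_couple_spec(
    seed = seed, acquisition = acq,
    pattern_schedule = data.frame(frame = 1L, pattern = pattern),
    contrast = contrast, axis = axis, shape_events = events,
    asym_angle_deg = asym_angle_deg,
    poisson_scale = if (noise) 1 else 0, gauss_sigma = if (noise) 5 else 0)
  sim <- simulate_couple(spec)
  tr <- track_couple(sim$volumes, sim$label_channel)
  list(spec = spec, sim = sim, tr = tr,
       vol = sim$volumes$frames[[1]], spacing = sim$volumes$spacing)
}

classify_single <- function(s, frame = 1, params = classifier_params(),
                            use_truth = FALSE) {
  iface <- if (use_truth) s$sim$truth$interfaces[[frame]]
           else s$tr$interfaces[[frame]]
  msk <- if (use_truth) s$sim$truth$tcell_masks[[frame]]
         else s$tr$tcell_masks[[frame]]
  if (use_truth) {
    # ground-truth interfaces carry no contact voxel set; derive it
    iface <- interface_geometry(msk, s$sim$truth$apc_masks[[frame]],
                                s$spacing)
  }
  enr <- measure_enrichment(s$sim$volumes$frames[[frame]], msk, iface,
                            s$spacing, params)
  classify_frame(s$sim$volumes$frames[[frame]], msk, iface, enr,
                 s$spacing, params)
}

# Constructed standardized maps on the default template grid.
template_dims <- c(32L, 64L, 64L)

constructed_map <- function(values) {
  tpl <- half_spheroid_template(template_dims)
  v <- array(0, template_dims)
  v[tpl$inside] <- values
  structure(list(values = v / sum(v), dims = template_dims),
            class = "standardized_map", template = tpl)
}

uniform_map <- function() {
  tpl <- half_spheroid_template(template_dims)
  constructed_map(rep(1, tpl$n_inside))
}

mask_map <- function(zone_mask, inside_weight = 1, outside_weight = 0) {
  tpl <- half_spheroid_template(template_dims)
  w <- ifelse(zone_mask[tpl$inside], inside_weight, outside_weight)
  constructed_map(w)
}

# Standardized map from a rendered single-frame couple.
map_single <- function(pattern, seed, axis = c(1, 0, 0),
                       acq = acquisition_spec(n_frames = 1), noise = TRUE,
                       use_truth = FALSE) {
  s <- sim_single(pattern, seed = seed, axis = axis, acq = acq, noise = noise)
  msk <- if (use_truth) s$sim$truth$tcell_masks[[1]] else s$tr$tcell_masks[[1]]
  iface <- if (use_truth)
    interface_geometry(msk, s$sim$truth$apc_masks[[1]], s$spacing)
  else s$tr$interfaces[[1]]
  reo <- reorient_interface_up(msk, s$vol, iface, s$spacing)
  standardize_half_spheroid(reo)
}

# Frequency row helper: named vector over the 7 patterns.
freq_row <- function(...) {
  v <- stats::setNames(numeric(7), pattern_levels())
  args <- c(...)
  v[names(args)] <- args
  v["none"] <- 1 - sum(v[setdiff(names(v), "none")])
  v
}
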