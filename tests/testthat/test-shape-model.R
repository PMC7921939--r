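# Reorientation, half-spheroid standardization and enrichment ratios.

test_that("an upright isotropic cell reorients by the identity", {
  # small isotropic acquisition so input and output grids coincide
  acq <- acquisition_spec(n_z = 40, z_step = 0.25, n_y = 40, n_x = 40,
                          n_frames = 1)
  spec <- synth_couple_spec(seed = 20, acquisition = acq, tcell_radius = 2,
                            apc_radius = 1.6, interface_radius = 1.2,
                            poisson_scale = 0, gauss_sigma = 0)
  sim <- simulate_couple(spec)
  msk <- sim$truth$tcell_masks[[1]]
  iface <- interface_geometry(msk, sim$truth$apc_masks[[1]],
                              sim$volumes$spacing)
  reo <- reorient_interface_up(msk, sim$volumes$frames[[1]], iface,
                               sim$volumes$spacing, out_spacing = 0.25)
  # every output voxel must equal the input voxel it sits on
  o <- reo$origin_index
  ctr_idx <- round(iface$center / sim$volumes$spacing) + 1
  for (probe in list(c(0, 0, 0), c(3, 2, -1), c(6, -4, 5))) {
    out_v <- reo$volume[o[1] + probe[1], o[2] + probe[2], o[3] + probe[3]]
    in_v <- sim$volumes$frames[[1]][ctr_idx[1] + probe[1],
                                    ctr_idx[2] + probe[2],
                                    ctr_idx[3] + probe[3]]
    expect_identical(out_v, in_v)
  }
})

test_that("rotation about the optical axis reorients to the same map", {
  acqw <- acquisition_spec(n_frames = 1, n_x = 96, n_y = 96)
  m1 <- map_single("central", seed = 21, axis = c(0, 0, 1), acq = acqw,
                   noise = FALSE, use_truth = TRUE)
  m2 <- map_single("central", seed = 21, axis = c(0, 1, 0), acq = acqw,
                   noise = FALSE, use_truth = TRUE)
  expect_gt(stats::cor(as.numeric(m1$values), as.numeric(m2$values)), 0.99)
})

test_that("an antiparallel normal gives a 180-degree rotation", {
  up <- sim_single("none", seed = 22, noise = FALSE, axis = c(1, 0, 0))
  dn <- sim_single("none", seed = 22, noise = FALSE, axis = c(-1, 0, 0))
  depth_centroid <- function(s) {
    msk <- s$tr$tcell_masks[[1]]
    i <- s$tr$interfaces[[1]]
    reo <- reorient_interface_up(msk, s$vol, i, s$spacing)
    idx <- which(reo$mask, arr.ind = TRUE)
    mean(idx[, 1] - reo$origin_index[1]) * reo$spacing[1]
  }
  expect_lt(abs(depth_centroid(up) - depth_centroid(dn)), 0.25)
})

test_that("uniform cells standardize to a uniform probability map", {
  m <- map_single("none", seed = 23, noise = FALSE)
  tpl <- half_spheroid_template(m$dims)
  v <- m$values[tpl$inside]
  expect_equal(sum(m$values), 1, tolerance = 1e-9)
  expect_true(all(m$values >= 0))
  expect_lte(stats::sd(v) / mean(v), 0.05)
})

test_that("cells of different radii with the same relative accumulation map alike", {
  big <- map_single("central", seed = 24, noise = FALSE)
  small_acq <- acquisition_spec(n_frames = 1)
  spec <- synth_couple_spec(seed = 25, acquisition = small_acq,
                            tcell_radius = 4, apc_radius = 3.2,
                            interface_radius = 2.4,
                            pattern_schedule = data.frame(frame = 1, pattern = "central"),
                            poisson_scale = 0, gauss_sigma = 0)
  sim <- simulate_couple(spec)
  tr <- track_couple(sim$volumes, sim$label_channel)
  reo <- reorient_interface_up(tr$tcell_masks[[1]], sim$volumes$frames[[1]],
                               tr$interfaces[[1]], sim$volumes$spacing)
  small <- standardize_half_spheroid(reo)
  # same relative geometry; residual L1 reflects voxel discretization of the
  # pattern edge at the two cell sizes
  expect_lt(sum(abs(big$values - small$values)), 0.1)
})

test_that("the enrichment region is the top decile with deterministic ties", {
  u <- uniform_map()
  reg <- build_enrichment_region(list(u))
  tpl <- half_spheroid_template(template_dims)
  expect_equal(reg$n_region, round(0.10 * tpl$n_inside))
  expect_equal(sum(reg$mask), reg$n_region)
  # all-ties input: region must be reproducible
  reg2 <- build_enrichment_region(list(u))
  expect_identical(reg$mask, reg2$mask)
  expect_error(build_enrichment_region(list()), "empty")
})

test_that("region from central-loaded cohorts concentrates under the interface centre", {
  core <- core_cylinder_mask(template_dims, 0.5, 0.5)
  maps <- lapply(1:4, function(i) mask_map(core, inside_weight = 1,
                                           outside_weight = 0.05))
  reg <- build_enrichment_region(maps)
  tpl <- half_spheroid_template(template_dims)
  inside_core <- sum(reg$mask & core) / reg$n_region
  expect_gte(inside_core, 0.8)
})

test_that("enrichment and core ratios have exact closed forms", {
  u <- uniform_map()
  reg <- build_enrichment_region(list(u))
  expect_equal(enrichment_ratio(u, reg), 1.0, tolerance = 1e-6)
  expect_equal(central_core_ratio(u), 1.0, tolerance = 1e-6)
  # all mass inside the region
  m_in <- mask_map(reg$mask, 1, 0)
  expect_equal(enrichment_ratio(m_in, reg), reg$n_total / reg$n_region,
               tolerance = 1e-6)
  # no mass in the region
  m_out <- mask_map(reg$mask, 0, 1)
  expect_equal(enrichment_ratio(m_out, reg), 0.0)
  # all mass in the core: template/core voxel-count quotient
  core <- core_cylinder_mask(template_dims, 0.5, 0.5)
  tpl <- half_spheroid_template(template_dims)
  m_core <- mask_map(core, 1, 0)
  expect_equal(central_core_ratio(m_core), tpl$n_inside / sum(core),
               tolerance = 1e-6)
})

test_that("enrichment ratio rises strictly with mass placed in the region", {
  u <- uniform_map()
  reg <- build_enrichment_region(list(u))
  r <- vapply(c(0.1, 0.3, 0.5, 0.8), function(lam)
    enrichment_ratio(mask_map(reg$mask, lam / reg$n_region,
                              (1 - lam) / (reg$n_total - reg$n_region)), reg),
    numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("central maps score higher core ratios than peripheral maps", {
  for (seed in 41:45) {
    mc <- map_single("central", seed = seed)
    mp <- map_single("peripheral", seed = seed + 100)
    expect_gt(central_core_ratio(mc), central_core_ratio(mp))
  }
})
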