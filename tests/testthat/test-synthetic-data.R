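# Synthetic couple and cohort generator.

test_that("simulation is bit-reproducible given the spec", {
  spec <- synth_couple_spec(seed = 11, acquisition = acquisition_spec(n_frames = 2),
                            pattern_schedule = data.frame(frame = 1, pattern = "central"))
  a <- simulate_couple(spec)
  b <- simulate_couple(spec)
  expect_identical(a$volumes$frames, b$volumes$frames)
  expect_identical(a$truth$tcell_masks, b$truth$tcell_masks)
  expect_identical(a$truth$patterns, b$truth$patterns)
})

test_that("default acquisition matches the spinning-disk protocol", {
  spec <- synth_couple_spec(seed = 1, acquisition = acquisition_spec(n_frames = 3))
  sim <- simulate_couple(spec)
  expect_equal(dim(sim$volumes$frames[[1]])[1], 21)
  expect_equal(sim$volumes$spacing, c(z = 1, y = 0.25, x = 0.25))
  expect_equal(diff(sim$volumes$timestamps), c(20, 20))
})

test_that("patterns add intensity only inside the T cell; none adds nothing", {
  s <- sim_single("none", seed = 2, noise = FALSE)
  msk <- s$sim$truth$tcell_masks[[1]]
  iface <- s$sim$truth$interfaces[[1]]
  base <- render_pattern_template("none", msk, iface, contrast = 2, s$spacing)
  expect_true(all(base[msk] == 1))        # flat background in the cell
  expect_true(all(base[!msk] == 0))
  for (p in setdiff(pattern_levels(), "none")) {
    tmpl <- render_pattern_template(p, msk, iface, contrast = 2, s$spacing)
    expect_identical(tmpl[!msk], base[!msk])   # conservation outside the cell
    expect_gt(sum(tmpl), sum(base))            # some accumulation inside
  }
  expect_error(render_pattern_template("vortex", msk, iface, 2, s$spacing),
               "unknown pattern")
  expect_error(render_pattern_template("central", msk, NULL, 2, s$spacing),
               "interface")
})

test_that("central template clears the 35% accumulation gate at contrast 2", {
  s <- sim_single("central", seed = 3, noise = FALSE)
  msk <- s$sim$truth$tcell_masks[[1]]
  iface <- interface_geometry(msk, s$sim$truth$apc_masks[[1]], s$spacing)
  enr <- measure_enrichment(s$vol, msk, iface, s$spacing)
  expect_gte(enr$interface_mean / enr$background_mean, 1.35)
})

test_that("peripheral template leaves the central disc empty", {
  s <- sim_single("peripheral", seed = 4, noise = FALSE)
  msk <- s$sim$truth$tcell_masks[[1]]
  iface <- s$sim$truth$interfaces[[1]]
  tmpl <- render_pattern_template("peripheral", msk, iface, 2, s$spacing)
  added <- (tmpl - 1) * (tmpl > 0)
  # brute-force voxel sums in cylindrical zones about the true axis
  cc <- synapsemap:::coord_arrays(dim(msk), s$spacing)
  d <- (cc$z - iface$center[1]) * iface$normal[1] +
       (cc$y - iface$center[2]) * iface$normal[2] +
       (cc$x - iface$center[3]) * iface$normal[3]
  rho <- sqrt(pmax((cc$z - iface$center[1])^2 + (cc$y - iface$center[2])^2 +
                   (cc$x - iface$center[3])^2 - d^2, 0))
  shellish <- msk & d >= 0 & d <= 1
  central <- shellish & rho < 0.5 * iface$radius
  annulus <- shellish & rho >= 0.5 * iface$radius
  expect_lt(mean(added[central]), 0.1 * mean(added[annulus]))
})

test_that("cohort draws recover programmed frequencies at 1/sqrt(n)", {
  f <- freq_row(central = 0.42, invagination = 0.13)
  sch <- cohort_schedule("Teff_pep", 10000, times = 20,
                         freq = matrix(f, 1, dimnames = list(NULL, names(f))),
                         seed = 5)
  co <- simulate_cohort(sch)
  expect_equal(nrow(co$timelines), 10000)
  for (pat in c("central", "invagination")) {
    phat <- mean(co$timelines$pattern == pat)
    p0 <- f[[pat]]
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  }
})

test_that("degenerate cohorts behave", {
  f <- freq_row()
  m <- matrix(f, 1, dimnames = list(NULL, names(f)))
  expect_equal(nrow(simulate_cohort(cohort_schedule("c", 0, 20, m))$timelines), 0)
  co <- simulate_cohort(cohort_schedule("c", 60, 20, m, seed = 2))
  expect_true(all(co$timelines$pattern == "none"))
  bad <- m; bad[1, "central"] <- 0.5
  expect_error(cohort_schedule("c", 5, 20, bad), "sum to 1")
})

test_that("geometry leaving the field of view is rejected", {
  spec <- synth_couple_spec(seed = 1, acquisition = acquisition_spec(n_y = 32, n_x = 32))
  expect_error(simulate_couple(spec), "field of view")
  expect_error(synth_couple_spec(pattern_schedule = data.frame(
    frame = c(3, 2), pattern = c("none", "central"))), "strictly increasing")
})

test_that("zero-contrast couples give unit enrichment on average", {
  ratios <- vapply(1:50, function(k) {
    spec <- synth_couple_spec(seed = 500 + k,
                              acquisition = acquisition_spec(n_frames = 1),
                              contrast = 0)
    sim <- simulate_couple(spec)
    msk <- sim$truth$tcell_masks[[1]]
    iface <- interface_geometry(msk, sim$truth$apc_masks[[1]],
                                sim$volumes$spacing)
    enr <- measure_enrichment(sim$volumes$frames[[1]], msk, iface,
                              sim$volumes$spacing)
    enr$interface_mean / enr$background_mean
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("rendered templates are pairwise separable in classifier statistics", {
  labs <- setdiff(pattern_levels(), "none")
  set.seed(99)
  for (seed in c(21, 22)) {
    got <- vapply(labs, function(p) {
      s <- sim_single(p, seed = seed, asym_angle_deg = runif(1, 0, 360))
      classify_single(s)
    }, character(1))
    expect_equal(unname(got), labs)
  }
})
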