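# Interface diameter, cell width/length, neck and lamella scoring.

acq_side <- acquisition_spec(n_frames = 1, n_x = 112)

side_phantom <- function(events, seed = 3) {
  sim_single("none", seed = seed, noise = FALSE, axis = c(0, 0, 1),
             acq = acq_side, events = events)
}

test_that("sphere with a contact disc recovers its closed-form axes", {
  s <- sim_single("none", seed = 2, noise = FALSE)
  ax <- measure_axes(s$tr$tcell_masks[[1]], s$tr$interfaces[[1]], s$spacing)
  expect_lt(abs(ax$interface_diameter - 6), 0.5)
  expect_lt(abs(ax$cell_width - 10), 0.5)
  # straight cell: arc length equals the interface-to-pole distance
  expect_lt(abs(ax$cell_length - 9), 0.5)
  # convex profile: no neck, not scorable
  lam <- score_lamella(ax$profile, ax$interface_diameter)
  expect_false(lam$has_scorable_lamella)
})

test_that("the >1.3 um neck rule is sharp on neck phantoms", {
  for (cfg in list(list(p = 1.1, scorable = FALSE),
                   list(p = 1.5, scorable = TRUE),
                   list(p = 2.0, scorable = TRUE))) {
    s <- side_phantom(list(list(type = "neck", position = cfg$p, width = 3.0)))
    ax <- measure_axes(s$tr$tcell_masks[[1]], s$tr$interfaces[[1]], s$spacing)
    lam <- score_lamella(ax$profile, ax$interface_diameter)
    expect_equal(lam$has_scorable_lamella, cfg$scorable, info = cfg$p)
    if (cfg$scorable)
      expect_lt(abs(lam$lamellal_length - cfg$p), 0.3)
  }
})

test_that("early lamellae are scorable with the programmed length", {
  s <- side_phantom(list(list(type = "early_lamella", length = 2.5)))
  ax <- measure_axes(s$tr$tcell_masks[[1]], s$tr$interfaces[[1]], s$spacing)
  lam <- score_lamella(ax$profile, ax$interface_diameter)
  expect_true(lam$has_scorable_lamella)
  expect_lt(abs(lam$lamellal_length - 2.5), 0.5)
  sf <- shape_factor(lam$lamellal_length, ax$interface_diameter)
  expect_gt(sf, 0); expect_lt(sf, 1)
})

test_that("shape factor is the exact quotient", {
  expect_identical(shape_factor(3, 6), 0.5)
  expect_identical(shape_factor(0, 6), 0)
  expect_identical(shape_factor(6, 6), 1)
  expect_error(shape_factor(3, 0), "positive")
})

test_that("cell length follows a bent midline", {
  # quarter-torus tube: centreline radius 4 um, tube radius 1.5 um,
  # closed-form arc length pi/2 * 4 = 6.283 um
  sp <- rep(0.25, 3)
  dm <- c(60, 60, 60)
  cc <- synapsemap:::coord_arrays(dm, sp)
  cx <- 3; cy <- 7.5   # torus centre in the (z, y) plane at x = 3
  Rc <- 4; rt <- 1.5
  zz <- cc$z - cx; yy <- cc$y - cy
  rad <- sqrt(zz^2 + yy^2)
  mask <- array((rad - Rc)^2 + (cc$x - 3)^2 <= rt^2 & zz >= 0 & yy <= 0, dm)
  iface <- list(center = c(cx, cy - Rc, 3), normal = c(1, 0, 0),
                radius = rt, diameter = 2 * rt)
  ax <- measure_axes(mask, iface, sp)
  expect_lt(abs(ax$cell_length - pi / 2 * Rc) / (pi / 2 * Rc), 0.05)
})

test_that("off-interface protrusions are detected only where programmed", {
  s <- sim_single("none", seed = 4, noise = FALSE,
                  acq = acquisition_spec(n_frames = 2),
                  events = list(list(type = "off_interface_protrusion",
                                     frame = 2, length = 2.0)))
  expect_false(detect_off_interface_lamella(s$tr$tcell_masks[[1]],
                                            s$tr$interfaces[[1]], s$spacing))
  expect_true(detect_off_interface_lamella(s$tr$tcell_masks[[2]],
                                           s$tr$interfaces[[2]], s$spacing))
})

test_that("interface lamellae do not count as off-interface", {
  s <- side_phantom(list(list(type = "early_lamella", length = 2.5)))
  expect_false(detect_off_interface_lamella(s$tr$tcell_masks[[1]],
                                            s$tr$interfaces[[1]], s$spacing))
})

test_that("shape factor is invariant under joint scaling of mask and spacing", {
  s <- side_phantom(list(list(type = "neck", position = 2.0, width = 3.0)))
  msk <- s$tr$tcell_masks[[1]]
  i <- s$tr$interfaces[[1]]
  sf_at <- function(k) {
    i2 <- i; i2$center <- i$center * k; i2$diameter <- i$diameter * k
    i2$radius <- i$radius * k
    ax <- measure_axes(msk, i2, s$spacing * k)
    lam <- score_lamella(ax$profile, ax$interface_diameter,
                         neck_min = 1.3 * k)
    shape_factor(lam$lamellal_length, ax$interface_diameter)
  }
  expect_equal(sf_at(2), sf_at(1), tolerance = 1e-9)
})

test_that("manual annotations agree with the automatic path", {
  s <- side_phantom(list(list(type = "neck", position = 2.0, width = 3.0)))
  ax <- measure_axes(s$tr$tcell_masks[[1]], s$tr$interfaces[[1]], s$spacing)
  lam <- score_lamella(ax$profile, ax$interface_diameter)
  ann <- data.frame(
    couple_id = 1, time_rel_s = 0,
    line_type = c("interface_diameter", "cell_width", "lamellal_length",
                  "cell_length"),
    x1 = 0, y1 = 0,
    x2 = c(6, 10, 2, 2 + sqrt(25 - 1.5^2) + 5), y2 = 0)
  man <- measure_from_annotations(ann)
  expect_lt(abs(man$interface_diameter - ax$interface_diameter) / 6, 0.1)
  expect_lt(abs(man$cell_width - ax$cell_width) / 10, 0.1)
  expect_lt(abs(man$lamellal_length - lam$lamellal_length) / 2, 0.1)
  expect_lt(abs(man$cell_length - ax$cell_length) / man$cell_length, 0.1)
  expect_true(man$has_scorable_lamella)
  expect_equal(man$shape_factor, 2 / 6, tolerance = 1e-9)
})
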