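# Cohort aggregation: frequencies, log2 ratio, cumulative curves, tests.

toy_timelines <- function(patterns, times = 0) {
  expand_idx <- expand.grid(couple_id = seq_along(patterns),
                            time_rel_s = times)
  data.frame(condition = "toy", couple_id = expand_idx$couple_id,
             time_rel_s = expand_idx$time_rel_s,
             pattern = patterns[expand_idx$couple_id])
}

test_that("percentages partition and degenerate cohorts are exact", {
  tab <- pattern_frequencies(toy_timelines(rep("central", 10)))
  expect_equal(tab$percent[tab$pattern == "central"], 100)
  expect_equal(tab$percent[tab$pattern == "invagination"], 0)
  expect_equal(tab$percent[tab$pattern == "any"], 100)
  mixed <- pattern_frequencies(toy_timelines(c(rep("central", 3),
                                               rep("none", 5),
                                               rep("lamellal", 2))))
  by7 <- mixed[mixed$pattern %in% pattern_levels(), ]
  expect_equal(sum(by7$percent), 100, tolerance = 1e-9)
  expect_equal(mixed$percent[mixed$pattern == "any"], 50)
})

test_that("programmed frequencies are recovered within binomial error", {
  f <- freq_row(central = 0.42, invagination = 0.13, diffuse = 0.05)
  sch <- cohort_schedule("Teff_pep", 10000, 20,
                         matrix(f, 1, dimnames = list(NULL, names(f))),
                         seed = 7)
  tab <- pattern_frequencies(simulate_cohort(sch)$timelines)
  for (pat in c("central", "invagination")) {
    p0 <- 100 * f[[pat]]
    row <- tab[tab$pattern == pat, ]
    expect_lt(abs(row$percent - p0), 3 * 100 * sqrt(f[[pat]] * (1 - f[[pat]]) / 10000))
  }
  p_any <- 100 * (1 - f[["none"]])
  expect_lt(abs(tab$percent[tab$pattern == "any"] - p_any), 3 * 0.5)
})

test_that("log2 central/invagination ratio follows the continuity-corrected form", {
  tl <- toy_timelines(c(rep("central", 40), rep("invagination", 10),
                        rep("none", 50)))
  rs <- central_invagination_ratio(pattern_frequencies(tl))
  expect_equal(rs$log2_ratio, log2(40.5 / 10.5), tolerance = 1e-12)
  expect_lt(abs(rs$log2_ratio - 2), 0.1)
  # the study scenario 42 vs 13 per 100: positive, central-preferring
  tl2 <- toy_timelines(c(rep("central", 42), rep("invagination", 13),
                         rep("none", 45)))
  rs2 <- central_invagination_ratio(pattern_frequencies(tl2))
  expect_equal(rs2$log2_ratio, log2(42.5 / 13.5), tolerance = 1e-12)
  expect_gt(rs2$log2_ratio, 0)
  # equal counts -> exactly zero
  tl3 <- toy_timelines(c(rep("central", 7), rep("invagination", 7)))
  expect_equal(central_invagination_ratio(pattern_frequencies(tl3))$log2_ratio, 0)
})

test_that("ratio sign tracks the central vs invagination comparison", {
  for (counts in list(c(30, 5), c(5, 30), c(12, 11))) {
    tl <- toy_timelines(c(rep("central", counts[1]),
                          rep("invagination", counts[2]), rep("none", 20)))
    rs <- central_invagination_ratio(pattern_frequencies(tl))
    expect_equal(rs$log2_ratio > 0, counts[1] > counts[2])
  }
})

test_that("cumulative off-interface curve equals the flag-time CDF", {
  flag_times <- c(20, 60, 60, 140, NA, NA)   # NA: never flagged
  rows <- list()
  for (i in seq_along(flag_times)) for (tt in seq(20, 200, 20))
    rows[[length(rows) + 1]] <- data.frame(
      couple_id = i, time_rel_s = tt,
      has_off_interface_lamella = !is.na(flag_times[i]) && tt >= flag_times[i])
  flags <- do.call(rbind, rows)
  cu <- cumulative_off_interface(flags, grid = seq(20, 200, 20))
  cdf <- vapply(seq(20, 200, 20),
                function(tt) 100 * sum(!is.na(flag_times) & flag_times <= tt) /
                  length(flag_times), numeric(1))
  expect_equal(cu$cumulative_percent, cdf)
  expect_true(all(diff(cu$cumulative_percent) >= 0))
  none <- flags; none$has_off_interface_lamella <- FALSE
  expect_true(all(cumulative_off_interface(none)$cumulative_percent == 0))
})

test_that("condition comparison matches an exact hypergeometric oracle", {
  ta <- pattern_frequencies(toy_timelines(c(rep("central", 42), rep("none", 58))))
  tb <- pattern_frequencies(toy_timelines(c(rep("central", 5), rep("none", 95))))
  cmp <- compare_conditions(ta, tb, patterns = "central")
  expect_lt(cmp$p_raw, 0.001)
  # brute-force two-sided Fisher p: sum of all tables as or less probable
  k <- 42 + 5; n1 <- 100; n2 <- 100
  dens <- dhyper(0:k, n1, n2, k)
  p_oracle <- sum(dens[dens <= dhyper(42, n1, n2, k) * (1 + 1e-7)])
  expect_equal(cmp$p_raw, p_oracle, tolerance = 1e-9)
  # identical tables: p = 1
  same <- compare_conditions(ta, ta, patterns = "central")
  expect_equal(same$p_raw, 1)
  # Holm never decreases p
  multi <- compare_conditions(
    pattern_frequencies(toy_timelines(rep(c("central", "none"), 30),
                                      times = c(0, 20, 40))),
    pattern_frequencies(toy_timelines(rep(c("central", "none", "none"), 20),
                                      times = c(0, 20, 40))),
    patterns = "central")
  expect_true(all(multi$p_adjusted >= multi$p_raw))
})

test_that("per-experiment dispersion mode reports SEM across experiments", {
  tl <- toy_timelines(c(rep("central", 30), rep("none", 30)))
  tl$experiment <- rep(1:3, length.out = nrow(tl))
  tab <- pattern_frequencies(tl, se_mode = "experiment")
  expect_true(all(is.finite(tab$se[tab$pattern == "central"])))
  expect_error(pattern_frequencies(toy_timelines("central"),
                                   se_mode = "experiment"), "experiment")
})
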