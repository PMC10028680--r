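test_that("ribbon compositions are valid partial-volume mixtures", {
  rib <- make_ribbon()
  expect_equal(nrow(rib), 11)
  frac <- as.matrix(rib[, c("GM", "WM", "CSF", "arterial", "venous")])
  expect_true(all(frac >= 0))
  expect_equal(unname(rowSums(frac)), rep(1, 11), tolerance = 1e-12)
  # venous fraction strictly increases toward the pial surface
  expect_true(all(diff(rib$venous) > 0))
  expect_gt(rib$venous[11], rib$venous[1])
  # jittered ribbons keep the gradient and are seed-reproducible
  r1 <- make_ribbon(jitter_sd = 0.2, seed = 7)
  r2 <- make_ribbon(jitter_sd = 0.2, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$venous) > 0))
  # zero vasculature: pure gray matter
  pure <- make_ribbon(venous_range = c(0, 0), arterial_range = c(0, 0))
  expect_equal(pure$GM, rep(1, 11))
  expect_error(make_ribbon(n_depths = 2), "n_depths")
  expect_error(make_ribbon(venous_range = c(0.9, 0.99),
                           arterial_range = c(0.2, 0.2)), "sum to 1")
})

test_that("time series are deterministic under a seed and flat without an effect", {
  rib <- make_ribbon(n_depths = 5)
  set <- default_compartments()
  sch <- abc_scheme()
  eff0 <- functional_effect(0, 0, n_blocks = 2, noise_sd = 0)
  flat <- simulate_timeseries(rib, sch, set, eff0)
  expect_equal(max(apply(unclass(flat), 2, stats::sd)), 0, tolerance = 1e-14)
  expect_equal(unname(unclass(flat)[1, ]), unname(attr(flat, "baseline")),
               tolerance = 1e-12)
  effn <- functional_effect(n_blocks = 2, noise_sd = 0.01, seed = 11)
  a <- simulate_timeseries(rib, sch, set, effn)
  b <- simulate_timeseries(rib, sch, set, effn)
  expect_identical(unclass(a), unclass(b))
})

test_that("noiseless epoch averaging recovers the configured composite effect", {
  rib <- make_ribbon(n_depths = 5)
  set <- default_compartments()
  eff <- functional_effect(delta_arterial_volume = 0.01,
                           delta_venous_signal = 0.01, n_blocks = 3,
                           noise_sd = 0)
  bold <- simulate_timeseries(rib, abc_scheme(), set, eff, "BOLD")
  psc <- percent_signal_change(bold)
  # in the unprepared contrast all weights are 1: the volume reallocation
  # cancels and only the venous signal change survives the mixing equation
  expect_equal(psc, rib$venous * 0.01 * 100, tolerance = 1e-6)
  # mixing linearity: ON-OFF difference equals the closed-form prediction
  abc <- simulate_timeseries(rib, abc_scheme(), set, eff, "ABC")
  supp <- attr(abc, "suppression")
  d <- unclass(abc)[which(attr(abc, "design") == 1L)[1], ] -
    unclass(abc)[which(attr(abc, "design") == 0L)[1], ]
  pred <- 0.01 * ((1 - supp[["arterial"]]) - (1 - supp[["GM"]])) +
    rib$venous * (1 - supp[["venous"]]) * 0.01
  expect_equal(unname(d), unname(pred), tolerance = 1e-12)
})

test_that("pure noise averages to no signal change", {
  rib <- make_ribbon(n_depths = 4)
  set <- default_compartments()
  eff <- functional_effect(0, 0, n_blocks = 40, noise_sd = 0.01, seed = 3)
  ser <- simulate_timeseries(rib, abc_scheme(), set, eff, "BOLD")
  psc <- percent_signal_change(ser)
  # ~120 retained volumes per condition: SE of the contrast ~ 0.13%
  expect_lt(max(abs(psc)), 0.5)
})

test_that("ratio maps divide, mask and stay consistent with the prediction", {
  x <- matrix(c(0.8, 0.4, 0.2, 0.1), 2, 2)
  expect_equal(mtr_map(x, x), matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(mtr_map(0.8 * x, x), matrix(0.8, 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  masked <- mtr_map(x, matrix(c(1, 1, 0.01, 1), 2, 2))
  expect_true(is.na(masked[1, 2]))
  expect_equal(attr(masked, "n_masked"), 1L)
  expect_error(mtr_map(x, matrix(1, 3, 3)), "equal shapes")
  # end-to-end: a ribbon's ABC/BOLD baseline ratio matches mtr_predict
  rib <- make_ribbon(n_depths = 4, venous_range = c(0, 0),
                     arterial_range = c(0, 0))
  set <- default_compartments()
  eff <- functional_effect(0, 0, n_blocks = 2, noise_sd = 0)
  abc <- simulate_timeseries(rib, abc_scheme(), set, eff, "ABC")
  bold <- simulate_timeseries(rib, abc_scheme(), set, eff, "BOLD")
  ratio <- mtr_map(abc, bold)
  mt <- mtr_predict(abc_scheme(), set)
  expect_equal(unname(ratio[1, 1]), mt$mtr[mt$compartment == "GM"],
               tolerance = 1e-9)
})

test_that("saturation preparation reduces the pial bias of the depth profile", {
  rib <- make_ribbon()
  set <- default_compartments()
  eff <- functional_effect(n_blocks = 4, noise_sd = 0)
  bold <- simulate_timeseries(rib, abc_scheme(), set, eff, "BOLD")
  abc <- simulate_timeseries(rib, abc_scheme(), set, eff, "ABC")
  prof_bold <- depth_profile(bold)
  expect_true(all(diff(as.numeric(prof_bold)) > 0))  # pial-ward bias
  iso <- mtr_map(abc, bold)
  prof_iso <- depth_profile(iso, design = attr(abc, "design"))
  expect_lt(attr(prof_iso, "pial_deep_ratio"),
            attr(prof_bold, "pial_deep_ratio"))
  # venous-dominated voxels lose more functional response under saturation
  # than arterial-dominated ones
  ven_rib <- make_ribbon(n_depths = 3, venous_range = c(0.1, 0.12),
                         arterial_range = c(0, 0))
  art_rib <- make_ribbon(n_depths = 3, venous_range = c(0, 0),
                         arterial_range = c(0.1, 0.12))
  drop_for <- function(r) {
    b <- percent_signal_change(simulate_timeseries(r, abc_scheme(), set, eff, "BOLD"))
    a <- percent_signal_change(simulate_timeseries(r, abc_scheme(), set, eff, "ABC"))
    mean(b - a)
  }
  expect_gt(drop_for(ven_rib), drop_for(art_rib))
})

test_that("degenerate designs are rejected", {
  rib <- make_ribbon(n_depths = 3)
  set <- default_compartments()
  eff1 <- functional_effect(n_blocks = 1, noise_sd = 0)
  ser <- simulate_timeseries(rib, abc_scheme(), set, eff1, "BOLD")
  expect_error(percent_signal_change(ser), "blocks")
  expect_error(percent_signal_change(matrix(1, 10, 2)), "design")
  expect_error(functional_effect(noise_sd = -1), "noise_sd")
  big <- functional_effect(delta_arterial_volume = 0.99, n_blocks = 2)
  expect_error(simulate_timeseries(rib, abc_scheme(), set, big, "BOLD"),
               "exceeds the gray-matter fraction")
})
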