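test_that("detailed balance completes the exchange-rate pair", {
  expect_equal(derive_exchange(0.5, 10), 10)
  expect_equal(derive_exchange(0, 123), 0)
  expect_equal(derive_exchange(0.15, 20), 20 * 0.15 / 0.85, tolerance = 1e-12)
  expect_error(derive_exchange(1, 10), "f must be")
  expect_error(derive_exchange(0.5, -1), "km")
  tis <- gm_tissue(km = 20)
  expect_equal((1 - tis$f) * tis$kf_s, tis$f * tis$km_s, tolerance = 1e-12)
})

test_that("coupled relaxation has the right limits", {
  tis <- gm_tissue()
  s0 <- coupled_state(0.2, 0.9)
  expect_equal(as.numeric(coupled_relax(s0, tis, 0)), as.numeric(s0))
  # long-time limit: full recovery
  far <- coupled_relax(s0, tis, 50 * 2500)
  expect_lt(max(abs(as.numeric(far))), 1e-8)
  # no macromolecular pool: exact monoexponential free-pool decay
  liq <- liquid_tissue()
  s <- coupled_relax(coupled_state(0.37, 0), liq, 100)
  expect_equal(s[["szf"]], 0.37 * exp(-100 / 2500), tolerance = 1e-12)
  expect_error(coupled_relax(s0, tis, -1), ">= 0")
})

test_that("the eigen-solution matches step-wise numerical integration", {
  tis <- gm_tissue()
  s0 <- coupled_state(0, 0.925)
  tgrid <- seq(1, 381, by = 5)
  ora <- ode_oracle(tis, s0, tgrid)
  ours <- t(vapply(tgrid, function(t) {
    as.numeric(coupled_relax(s0, tis, t))
  }, numeric(2)))
  expect_lt(max(abs(ours - ora)), 1e-6)
})

test_that("eigen/ODE agreement holds across random physical parameters", {
  set.seed(421)
  for (i in 1:25) {
    tis <- tissue_params(
      pool_params(runif(1, 500, 4000), 100),
      pool_params(runif(1, 100, 1000), 0.070),
      f = runif(1, 0.02, 0.45), km_s = runif(1, 0.1, 60)
    )
    s0 <- coupled_state(runif(1), runif(1))
    tgrid <- seq(10, 2000, length.out = 15)
    ora <- ode_oracle(tis, s0, tgrid)
    ours <- t(vapply(tgrid, function(t) as.numeric(coupled_relax(s0, tis, t)),
                     numeric(2)))
    expect_lt(max(abs(ours - ora)), 1e-6)
  }
})

test_that("decay rates are real, positive and ordered; amplitudes sum to Szf(0)", {
  set.seed(99)
  for (i in 1:20) {
    tis <- tissue_params(
      pool_params(runif(1, 500, 4000), 100),
      pool_params(runif(1, 100, 1000), 0.070),
      f = runif(1, 0.02, 0.45), km_s = runif(1, 0.1, 60)
    )
    s0 <- coupled_state(runif(1), runif(1))
    bi <- biexp_solution(tis, s0)
    expect_true(is.double(bi$lambda1_s) && is.double(bi$lambda2_s))
    expect_gt(bi$lambda2_s, 0)
    expect_gte(bi$lambda1_s, bi$lambda2_s)
    expect_equal(bi$a1 + bi$a2, s0[["szf"]], tolerance = 1e-10)
    # the closed form it describes matches coupled_relax
    t <- runif(1, 0, 1000)
    expect_equal(bi$a1 * exp(-bi$lambda1_s * t / 1000) +
                   bi$a2 * exp(-bi$lambda2_s * t / 1000),
                 coupled_relax(s0, tis, t)[["szf"]], tolerance = 1e-9)
  }
})

test_that("exchange alone conserves pool-weighted longitudinal magnetization", {
  tis <- tissue_params(pool_params(Inf, 900), pool_params(Inf, 0.070),
                       f = 0.15, km_s = 5)
  s0 <- coupled_state(0.1, 0.925)
  for (t in c(10, 100, 1000)) {
    s <- coupled_relax(s0, tis, t)
    tot0 <- (1 - tis$f) * s0[["szf"]] + tis$f * s0[["szm"]]
    tot <- (1 - tis$f) * s[["szf"]] + tis$f * s[["szm"]]
    expect_equal(tot, tot0, tolerance = 1e-9)
  }
})

test_that("buildup iterates to the exact affine-map fixed point", {
  tis <- gm_tissue()
  op <- train_operator(default_train(), tis)
  bu <- buildup(op, tis, period_ms = 387, n_trains = 130, probe_delay_ms = 100)
  # monotone non-decreasing and convergent
  expect_true(all(diff(bu$szf_probed) > -1e-12))
  expect_equal(bu$szf_probed[130], bu$fixed_point$probe[["szf"]],
               tolerance = 1e-9)
  # identity operator leaves the system at equilibrium
  bu0 <- buildup(identity_operator(), tis, 387, 5, 100)
  expect_equal(bu0$szf_probed, rep(0, 5))
  expect_error(buildup(op, tis, 387, 0, 100), "n_trains")
  expect_error(buildup(op, tis, 387, 5, 400), "probe_delay")
})

test_that("the quasi-steady-state decay curve is consistent and biexponential", {
  tis <- gm_tissue()
  op <- train_operator(default_train(), tis)
  cur <- inter_train_decay_curve(tis, op, 387)
  bu <- buildup(op, tis, 387, 5, 100)
  # endpoints tie back to the fixed point: post-train at t = 0,
  # pre-next-train at t = period - train duration
  expect_equal(cur$szf[1], bu$fixed_point$post[["szf"]], tolerance = 1e-12)
  expect_equal(cur$szf[cur$t_ms == 381], bu$fixed_point$pre[["szf"]],
               tolerance = 1e-10)
  # coupled tissue: the curve is a genuine two-exponential (both amplitudes
  # matter); a best single-exponential fit leaves structured residuals
  bi <- biexp_solution(tis, coupled_state(cur$szf[1], cur$szm[1]))
  closed <- bi$a1 * exp(-bi$lambda1_s * cur$t_ms / 1000) +
    bi$a2 * exp(-bi$lambda2_s * cur$t_ms / 1000)
  expect_lt(max(abs(closed - cur$szf)), 1e-6)
  fit1 <- stats::nls(szf ~ a * exp(-l * t_ms / 1000), data = cur,
                     start = list(a = cur$szf[1], l = 1))
  expect_gt(max(abs(stats::resid(fit1))), 1e-4)
  # liquid: exactly monoexponential
  liq <- liquid_tissue()
  opl <- train_operator(default_train(), liq)
  curl <- inter_train_decay_curve(liq, opl, 387)
  expect_equal(curl$szf, curl$szf[1] * exp(-curl$t_ms / 2500),
               tolerance = 1e-10)
})
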