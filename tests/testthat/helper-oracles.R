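# Independent numerical oracles and small fixtures shared across tests.

# generator matrix of the coupled saturation dynamics, duplicated here on
# purpose so the oracle does not share code with the implementation
oracle_generator <- function(tissue) {
  R1f <- 1000 / tissue$free$T1_ms
  R1m <- 1000 / tissue$macro$T1_ms
  matrix(c(R1f + tissue$kf_s, -tissue$kf_s,
           -tissue$km_s, R1m + tissue$km_s), 2, 2, byrow = TRUE)
}

# fixed-step numerical integration of dS/dt = -A S (deSolve lsoda)
ode_oracle <- function(tissue, state0, t_ms) {
  A <- oracle_generator(tissue)
  sol <- deSolve::lsoda(
    y = as.numeric(state0), times = c(0, t_ms) / 1000,
    func = function(t, y, p) list(as.numeric(-A %*% y)),
    rtol = 1e-11, atol = 1e-13
  )
  sol[-1, -1, drop = FALSE]  # rows: t_ms, cols: szf, szm
}

gm_tissue <- function(km = KM_DEFAULT) {
  tissue_params(pool_params(2500, 900), pool_params(500, 0.070),
                f = 0.15, km_s = km)
}

liquid_tissue <- function(T2 = 7, T1 = 2500) {
  tissue_params(pool_params(T1, T2))
}

# a single hard subpulse with a given on-resonance flip angle (degrees)
single_subpulse <- function(flip_deg, b1 = 10, phase = 0) {
  dur_ms <- flip_deg / 360 / (GAMMA_HZ_PER_UT * b1) * 1000
  pulse_train(b1, dur_ms, phase)
}
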