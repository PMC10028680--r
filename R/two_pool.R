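# Coupled longitudinal dynamics of the macromolecular / free-water pair.
#
# In fractional-saturation coordinates S = (Szf, Szm), free evolution obeys
# dS/dt = -A S with
#     A = [ R1f + kf   -kf  ]
#         [ -km    R1m + km ]
# (rates in 1/s). The radicand of the eigenvalue split,
# (R1f + kf - R1m - km)^2 + 4 kf km, is non-negative, so both decay rates are
# real; they are positive because trace(A) > 0 and
# det(A) = R1f R1m + R1f km + R1m kf > 0.

relax_generator <- function(tissue) {
  R1f <- 1000 / tissue$free$T1_ms
  R1m <- 1000 / tissue$macro$T1_ms
  matrix(c(R1f + tissue$kf_s, -tissue$kf_s,
           -tissue$km_s, R1m + tissue$km_s),
         2, 2, byrow = TRUE)
}

# expm(-A * t_s) for the 2x2 generator; eigen route with a Taylor fallback
# for (near-)degenerate rates
relax_propagator <- function(A, t_s) {
  if (t_s == 0) return(diag(2))
  e <- eigen(A)
  if (abs(e$values[1] - e$values[2]) > 1e-9 * max(abs(e$values), 1)) {
    P <- e$vectors %*% diag(exp(-e$values * t_s)) %*% solve(e$vectors)
    return(Re(P))
  }
  # scaling and squaring with a short Taylor series
  B <- -A * t_s
  k <- max(0L, ceiling(log2(max(1e-12, norm(B, "F")))))
  B <- B / 2^k
  P <- diag(2)
  term <- diag(2)
  for (j in 1:12) {
    term <- term %*% B / j
    P <- P + term
  }
  for (j in seq_len(k)) P <- P %*% P
  P
}

#' Free coupled relaxation of a two-pool saturation state
#'
#' Evolves a [coupled_state()] under T1 relaxation and inter-pool exchange
#' for `t_ms` milliseconds, using the closed-form eigen-solution of the 2x2
#' linear system (the biexponential recovery of coupled tissue). With
#' `f = 0` the pools decouple and the free pool relaxes monoexponentially.
#'
#' @param state a [coupled_state()]
#' @param tissue a [tissue_params()]
#' @param t_ms evolution time (ms), >= 0
#' @return a [coupled_state()]
#' @export
coupled_relax <- function(state, tissue, t_ms) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (!is.finite(t_ms) || t_ms < 0) stop("t_ms must be >= 0")
  A <- relax_generator(tissue)
  S <- as.numeric(relax_propagator(A, t_ms / 1000) %*% as.numeric(state))
  coupled_state(S[1], S[2])
}

#' Biexponential decomposition of the free-pool saturation decay
#'
#' Writes the free-pool fractional saturation after free evolution from
#' `state0` as `Szf(t) = a1 exp(-lambda1 t) + a2 exp(-lambda2 t)` with
#' `lambda1 >= lambda2 > 0` (1/s), computed from the eigen-decomposition of
#' the coupled generator. The amplitudes satisfy `a1 + a2 = Szf(0)`.
#'
#' @param tissue a [tissue_params()]
#' @param state0 initial [coupled_state()]
#' @return list of class `biexp_solution` with `lambda1_s`, `lambda2_s`,
#'   `a1`, `a2`
#' @export
biexp_solution <- function(tissue, state0) {
  A <- relax_generator(tissue)
  e <- eigen(A)
  ord <- order(e$values, decreasing = TRUE)
  lam <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  cvec <- solve(V, as.numeric(state0))
  structure(list(lambda1_s = lam[1], lambda2_s = lam[2],
                 a1 = V[1, 1] * cvec[1], a2 = V[1, 2] * cvec[2]),
            class = "biexp_solution")
}

# apply a train operator to a saturation state: Mz -> sigma * Mz per pool,
# i.e. S -> (1 - sigma) + sigma * S
apply_operator <- function(op, S) {
  sig <- as.numeric(op)
  (1 - sig) + sig * S
}

train_ms_of <- function(op) {
  tm <- attr(op, "train_ms")
  if (is.null(tm)) 0 else tm
}

#' Saturation buildup over repeated pulse trains
#'
#' Iterates (instantaneous per-pool train saturation) -> (coupled relaxation
#' over the inter-train interval) starting from equilibrium, probing the
#' free-pool saturation `probe_delay_ms` after each train. Also solves the
#' fixed point of the per-period affine map (the quasi-steady state) exactly.
#'
#' @param op a [train_operator()] (carries the train duration)
#' @param tissue a [tissue_params()]
#' @param period_ms train-to-train repetition time (ms)
#' @param n_trains number of trains to iterate, >= 1
#' @param probe_delay_ms probe time after each train end (ms), < period
#' @return list with `szf_probed` (length `n_trains`), `fixed_point`
#'   (list `pre`, `post`, `probe`: coupled states at quasi-steady state),
#'   and `trains_to_fixed_point` (first train whose probed value is within
#'   1 percent, relative, of the fixed-point probe)
#' @export
buildup <- function(op, tissue, period_ms = 387, n_trains = 30,
                    probe_delay_ms = 100) {
  stopifnot(inherits(op, "train_operator"), inherits(tissue, "tissue_params"))
  if (n_trains < 1) stop("n_trains must be >= 1")
  tm <- train_ms_of(op)
  if (period_ms < tm) stop("period shorter than the train itself")
  if (probe_delay_ms >= period_ms) stop("probe_delay_ms must be < period_ms")
  A <- relax_generator(tissue)
  gap_s <- (period_ms - tm) / 1000
  E <- relax_propagator(A, gap_s)
  P <- relax_propagator(A, probe_delay_ms / 1000)
  S <- c(0, 0)
  probed <- numeric(n_trains)
  for (i in seq_len(n_trains)) {
    S <- apply_operator(op, S)
    probed[i] <- (P %*% S)[1]
    S <- as.numeric(E %*% S)
  }
  fp <- qss_fixed_point(op, tissue, period_ms)
  fp_probe <- (P %*% as.numeric(fp$post))[1]
  within <- abs(probed - fp_probe) <= 0.01 * abs(fp_probe)
  list(
    szf_probed = probed,
    fixed_point = list(pre = fp$pre, post = fp$post,
                       probe = coupled_state(fp_probe,
                                             (P %*% as.numeric(fp$post))[2])),
    trains_to_fixed_point = if (any(within)) which(within)[1] else NA_integer_
  )
}

# fixed point of the per-period map S_pre -> E (apply_operator(op, S_pre))
qss_fixed_point <- function(op, tissue, period_ms) {
  A <- relax_generator(tissue)
  tm <- train_ms_of(op)
  E <- relax_propagator(A, (period_ms - tm) / 1000)
  sig <- as.numeric(op)
  Spre <- solve(diag(2) - E %*% diag(sig), as.numeric(E %*% (1 - sig)))
  Spost <- apply_operator(op, Spre)
  list(pre = coupled_state(Spre[1], Spre[2]),
       post = coupled_state(Spost[1], Spost[2]))
}

#' Free-pool saturation decay over one quasi-steady-state period
#'
#' Samples the free-pool (and macromolecular) saturation over the interval
#' between a train and its repetition, at the fixed point of the per-period
#' map. In coupled tissue the curve is biexponential (fast inter-pool
#' equilibration followed by slow T1 decay); for a liquid (`f = 0`) it is
#' exactly monoexponential.
#'
#' @param tissue a [tissue_params()]
#' @param op a [train_operator()]
#' @param period_ms repetition period (ms)
#' @param t_grid_ms sample times after the train end (ms); default a 1 ms
#'   grid over the full inter-train interval
#' @return data frame with columns `t_ms`, `szf`, `szm`
#' @export
inter_train_decay_curve <- function(tissue, op, period_ms = 387,
                                    t_grid_ms = NULL) {
  tm <- train_ms_of(op)
  horizon <- period_ms - tm
  if (is.null(t_grid_ms)) t_grid_ms <- seq(0, horizon, by = 1)
  if (any(t_grid_ms < 0 | t_grid_ms > horizon + 1e-9)) {
    stop("t_grid_ms outside [0, period - train duration]")
  }
  A <- relax_generator(tissue)
  Spost <- as.numeric(qss_fixed_point(op, tissue, period_ms)$post)
  out <- vapply(t_grid_ms, function(t) {
    as.numeric(relax_propagator(A, t / 1000) %*% Spost)
  }, numeric(2))
  data.frame(t_ms = t_grid_ms, szf = out[1, ], szm = out[2, ])
}
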