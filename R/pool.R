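#' Relaxation parameters of a single spin pool
#'
#' @param T1_ms longitudinal relaxation time (ms), > 0 (`Inf` allowed for
#'   idealized non-relaxing pools)
#' @param T2_ms transverse relaxation time (ms), > 0 and <= T1
#' @param M0 equilibrium longitudinal magnetization (dimensionless, default 1)
#' @return object of class `pool_params`
#' @export
pool_params <- function(T1_ms, T2_ms, M0 = 1) {
  if (is.na(T1_ms) || T1_ms <= 0) stop("T1 must be > 0")
  if (is.na(T2_ms) || T2_ms <= 0) stop("T2 must be > 0")
  if (T2_ms > T1_ms) stop("T2 must not exceed T1")
  if (!is.finite(M0) || M0 <= 0) stop("M0 must be finite and > 0")
  structure(list(T1_ms = T1_ms, T2_ms = T2_ms, M0 = M0),
            class = "pool_params")
}

#' @export
print.pool_params <- function(x, ...) {
  cat(sprintf("<pool_params> T1 = %g ms, T2 = %g ms, M0 = %g\n",
              x$T1_ms, x$T2_ms, x$M0))
  invisible(x)
}

#' Complete the exchange-rate pair of a two-pool tissue
#'
#' Detailed balance between the macromolecular and free-water pools requires
#' `(1 - f) * kf = f * km`, where `f` is the macromolecular-to-total pool
#' fraction, `km` the exchange rate out of the macromolecular pool and `kf`
#' the exchange rate out of the free pool. Given `f` and `km`, returns `kf`.
#'
#' @param f macromolecular pool fraction, in `[0, 1)`
#' @param km_s exchange rate from the macromolecular pool (1/s), >= 0
#' @return kf in 1/s
#' @export
derive_exchange <- function(f, km_s) {
  if (!is.finite(f) || f < 0 || f >= 1) stop("f must be in [0, 1)")
  if (!is.finite(km_s) || km_s < 0) stop("km must be >= 0")
  f * km_s / (1 - f)
}

#' Two-pool tissue parameters
#'
#' A tissue is a free-water pool coupled to a macromolecular pool by
#' longitudinal exchange. The free-pool exchange rate `kf` is derived from
#' `f` and `km` via detailed balance (see [derive_exchange()]). Liquids are
#' represented by `f = 0`, which decouples the pools.
#'
#' @param free [pool_params()] of the free-water pool
#' @param macro [pool_params()] of the macromolecular pool
#' @param f macromolecular-to-total pool fraction in `[0, 1)`
#' @param km_s exchange rate from the macromolecular pool (1/s)
#' @return object of class `tissue_params` with derived field `kf_s`
#' @export
tissue_params <- function(free, macro = pool_params(500, 0.070), f = 0,
                          km_s = 0) {
  stopifnot(inherits(free, "pool_params"), inherits(macro, "pool_params"))
  kf_s <- derive_exchange(f, km_s)
  structure(list(free = free, macro = macro, f = f,
                 km_s = if (f > 0) km_s else 0, kf_s = kf_s),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params> f = %g, km = %g /s, kf = %g /s\n  free : T1 %g / T2 %g ms\n  macro: T1 %g / T2 %g ms\n",
    x$f, x$km_s, x$kf_s, x$free$T1_ms, x$free$T2_ms,
    x$macro$T1_ms, x$macro$T2_ms
  ))
  invisible(x)
}

#' Fractional-saturation state of a coupled two-pool system
#'
#' `szf` and `szm` are fractional saturations of the free and macromolecular
#' pools: 0 at equilibrium, 1 when the pool's longitudinal magnetization is
#' fully destroyed (`szf = 1 - Mzf / Mzf_equilibrium`).
#'
#' @param szf free-pool fractional saturation
#' @param szm macromolecular-pool fractional saturation
#' @export
coupled_state <- function(szf = 0, szm = 0) {
  if (!all(is.finite(c(szf, szm)))) stop("saturations must be finite")
  structure(c(szf = szf, szm = szm), class = "coupled_state")
}
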