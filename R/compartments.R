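#' Default macromolecular exchange rate (1/s)
#'
#' The absolute exchange rate out of the macromolecular pool. Calibrated
#' once so that the default gray-matter compartment (f = 0.15) shows exactly
#' 20% free-pool suppression 100 ms after the train at the quasi-steady
#' state of the default scheme; held fixed thereafter (white matter, with
#' f = 0.30 and the same rate, is then a parameter-free prediction).
#' [calibrate_km()] reproduces this value.
#' @export
KM_DEFAULT <- 1.0139

#' A named signal compartment
#'
#' @param name compartment label (unique within a set)
#' @param tissue a [tissue_params()]; liquids have `f = 0`
#' @param volume_fraction optional partial-volume fraction (used by the
#'   synthetic ribbon generator)
#' @export
compartment <- function(name, tissue, volume_fraction = NA_real_) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(tissue, "tissue_params"))
  structure(list(name = name, tissue = tissue,
                 volume_fraction = volume_fraction),
            class = "compartment")
}

#' Construct a compartment set
#'
#' @param ... [compartment()] objects with unique names
#' @export
compartment_set <- function(...) {
  cps <- list(...)
  if (length(cps) == 1 && is.list(cps[[1]]) &&
      !inherits(cps[[1]], "compartment")) {
    cps <- cps[[1]]
  }
  stopifnot(all(vapply(cps, inherits, logical(1), "compartment")))
  nms <- vapply(cps, function(x) x$name, character(1))
  if (anyDuplicated(nms)) stop("compartment names must be unique")
  names(cps) <- nms
  vf <- vapply(cps, function(x) x$volume_fraction, numeric(1))
  if (all(is.finite(vf)) && abs(sum(vf) - 1) > 1e-6) {
    stop("volume fractions, when all given, must sum to 1")
  }
  structure(cps, class = "compartment_set")
}

#' The five default signal compartments
#'
#' Gray matter and white matter are two-pool tissues (free water T1/T2 =
#' 2500/900 ms coupled to a macromolecular pool with T1 = 500 ms, T2 =
#' 70 us; macromolecular fractions 0.15 and 0.30). Cerebrospinal fluid
#' (T2 = 900 ms), arterial blood (T2 = 67.5 ms) and venous blood (T2 =
#' 7 ms) are liquids (no macromolecular pool), all with T1 = 2500 ms.
#'
#' @param km_s macromolecular exchange rate (1/s), default [KM_DEFAULT]
#' @return a [compartment_set()]
#' @export
default_compartments <- function(km_s = KM_DEFAULT) {
  fw <- pool_params(2500, 900)
  mp <- pool_params(500, 0.070)
  compartment_set(
    compartment("GM", tissue_params(fw, mp, f = 0.15, km_s = km_s)),
    compartment("WM", tissue_params(fw, mp, f = 0.30, km_s = km_s)),
    compartment("CSF", tissue_params(pool_params(2500, 900))),
    compartment("arterial", tissue_params(pool_params(2500, 67.5))),
    compartment("venous", tissue_params(pool_params(2500, 7)))
  )
}

#' Per-compartment suppression versus time after the preparation
#'
#' For each compartment, computes the quasi-steady state of the scheme and
#' tabulates the free-pool fractional suppression
#' `1 - Mzf(t) / Mzf(equilibrium)` at times `t` after the last train.
#'
#' @param scheme a [scheme_timing()]
#' @param set a [compartment_set()]
#' @param t_grid_ms probe times (ms) within the free interval after the
#'   preparation; default a 1 ms grid
#' @param config an [engine_config()]
#' @return data frame of class `suppression_profile` with columns
#'   `compartment`, `t_ms`, `suppression`
#' @export
suppression_profile <- function(scheme, set, t_grid_ms = NULL,
                                config = engine_config()) {
  stopifnot(inherits(scheme, "scheme_timing"), inherits(set, "compartment_set"))
  free_ms <- scheme$period_ms - prep_duration(scheme)
  if (is.null(t_grid_ms)) t_grid_ms <- seq(0, floor(free_ms), by = 1)
  if (any(t_grid_ms < 0 | t_grid_ms > free_ms + 1e-9)) {
    stop("t_grid_ms outside [0, period - preparation duration]")
  }
  rows <- lapply(set, function(cp) {
    q <- scheme_qss(scheme, cp$tissue, config)
    supp <- vapply(t_grid_ms, function(t) q$probe(t)[1], numeric(1))
    data.frame(compartment = cp$name, t_ms = t_grid_ms, suppression = supp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("suppression_profile", "data.frame")
  out
}

#' Optimal k0 delay: maximum gray-matter/arterial saturation difference
#'
#' Grid search over the inter-train interval for the time at which the
#' gray-matter minus arterial free-pool suppression difference is largest
#' (the contrast-optimal k-space-center time). Ties are broken toward
#' earlier times.
#'
#' @param scheme a [scheme_timing()]
#' @param set a [compartment_set()] containing compartments named `GM` and
#'   `arterial`
#' @param grid_ms candidate k0 delays (ms), non-empty, within the free
#'   interval
#' @param config an [engine_config()]
#' @return list with `k0_ms` (argmax), `difference` (its value), and the
#'   search table `table`
#' @export
optimal_k0 <- function(scheme, set, grid_ms = NULL,
                       config = engine_config()) {
  free_ms <- scheme$period_ms - prep_duration(scheme)
  if (is.null(grid_ms)) grid_ms <- seq(1, floor(free_ms), by = 1)
  if (length(grid_ms) == 0) stop("empty search grid")
  if (!all(c("GM", "arterial") %in% names(set))) {
    stop("compartment set must contain 'GM' and 'arterial'")
  }
  prof <- suppression_profile(scheme,
                              compartment_set(list(set[["GM"]], set[["arterial"]])),
                              t_grid_ms = grid_ms, config = config)
  gm <- prof$suppression[prof$compartment == "GM"]
  ar <- prof$suppression[prof$compartment == "arterial"]
  d <- gm - ar
  i <- which(d >= max(d) - 1e-12)[1]  # ties toward earlier t
  list(k0_ms = grid_ms[i], difference = d[i],
       table = data.frame(t_ms = grid_ms, difference = d))
}

#' Predicted saturation ratio (saturated / unsaturated signal) at k0
#'
#' The magnetization-transfer ratio each compartment would show when a
#' saturation-prepared image is divided by an unprepared one:
#' `MTR = 1 - suppression` at the scheme's k0 delay.
#'
#' @param scheme a [scheme_timing()]
#' @param set a [compartment_set()]
#' @param config an [engine_config()]
#' @return data frame with columns `compartment`, `suppression`, `mtr`
#' @export
mtr_predict <- function(scheme, set, config = engine_config()) {
  prof <- suppression_profile(scheme, set,
                              t_grid_ms = scheme$k0_delay_ms, config = config)
  data.frame(compartment = prof$compartment, suppression = prof$suppression,
             mtr = 1 - prof$suppression)
}

#' Calibrate the macromolecular exchange rate against the gray-matter anchor
#'
#' Finds the `km` for which the gray-matter compartment's quasi-steady-state
#' free-pool suppression at the probe time equals `target` under the given
#' scheme. This is how [KM_DEFAULT] was fixed (target 0.20 at 100 ms under
#' the default scheme).
#'
#' @param target target suppression fraction, default 0.20
#' @param probe_ms probe delay after the train (ms), default 100
#' @param scheme a [scheme_timing()], default [abc_scheme()]
#' @param f macromolecular fraction of the calibration tissue, default 0.15
#' @param interval search interval for km (1/s)
#' @param config an [engine_config()]
#' @return km in 1/s
#' @export
calibrate_km <- function(target = 0.20, probe_ms = 100,
                         scheme = abc_scheme(), f = 0.15,
                         interval = c(0.01, 50),
                         config = engine_config()) {
  fw <- pool_params(2500, 900)
  mp <- pool_params(500, 0.070)
  gm_at <- function(km) {
    tis <- tissue_params(fw, mp, f = f, km_s = km)
    scheme_qss(scheme, tis, config)$probe(probe_ms)[1]
  }
  stats::uniroot(function(k) gm_at(k) - target, interval, tol = 1e-10)$root
}
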