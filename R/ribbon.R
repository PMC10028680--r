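# Synthetic 1-D cortical ribbon: partial-volume mixtures of the five signal
# compartments across cortical depth, with a block-design functional
# response. A deliberately simple phantom for exercising MTR computation,
# percent-signal-change extraction and depth profiles - not an anatomical
# model.

#' Generate a synthetic cortical ribbon
#'
#' Depth bins run from the white-matter boundary (depth 0) to the pial
#' surface (depth 1). The venous volume fraction increases strictly toward
#' the pial surface (ascending veins pool blood into the pial network),
#' the arterial fraction follows a configurable linear gradient, and the
#' remainder is gray matter. Optional lognormal jitter perturbs the vascular
#' fractions reproducibly under `seed` (the venous gradient is re-sorted so
#' the pial-ward increase is preserved by construction).
#'
#' @param n_depths number of depth bins, >= 3 (default 11)
#' @param venous_range venous fraction at `c(WM boundary, pial surface)`
#' @param arterial_range arterial fraction at `c(WM boundary, pial surface)`
#' @param jitter_sd lognormal sd of multiplicative vascular jitter, >= 0
#' @param seed integer seed used when `jitter_sd > 0`
#' @return object of class `ribbon`: data frame with columns `depth`, `GM`,
#'   `WM`, `CSF`, `arterial`, `venous`; fractions sum to 1 in every bin
#' @export
make_ribbon <- function(n_depths = 11, venous_range = c(0.01, 0.06),
                        arterial_range = c(0.02, 0.02), jitter_sd = 0,
                        seed = 1L) {
  if (n_depths < 3) stop("n_depths must be >= 3")
  depth <- seq(0, 1, length.out = n_depths)
  ve <- venous_range[1] + (venous_range[2] - venous_range[1]) * depth
  ar <- arterial_range[1] + (arterial_range[2] - arterial_range[1]) * depth
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    ve <- sort(ve * exp(stats::rnorm(n_depths, 0, jitter_sd)))
    ar <- ar * exp(stats::rnorm(n_depths, 0, jitter_sd))
  }
  gm <- 1 - ve - ar
  if (any(gm < 0)) stop("vascular fractions exceed 1; cannot sum to 1")
  out <- data.frame(depth = depth, GM = gm, WM = 0, CSF = 0,
                    arterial = ar, venous = ve)
  class(out) <- c("ribbon", "data.frame")
  out
}

#' Block-design functional effect parameters
#'
#' The functional response is modeled mechanistically: during ON blocks an
#' arterial cerebral-blood-volume increase reallocates `delta_arterial_volume`
#' of voxel volume from gray matter to the arterial compartment (active in
#' both contrasts), and the venous compartment's signal increases by
#' `delta_venous_signal` (the venous-centric surrogate of the
#' deoxygenation-driven signal change; in a saturation-prepared acquisition
#' it is carried by the suppressed venous signal and hence attenuated). The
#' response is a boxcar; no haemodynamic convolution is applied.
#'
#' @param delta_arterial_volume absolute volume fraction reallocated from
#'   gray matter to arterial during ON (default 0.01)
#' @param delta_venous_signal fractional venous-compartment signal increase
#'   during ON (default 0.2, i.e. ~0.6% voxel-level change at a 3% venous
#'   fraction)
#' @param on_s,off_s block durations in seconds (default 13.5 / 13.5)
#' @param n_blocks number of OFF+ON cycles, >= 1 (default 14)
#' @param tr_s volume repetition time in seconds (default 2.7)
#' @param noise_sd Gaussian noise sd relative to the baseline signal, >= 0
#' @param seed integer seed for the noise stream
#' @export
functional_effect <- function(delta_arterial_volume = 0.01,
                              delta_venous_signal = 0.2,
                              on_s = 13.5, off_s = 13.5, n_blocks = 14,
                              tr_s = 2.7, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(delta_arterial_volume = delta_arterial_volume,
                 delta_venous_signal = delta_venous_signal,
                 on_s = on_s, off_s = off_s, n_blocks = n_blocks,
                 tr_s = tr_s, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "functional_effect")
}

#' ON/OFF design vector of a functional effect (one entry per volume)
#' @param effect a [functional_effect()]
#' @return integer vector of 0 (OFF) / 1 (ON)
#' @export
block_design <- function(effect) {
  n_off <- max(1L, round(effect$off_s / effect$tr_s))
  n_on <- max(1L, round(effect$on_s / effect$tr_s))
  rep(rep(c(0L, 1L), effect$n_blocks), rep(c(n_off, n_on), effect$n_blocks))
}

#' Simulate a per-depth signal time series of the ribbon
#'
#' Per volume and depth, the signal is the fraction-weighted sum of the
#' compartment signals, each scaled by its quasi-steady-state suppression at
#' the scheme's k0 (mixing is linear; no interaction terms). For the
#' `"BOLD"` contrast the train amplitude is set to zero, so no compartment
#' is suppressed. During ON volumes the arterial volume increase and venous
#' signal change of `effect` are applied; Gaussian noise (relative to the
#' per-depth baseline) is added under `effect$seed`.
#'
#' @param ribbon a [make_ribbon()] object
#' @param scheme a [scheme_timing()]
#' @param set a [compartment_set()] (names must cover the ribbon columns)
#' @param effect a [functional_effect()]
#' @param contrast `"ABC"` (saturation-prepared) or `"BOLD"` (no saturation)
#' @param config an [engine_config()]
#' @return matrix (volumes x depths) of class `ribbon_timeseries`, with
#'   attributes `design`, `baseline`, `contrast`, `suppression`
#' @export
simulate_timeseries <- function(ribbon, scheme, set, effect,
                                contrast = c("ABC", "BOLD"),
                                config = engine_config()) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(ribbon, "ribbon"), inherits(effect, "functional_effect"))
  sch <- scheme
  if (contrast == "BOLD") {
    sch$trains <- lapply(sch$trains, function(tr) {
      tr$amplitude_ut[] <- 0
      tr
    })
  }
  mt <- mtr_predict(sch, set, config)
  supp <- stats::setNames(mt$suppression, mt$compartment)
  comps <- c("GM", "WM", "CSF", "arterial", "venous")
  if (!all(comps %in% names(supp))) {
    stop("compartment set must contain: ", paste(comps, collapse = ", "))
  }
  w <- 1 - supp[comps]
  design <- block_design(effect)
  n_vol <- length(design)
  n_d <- nrow(ribbon)
  frac <- as.matrix(ribbon[, comps])
  if (any(frac[, "GM"] - effect$delta_arterial_volume < 0)) {
    stop("arterial volume increase exceeds the gray-matter fraction")
  }
  sig <- matrix(0, n_vol, n_d)
  for (v in seq_len(n_vol)) {
    f <- frac
    dv <- 0
    if (design[v] == 1L) {
      f[, "arterial"] <- f[, "arterial"] + effect$delta_arterial_volume
      f[, "GM"] <- f[, "GM"] - effect$delta_arterial_volume
      dv <- effect$delta_venous_signal
    }
    sig[v, ] <- f %*% w + f[, "venous"] * w["venous"] * dv
  }
  baseline <- as.numeric(frac %*% w)
  if (effect$noise_sd > 0) {
    set.seed(effect$seed)
    sig <- sig + matrix(stats::rnorm(n_vol * n_d, 0, effect$noise_sd),
                        n_vol, n_d) * rep(baseline, each = n_vol)
  }
  structure(sig, design = design, baseline = baseline, contrast = contrast,
            suppression = supp[comps], class = c("ribbon_timeseries", "matrix"))
}

#' Saturated-to-unsaturated signal ratio of two time series
#'
#' Elementwise ratio of a saturation-prepared series by an unprepared one,
#' masking (NA) positions where the denominator falls below `threshold`.
#'
#' @param abc_signal,bold_signal numeric arrays of equal shape
#' @param threshold mask threshold on the denominator (default 0.05)
#' @return array of ratios with attribute `n_masked`
#' @export
mtr_map <- function(abc_signal, bold_signal, threshold = 0.05) {
  if (!all(dim(as.matrix(abc_signal)) == dim(as.matrix(bold_signal)))) {
    stop("abc_signal and bold_signal must have equal shapes")
  }
  bad <- !is.finite(bold_signal) | bold_signal < threshold
  out <- unclass(abc_signal) / unclass(bold_signal)
  out[bad] <- NA_real_
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Epoch-averaged percent signal change per depth
#'
#' `(mean ON - mean OFF) / mean OFF * 100` per depth, excluding the first
#' `skip_volumes` volumes after every block transition (a haemodynamic-delay
#' skip; the run onset is treated as a transition).
#'
#' @param series a `ribbon_timeseries` (or matrix volumes x depths with a
#'   `design` attribute)
#' @param design ON/OFF vector; defaults to the series' `design` attribute
#' @param skip_volumes volumes discarded after each transition (default 2)
#' @return numeric vector of percent signal change, one value per depth
#' @export
percent_signal_change <- function(series, design = attr(series, "design"),
                                  skip_volumes = 2) {
  x <- unclass(series)
  if (is.null(design) || length(design) != nrow(x)) {
    stop("a design vector matching the series length is required")
  }
  if (sum(diff(design) != 0) < 2) stop("need at least 2 blocks")
  # volumes elapsed since the most recent transition (run start counts)
  tr_idx <- c(TRUE, diff(design) != 0)
  grp <- cumsum(tr_idx)
  within <- stats::ave(seq_along(design), grp, FUN = seq_along)
  keep <- within > skip_volumes
  if (!any(keep & design == 1L) || !any(keep & design == 0L)) {
    stop("no volumes left after the transition skip")
  }
  on_mean <- colMeans(x[keep & design == 1L, , drop = FALSE])
  off_mean <- colMeans(x[keep & design == 0L, , drop = FALSE])
  as.numeric((on_mean - off_mean) / off_mean * 100)
}

#' Cortical-depth profile of the functional response
#'
#' Percent signal change per depth bin, ordered from the white-matter
#' boundary to the pial surface. The `pial_deep_ratio` attribute (last bin /
#' first bin) summarizes the superficial bias of the contrast.
#'
#' @inheritParams percent_signal_change
#' @param depth depth coordinates; defaults to equally spaced `[0, 1]`
#' @return numeric vector of class `depth_profile` with attributes `depth`
#'   and `pial_deep_ratio`
#' @export
depth_profile <- function(series, design = attr(series, "design"),
                          skip_volumes = 2, depth = NULL) {
  psc <- percent_signal_change(series, design, skip_volumes)
  if (is.null(depth)) depth <- seq(0, 1, length.out = length(psc))
  structure(psc, depth = depth, pial_deep_ratio = psc[length(psc)] / psc[1],
            class = "depth_profile")
}

#' Write a ribbon time series as a NIfTI volume (1 x 1 x depths x volumes)
#'
#' Interoperability export for neuroimaging viewers; requires the RNifti
#' package. Generator parameters should be kept alongside (see
#' [write_sidecar()]).
#'
#' @param series a `ribbon_timeseries`
#' @param path output file (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
write_ribbon_nifti <- function(series, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export")
  }
  x <- unclass(series)
  arr <- array(t(x), dim = c(1, 1, ncol(x), nrow(x)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write generator parameters as a JSON sidecar
#' @param params a named list (e.g. a [functional_effect()])
#' @param path output .json path
#' @export
write_sidecar <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
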