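#' Sequence scheme timing
#'
#' A scheme is a (possibly composite) saturation preparation repeated with a
#' fixed period, followed by one or two segmented readouts. The preparation
#' is a list of pulse trains separated by cross-relaxation gaps; k-space
#' center (k0) delays are measured from the end of the last train, which is
#' where a center-slice-out readout places its contrast-defining sample.
#'
#' @param trains list of [pulse_train()] objects (one per preparation train)
#' @param gaps_ms cross-relaxation gaps between consecutive trains (ms);
#'   length `length(trains) - 1`
#' @param period_ms preparation-to-preparation repetition time (ms)
#' @param k0_delay_ms delay from last train end to the k0 sample (ms)
#' @param segment_ms total readout time per period (ms)
#' @param second_k0_delay_ms optional second k0 delay (ms) for dual-readout
#'   schemes
#' @return object of class `scheme_timing`
#' @export
scheme_timing <- function(trains, gaps_ms = numeric(0), period_ms,
                          k0_delay_ms, segment_ms,
                          second_k0_delay_ms = NULL) {
  if (inherits(trains, "pulse_train")) trains <- list(trains)
  stopifnot(all(vapply(trains, inherits, logical(1), "pulse_train")))
  if (length(gaps_ms) != length(trains) - 1) {
    stop("gaps_ms must have one entry per pair of consecutive trains")
  }
  if (any(gaps_ms < 0)) stop("gaps must be >= 0")
  sch <- structure(list(
    trains = trains, gaps_ms = gaps_ms, period_ms = period_ms,
    k0_delay_ms = k0_delay_ms, segment_ms = segment_ms,
    second_k0_delay_ms = second_k0_delay_ms
  ), class = "scheme_timing")
  check_scheme(sch)
  sch
}

#' Preparation duration of a scheme (trains plus gaps), ms
#' @param scheme a [scheme_timing()]
#' @export
prep_duration <- function(scheme) {
  sum(vapply(scheme$trains, train_duration, numeric(1))) + sum(scheme$gaps_ms)
}

#' Feasibility check of a scheme
#'
#' Rejects schemes whose preparation plus readout exceed the period, or
#' whose k0 delays fall outside the free interval after the preparation.
#'
#' @param scheme a [scheme_timing()]
#' @return the scheme, invisibly, if feasible; otherwise an error with a
#'   diagnostic
#' @export
check_scheme <- function(scheme) {
  prep <- prep_duration(scheme)
  free_ms <- scheme$period_ms - prep
  if (prep + scheme$segment_ms > scheme$period_ms + 1e-9) {
    stop(sprintf(
      "infeasible scheme: preparation (%.1f ms) + readout (%.1f ms) exceed the period (%.1f ms)",
      prep, scheme$segment_ms, scheme$period_ms
    ))
  }
  delays <- c(scheme$k0_delay_ms, scheme$second_k0_delay_ms)
  if (any(delays < 0 | delays >= free_ms)) {
    stop(sprintf(
      "infeasible scheme: k0 delay outside the free interval [0, %.1f) ms after the preparation",
      free_ms
    ))
  }
  invisible(scheme)
}

#' @export
print.scheme_timing <- function(x, ...) {
  cat(sprintf(
    "<scheme_timing> %d train(s), prep %.2f ms, period %g ms, k0 %g ms%s, readout %g ms\n",
    length(x$trains), prep_duration(x), x$period_ms, x$k0_delay_ms,
    if (!is.null(x$second_k0_delay_ms)) {
      sprintf(" (+ second k0 %g ms)", x$second_k0_delay_ms)
    } else "",
    x$segment_ms
  ))
  invisible(x)
}

#' The canonical densely-repeated saturation scheme
#'
#' One 7-subpulse 10 uT zero-net-flip train of 6 ms ([default_train()]),
#' repeated every 387 ms, k0 sampled 100 ms after the train, 218 ms readout
#' segment per period.
#'
#' @param b1_ut train amplitude (uT), default 10
#' @return a [scheme_timing()]
#' @export
abc_scheme <- function(b1_ut = 10) {
  scheme_timing(list(default_train(b1_ut)), numeric(0),
                period_ms = 387, k0_delay_ms = 100, segment_ms = 218)
}

#' The sparse dual-readout preparation scheme
#'
#' A composite preparation of four 4-subpulse 12 uT trains separated by
#' 60 ms cross-relaxation gaps, repeated every 3.3 s, with two full-volume
#' readouts per period: the first k0 close to the maximum gray-matter
#' saturation (100 ms after the last train), the second one volume later
#' (1500 ms), close to longitudinal equilibrium. Dividing the first readout
#' by the second isolates the saturation contrast from slow signal drifts.
#'
#' @param b1_ut train amplitude (uT), default 12
#' @param n_trains number of preparation trains, default 4
#' @param subpulses_per_train subpulses per train, default 4
#' @param gap_ms cross-relaxation gap (ms), default 60
#' @return a [scheme_timing()]
#' @export
isolated_abc_scheme <- function(b1_ut = 12, n_trains = 4,
                                subpulses_per_train = 4, gap_ms = 60) {
  trains <- replicate(n_trains, zero_flip_block(subpulses_per_train, b1_ut),
                      simplify = FALSE)
  scheme_timing(trains, rep(gap_ms, n_trains - 1),
                period_ms = 3300, k0_delay_ms = 100, segment_ms = 3000,
                second_k0_delay_ms = 1600)
}

#' Relative RF power deposition of a scheme
#'
#' Time-averaged `B1^2` duty of the preparation, `sum(B1^2 * duration) /
#' period`, reported relative to the canonical dense scheme
#' ([abc_scheme()] = 1). RF power deposition scales quadratically with
#' amplitude and inversely with the repetition period.
#'
#' @param scheme a [scheme_timing()]
#' @return object of class `sar_proxy` (a number, >= 0)
#' @export
sar_proxy <- function(scheme) {
  duty <- function(s) {
    sum(vapply(s$trains, function(tr) {
      sum(tr$amplitude_ut^2 * tr$duration_ms)
    }, numeric(1))) / s$period_ms
  }
  structure(duty(scheme) / duty(abc_scheme()), class = "sar_proxy")
}

#' @export
print.sar_proxy <- function(x, ...) {
  cat(sprintf("<sar_proxy> %.4g (relative to the dense default scheme)\n",
              unclass(x)))
  invisible(x)
}

# Quasi-steady state of a tissue under a (possibly composite) scheme.
# Returns the post-preparation coupled state and a probe(t_ms) function for
# times after the last train end, plus the per-train operators used.
scheme_qss <- function(scheme, tissue, config = engine_config()) {
  A <- relax_generator(tissue)
  ops <- lapply(scheme$trains, train_operator, tissue = tissue,
                config = config)
  # per-period affine map S -> M S + b, starting just before the first train
  M <- diag(2)
  b <- c(0, 0)
  step_op <- function(op) {
    sig <- as.numeric(op)
    M <<- diag(sig) %*% M
    b <<- sig * b + (1 - sig)
  }
  step_relax <- function(t_ms) {
    E <- relax_propagator(A, t_ms / 1000)
    M <<- E %*% M
    b <<- as.numeric(E %*% b)
  }
  for (i in seq_along(ops)) {
    step_op(ops[[i]])
    if (i < length(ops)) step_relax(scheme$gaps_ms[i])
  }
  Mpost <- M
  bpost <- b
  tail_ms <- scheme$period_ms - prep_duration(scheme)
  step_relax(tail_ms)
  Spre <- solve(diag(2) - M, b)
  Spost <- as.numeric(Mpost %*% Spre + bpost)
  list(
    post = coupled_state(Spost[1], Spost[2]),
    probe = function(t_ms) {
      as.numeric(relax_propagator(A, t_ms / 1000) %*% Spost)
    },
    ops = ops,
    free_interval_ms = tail_ms
  )
}

#' Dual-readout suppression of a sparse scheme
#'
#' Quasi-steady-state coupled simulation of a dual-readout scheme, returning
#' the free-pool suppression at the first and second k0 per compartment.
#'
#' @param scheme a dual-readout [scheme_timing()] (with `second_k0_delay_ms`)
#' @param set a [compartment_set()]
#' @param config an [engine_config()]
#' @return data frame with columns `compartment`, `suppression_k0_first`,
#'   `suppression_k0_second`
#' @export
simulate_isolated_abc <- function(scheme, set, config = engine_config()) {
  if (is.null(scheme$second_k0_delay_ms)) {
    stop("scheme has a single readout; a dual-readout scheme is required")
  }
  stopifnot(inherits(set, "compartment_set"))
  rows <- lapply(set, function(cp) {
    q <- scheme_qss(scheme, cp$tissue, config)
    data.frame(
      compartment = cp$name,
      suppression_k0_first = q$probe(scheme$k0_delay_ms)[1],
      suppression_k0_second = q$probe(scheme$second_k0_delay_ms)[1]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
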