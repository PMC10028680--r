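# Configuration surface shared by the CLI and the programmatic interface.
# All defaults reproduce the canonical dense saturation scheme.

#' Default run configuration
#'
#' @return named list of class `run_config`
#' @export
default_config <- function() {
  structure(list(
    scheme = "abc",            # "abc" or "isolated-abc"
    b1_ut = 10,
    km_s = KM_DEFAULT,
    sample_step_us = 5,
    offsets_hz = seq(-300, 300, by = 10),
    k0_delay_ms = 100,
    out_dir = ".",
    seed = 1L,
    verbosity = 1L,
    compartments = NULL        # optional per-name overrides
  ), class = "run_config")
}

validate_config <- function(cfg) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  num_pos <- c("b1_ut", "sample_step_us")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("configuration key '", k, "' must be a positive number")
    }
  }
  if (!cfg$scheme %in% c("abc", "isolated-abc")) {
    stop("configuration key 'scheme' must be 'abc' or 'isolated-abc'")
  }
  if (!is.null(cfg$compartments)) {
    for (nm in names(cfg$compartments)) {
      ov <- cfg$compartments[[nm]]
      bad <- setdiff(names(ov), c("T1_ms", "T2_ms", "f"))
      if (length(bad) > 0) {
        stop("unknown compartment override key(s) for '", nm, "': ",
             paste(bad, collapse = ", "))
      }
      T1 <- if (!is.null(ov$T1_ms)) ov$T1_ms else 2500
      T2 <- if (!is.null(ov$T2_ms)) ov$T2_ms else 900
      if (T2 <= 0 || T1 <= 0) {
        stop("compartment '", nm, "': relaxation times must be > 0")
      }
      if (T2 > T1) stop("compartment '", nm, "': T2 must not exceed T1")
      if (!is.null(ov$f) && (ov$f < 0 || ov$f >= 1)) {
        stop("compartment '", nm, "': f must be in [0, 1)")
      }
    }
  }
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' Unset keys are filled with the canonical defaults; unknown keys and
#' physically invalid parameters are rejected with a message naming the
#' offending key.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`)
#' @return validated `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  # preserve key set for unknown-key detection
  extra <- setdiff(names(raw), names(default_config()))
  for (k in extra) cfg[[k]] <- raw[[k]]
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

#' Write a run configuration to YAML (round-trips through [load_config()])
#' @param cfg a `run_config`
#' @param path output path (.yaml)
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Build the scheme described by a configuration
#' @param cfg a `run_config`
#' @export
config_scheme <- function(cfg) {
  sch <- if (cfg$scheme == "isolated-abc") {
    isolated_abc_scheme()
  } else {
    abc_scheme(b1_ut = cfg$b1_ut)
  }
  sch$k0_delay_ms <- cfg$k0_delay_ms
  check_scheme(sch)
  sch
}

#' Build the compartment set described by a configuration
#' @param cfg a `run_config`
#' @export
config_compartments <- function(cfg) {
  set <- default_compartments(km_s = cfg$km_s)
  if (is.null(cfg$compartments)) return(set)
  mp <- pool_params(500, 0.070)
  lst <- unclass(set)
  for (nm in names(cfg$compartments)) {
    if (!nm %in% names(lst)) stop("unknown compartment: ", nm)
    ov <- cfg$compartments[[nm]]
    old <- lst[[nm]]$tissue
    T1 <- if (!is.null(ov$T1_ms)) ov$T1_ms else old$free$T1_ms
    T2 <- if (!is.null(ov$T2_ms)) ov$T2_ms else old$free$T2_ms
    f <- if (!is.null(ov$f)) ov$f else old$f
    lst[[nm]] <- compartment(nm, tissue_params(pool_params(T1, T2), mp,
                                               f = f, km_s = cfg$km_s))
  }
  compartment_set(lst)
}

#' Write a table as CSV with a header and deterministic column order
#' @param rows a data frame
#' @param path output path
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Human-readable run report
#'
#' @param cfg the `run_config` used
#' @param scheme the [scheme_timing()] used
#' @param extra optional named list of extra result lines
#' @return character vector of report lines (also printed at verbosity >= 1)
#' @export
run_report <- function(cfg, scheme, extra = list()) {
  lines <- c(
    sprintf("satprep %s", as.character(utils::packageVersion("satprep"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("scheme: %s | %d train(s), prep %.2f ms, period %g ms, k0 %g ms",
            cfg$scheme, length(scheme$trains), prep_duration(scheme),
            scheme$period_ms, scheme$k0_delay_ms),
    sprintf("relative SAR: %.4g", unclass(sar_proxy(scheme))),
    sprintf("engine: sample step %g us", cfg$sample_step_us)
  )
  for (nm in names(extra)) {
    lines <- c(lines, sprintf("%s: %s", nm, format(extra[[nm]])))
  }
  if (isTRUE(cfg$verbosity >= 1)) cat(paste0(lines, "\n"), sep = "")
  invisible(lines)
}
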