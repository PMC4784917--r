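#' Load and validate a structured simulation configuration
#'
#' Reads a YAML (or JSON) file describing the particle population, the fluid
#' environment and the drive field, validates it strictly (unknown keys are
#' rejected, missing required keys reported together), applies defaults, and
#' converts all quantities to SI.
#'
#' Schema (units in key names):
#' \preformatted{
#' particles:
#'   mean_core_radius_nm:  20
#'   mean_hydro_radius_nm: 50
#'   size_cv:              0.10     # optional, default 0.10
#'   Ms_kA_per_m:          250
#' environment:
#'   viscosity_mPa_s:      1.0
#'   temperature_K:        293      # optional, default 293
#'   density_kg_m3:        1000     # optional, default 1000
#' field:
#'   amplitude_mT:         5
#'   frequency_Hz:         1000
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `msb_config`: list with elements `particles`
#'   ([msb_particle_spec()]), `environment` ([msb_environment()]), `field`
#'   ([msb_drive_field()]) and `raw` (the canonicalized key-value form that
#'   [dump_config()] writes back).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "example_config.yaml",
#'                                package = "msbsim"))
#' cfg$field$amplitude  # 5 mT in tesla
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0)
    stop(paste("empty config; required keys:",
               "particles.{mean_core_radius_nm, mean_hydro_radius_nm,",
               "Ms_kA_per_m}, environment.{viscosity_mPa_s},",
               "field.{amplitude_mT, frequency_Hz}"))
  validate_config(raw)
}

config_schema <- list(
  particles = list(required = c("mean_core_radius_nm", "mean_hydro_radius_nm",
                                "Ms_kA_per_m"),
                   optional = c(size_cv = 0.10)),
  environment = list(required = "viscosity_mPa_s",
                     optional = c(temperature_K = 293, density_kg_m3 = 1000)),
  field = list(required = c("amplitude_mT", "frequency_Hz"),
               optional = numeric(0))
)

validate_config <- function(raw) {
  problems <- character(0)
  unknown_sections <- setdiff(names(raw), names(config_schema))
  if (length(unknown_sections))
    problems <- c(problems, paste("unknown section(s):",
                                  paste(unknown_sections, collapse = ", ")))
  canon <- list()
  for (sec in names(config_schema)) {
    sch <- config_schema[[sec]]
    got <- raw[[sec]]
    if (is.null(got)) {
      problems <- c(problems, sprintf("missing section '%s' (keys: %s)", sec,
                                      paste(sch$required, collapse = ", ")))
      next
    }
    unknown <- setdiff(names(got), c(sch$required, names(sch$optional)))
    if (length(unknown))
      problems <- c(problems, sprintf("unknown key(s) in '%s': %s", sec,
                                      paste(unknown, collapse = ", ")))
    missing <- setdiff(sch$required, names(got))
    if (length(missing))
      problems <- c(problems, sprintf("missing key(s) in '%s': %s", sec,
                                      paste(missing, collapse = ", ")))
    vals <- got[intersect(names(got), c(sch$required, names(sch$optional)))]
    bad <- names(vals)[!vapply(vals, function(v)
      is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
    if (length(bad))
      problems <- c(problems, sprintf("non-numeric value(s) in '%s': %s", sec,
                                      paste(bad, collapse = ", ")))
    for (k in names(sch$optional))
      if (is.null(vals[[k]])) vals[[k]] <- unname(sch$optional[[k]])
    canon[[sec]] <- vals[order(names(vals))]
  }
  if (length(problems))
    stop(paste0("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - ")))
  p <- canon$particles; e <- canon$environment; f <- canon$field
  structure(list(
    particles = msb_particle_spec(p$mean_core_radius_nm * 1e-9,
                                  p$mean_hydro_radius_nm * 1e-9,
                                  Ms = p$Ms_kA_per_m * 1e3, cv = p$size_cv),
    environment = msb_environment(e$viscosity_mPa_s * 1e-3, e$temperature_K,
                                  e$density_kg_m3),
    field = msb_drive_field(f$amplitude_mT * 1e-3, f$frequency_Hz),
    raw = canon), class = "msb_config")
}

#' Write a configuration back to YAML
#'
#' @param config An `msb_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "msb_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Write a magnetization trace as CSV
#'
#' Columns `t_star`, `mz_mean`, `mz_sem` (exact headers).
#' @param trace A `mag_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("t_star", "mz_mean", "mz_sem")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a magnetization trace CSV
#'
#' Accepts the schema written by [write_trace_csv()].  The number of periods
#' covered must be supplied (the CSV carries only the grid).
#' @param path CSV path with columns `t_star`, `mz_mean`, `mz_sem`.
#' @param n_periods Whole drive periods covered by the samples.
#' @return A `mag_trace`.
#' @export
read_trace_csv <- function(path, n_periods) {
  df <- utils::read.csv(path)
  need <- c("t_star", "mz_mean", "mz_sem")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns t_star, mz_mean, mz_sem")
  P <- as.integer(n_periods)
  if (nrow(df) %% P != 0)
    stop("trace length is not a multiple of the stated period count")
  dt <- diff(df$t_star)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("t_star grid must be uniform")
  out <- df[need]
  class(out) <- c("mag_trace", "data.frame")
  attr(out, "dt_star") <- dt[1]
  attr(out, "steps_per_period") <- nrow(df) %/% P
  attr(out, "n_periods_analysis") <- P
  attr(out, "n_particles") <- NA_integer_
  out
}

#' Write a harmonic spectrum as CSV
#'
#' Columns `l`, `a_l`, `a_l_norm` (amplitudes normalized by the maximum over
#' the reported harmonics).
#' @param spec A `harmonic_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "harmonic_spectrum"))
  df <- data.frame(l = spec$l, a_l = spec$a_l,
                   a_l_norm = spec$a_l / max(spec$a_l))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an externally measured harmonic spectrum CSV
#'
#' Accepts the `l, a_l, a_l_norm` schema (the `a_l_norm` column is optional),
#' so measured spectra can be pushed through the same ratio/collapse analysis
#' as simulated ones.
#' @param path CSV path.
#' @return A `harmonic_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("l", "a_l") %in% names(df)))
    stop("spectrum CSV must have columns l, a_l")
  out <- data.frame(l = as.integer(df$l), a_l = df$a_l)
  class(out) <- c("harmonic_spectrum", "data.frame")
  attr(out, "n_periods") <- NA_integer_
  out
}

#' Write a sweep as CSV
#'
#' Columns `A`, `xi0_mean`, `omega_mean`, `a3`, `a5`, ... and the matching
#' `_se` columns when present.
#' @param sweep An `msb_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
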