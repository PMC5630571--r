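# Plain-text dialects: gas and liquid series CSVs (UTF-8, decimal point,
# header required) and YAML scenario files. write -> read is the identity on
# valid series at the declared precision.

#' Write / read an off-gas series CSV
#'
#' Columns: `time_h`, `o2_pct`, `n2_pct`, `co_pct`, `co2_pct`, `h2_pct`,
#' `ar_pct`, `flow_l_h`. Reference temperature and pressure are carried as
#' `# key: value` comment headers.
#'
#' @param series A [gas_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_series <- function(series, path) {
  stopifnot(inherits(series, "gas_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# temperature_c: %g", attr(series, "temperature")), con)
  writeLines(sprintf("# pressure_atm: %g", attr(series, "pressure")), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gas_series
#' @param validate Re-validate fractions and time monotonicity on read.
#' @export
read_gas_series <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("gas series file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*:", "", hit[1])) else default
  }
  tab <- utils::read.csv(text = lines[body], stringsAsFactors = FALSE)
  needed <- c("time_h", GAS_COLUMNS, "flow_l_h")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("malformed gas series header in ", path, ": missing ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(tab[needed]))
  if (length(bad)) {
    stop("malformed row at line ", body[bad[1] + 1], " of ", path)
  }
  if (!validate) {
    return(tab)
  }
  gas_series(tab$time_h, tab[GAS_COLUMNS], tab$flow_l_h,
             temperature = get_meta("temperature_c", 37),
             pressure = get_meta("pressure_atm", 1))
}

#' Write / read a liquid-phase concentration series CSV
#'
#' Columns: `time_h` plus one `<species>_g_l` column per measured species
#' (sugars, products, biomass).
#'
#' @param liquid Data frame with `time_h` and `*_g_l` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_liquid_series <- function(liquid, path) {
  stopifnot("time_h" %in% names(liquid))
  utils::write.csv(liquid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_liquid_series
#' @export
read_liquid_series <- function(path) {
  if (!file.exists(path)) stop("liquid series file does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(tab)) {
    stop("malformed liquid series in ", path, ": no time_h column")
  }
  if (any(diff(tab$time_h) <= 0)) {
    stop("non-monotone time in ", path, " at line ",
         which(diff(tab$time_h) <= 0)[1] + 2)
  }
  conc_cols <- grep("_g_l$", names(tab), value = TRUE)
  for (col in conc_cols) {
    if (any(tab[[col]] < 0, na.rm = TRUE)) {
      stop("negative concentration in column ", col, " of ", path)
    }
  }
  tab
}

#' Write / read a simulation scenario as YAML
#'
#' A scenario file fully determines a synthetic run (including seed), so a
#' run is reproducible from its config alone.
#'
#' @param scenario A [sim_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  yaml::write_yaml(lapply(unclass(scenario), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("blend", "sugar_feed", "base_yields")) {
    if (!is.null(raw[[field]])) raw[[field]] <- unlist(raw[[field]])
  }
  do.call(sim_scenario, raw)
}
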