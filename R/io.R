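INFLUX_HEADER <- c("n_source", "S_mM", "replicate", "v_umol_per_gDW_h")
METAB_HEADER <- c("treatment", "organ", "replicate", "analyte",
                  "concentration")

#' Read and write influx CSV files
#'
#' The influx dialect is a plain CSV with the fixed header
#' `n_source,S_mM,replicate,v_umol_per_gDW_h`, `.` decimal separator.
#' Reading is strict: a missing column is a schema error, and any
#' non-numeric concentration or rate is reported with its location rather
#' than coerced. Writing optionally emits a sidecar `<path>.provenance.json`
#' with the generating parameters and seed when the tibble carries a
#' `provenance` attribute.
#'
#' @param path CSV file path.
#' @return `read_influx_csv()` returns a tibble in the influx dialect;
#'   `write_influx_csv()` returns `data` invisibly.
#' @export
read_influx_csv <- function(path) {
  data <- read_strict_csv(path, INFLUX_HEADER,
                          readr::cols(
                            n_source = readr::col_character(),
                            S_mM = readr::col_double(),
                            replicate = readr::col_character(),
                            v_umol_per_gDW_h = readr::col_double()
                          ))
  if (nrow(data)) check_influx_data(data)
  dup <- dplyr::count(data, .data$n_source, .data$S_mM, .data$replicate)
  if (any(dup$n > 1))
    abort("duplicate (n_source, S_mM, replicate) records in influx file",
          class = "ninflux_schema_error")
  data
}

#' @rdname read_influx_csv
#' @param data Influx tibble to write.
#' @param provenance Write the sidecar JSON if provenance is available?
#' @export
write_influx_csv <- function(data, path, provenance = TRUE) {
  miss <- setdiff(INFLUX_HEADER, names(data))
  if (length(miss))
    abort(paste0("influx data is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ninflux_schema_error")
  readr::write_csv(data[INFLUX_HEADER], path)
  prov <- attr(data, "provenance")
  if (provenance && !is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(data)
}

#' Read and write metabolite CSV files
#'
#' Fixed header `treatment,organ,replicate,analyte,concentration`; same
#' strictness rules as [read_influx_csv()].
#'
#' @inheritParams read_influx_csv
#' @return `read_metabolite_csv()` returns a tibble;
#'   `write_metabolite_csv()` returns `data` invisibly.
#' @export
read_metabolite_csv <- function(path) {
  data <- read_strict_csv(path, METAB_HEADER,
                          readr::cols(
                            treatment = readr::col_character(),
                            organ = readr::col_character(),
                            replicate = readr::col_character(),
                            analyte = readr::col_character(),
                            concentration = readr::col_double()
                          ))
  if (nrow(data) && any(data$concentration < 0, na.rm = TRUE))
    abort("concentrations must be nonnegative",
          class = "ninflux_domain_error")
  dup <- dplyr::count(data, .data$treatment, .data$organ, .data$replicate,
                      .data$analyte)
  if (any(dup$n > 1))
    abort("duplicate (treatment, organ, replicate, analyte) records",
          class = "ninflux_schema_error")
  data
}

#' @rdname read_metabolite_csv
#' @param data Metabolite tibble to write.
#' @param provenance Write the sidecar JSON if provenance is available?
#' @export
write_metabolite_csv <- function(data, path, provenance = TRUE) {
  miss <- setdiff(METAB_HEADER, names(data))
  if (length(miss))
    abort(paste0("metabolite data is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ninflux_schema_error")
  readr::write_csv(data[METAB_HEADER], path)
  prov <- attr(data, "provenance")
  if (provenance && !is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(data)
}

read_strict_csv <- function(path, header, col_spec) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "ninflux_config_error")
  # parsing problems are surfaced below as structured errors, not warnings
  data <- suppressWarnings(
    readr::read_csv(path, col_types = col_spec, na = character(),
                    progress = FALSE, show_col_types = FALSE))
  miss <- setdiff(header, names(data))
  if (length(miss))
    abort(paste0("file '", path, "' is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ninflux_schema_error")
  probs <- readr::problems(data)
  if (nrow(probs)) {
    loc <- paste(sprintf("line %d, column %d (%s): expected %s, got '%s'",
                         probs$row, probs$col,
                         names(data)[probs$col], probs$expected,
                         probs$actual),
                 collapse = "; ")
    abort(paste0("malformed rows in '", path, "': ", loc),
          class = "ninflux_parse_error")
  }
  tibble::as_tibble(data[header])
}
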