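#' Source CSV dialects
#'
#' A dialect describes how one database's CSV export maps onto the harmonized
#' record schema: which source column feeds which harmonized field, the date
#' format, whether the killed count includes the perpetrator
#' (`victim_count_basis`), whether states are written as full names or USPS
#' codes, whether rows are victim-level (SHR) and whether city/state are
#' combined in one column (Mother Jones style).
#'
#' `bundled_dialect()` loads one of the five dialect configurations shipped
#' with the package (`inst/extdata/dialects/*.yaml`); `read_dialect()` loads a
#' user-edited YAML file.
#'
#' @param source One of `ms_sources()`.
#' @param column_map Named list mapping harmonized field -> source column
#'   name. Must cover `date` and at least one of `state`, `city`.
#' @param date_format `strptime()` format string, parsed strictly.
#' @param victim_count_basis `"EXCLUDES_PERP"`, `"INCLUDES_PERP"` or
#'   `"UNKNOWN"`.
#' @param encoding Text encoding of the file.
#' @param delim Field delimiter.
#' @param state_style `"usps"` or `"full"` — how the source writes states.
#' @param list_sep Separator for multi-name shooter fields.
#' @param victim_level Logical; `TRUE` for one-row-per-victim exports (SHR).
#' @param combined_location Logical; `TRUE` when one column holds
#'   `"City, State"`.
#' @return A `source_dialect` object.
#' @export
source_dialect <- function(source, column_map, date_format,
                           victim_count_basis = c(
                             "EXCLUDES_PERP",
                             "INCLUDES_PERP", "UNKNOWN"
                           ),
                           encoding = "UTF-8", delim = ",",
                           state_style = c("usps", "full"), list_sep = ";",
                           victim_level = FALSE, combined_location = FALSE) {
  source <- match.arg(source, ms_sources())
  victim_count_basis <- match.arg(victim_count_basis)
  state_style <- match.arg(state_style)
  if (!("date" %in% names(column_map))) {
    stop("dialect error: column_map must map the `date` field", call. = FALSE)
  }
  if (!any(c("state", "city") %in% names(column_map))) {
    stop("dialect error: column_map must map `state` or `city`", call. = FALSE)
  }
  structure(
    list(
      source = source, column_map = column_map, date_format = date_format,
      victim_count_basis = victim_count_basis, encoding = encoding,
      delim = delim, state_style = state_style, list_sep = list_sep,
      victim_level = isTRUE(victim_level),
      combined_location = isTRUE(combined_location)
    ),
    class = "source_dialect"
  )
}

#' @rdname source_dialect
#' @param path Path to a dialect YAML file.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  source_dialect(
    source = cfg$source, column_map = cfg$column_map,
    date_format = cfg$date_format,
    victim_count_basis = cfg$victim_count_basis,
    encoding = cfg$encoding %||% "UTF-8", delim = cfg$delim %||% ",",
    state_style = cfg$state_style %||% "usps",
    list_sep = cfg$list_sep %||% ";",
    victim_level = cfg$victim_level %||% FALSE,
    combined_location = cfg$combined_location %||% FALSE
  )
}

#' @rdname source_dialect
#' @export
bundled_dialect <- function(source) {
  source <- match.arg(source, ms_sources())
  path <- system.file("extdata", "dialects",
    paste0(tolower(source), ".yaml"),
    package = "msdblink"
  )
  if (!nzchar(path)) stop("bundled dialect not found for ", source)
  read_dialect(path)
}

#' @export
print.source_dialect <- function(x, ...) {
  cat(sprintf(
    "<source_dialect %s: %d mapped columns, dates '%s', %s%s>\n",
    x$source, length(x$column_map), x$date_format,
    x$victim_count_basis,
    if (x$victim_level) ", victim-level" else ""
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
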