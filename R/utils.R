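# Internal parsing helpers shared by the readers and the generator.

# Strict date parsing: a value parses only if formatting the parsed date back
# with the same format reproduces the (squished) input. This rejects
# impossible dates ("2013-02-30") and partially matching strings without any
# imputation.
strict_parse_date <- function(x, format) {
  x <- stringr::str_squish(as.character(x))
  d <- as.Date(x, format = format)
  ok <- !is.na(d) & !is.na(x)
  # round-trip check; formats with non-padded components still round-trip
  # because the generator writes with the same format string
  rt <- rep(NA_character_, length(x))
  rt[ok] <- format(d[ok], format = format)
  mismatch <- ok & !is.na(rt) & (rt != x)
  d[mismatch | !ok] <- as.Date(NA)
  d
}

parse_bool <- function(x) {
  x <- tolower(stringr::str_squish(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("y", "yes", "true", "t", "1", "died", "deceased", "dead")] <- TRUE
  out[x %in% c("n", "no", "false", "f", "0", "survived", "alive", "apprehended")] <- FALSE
  out
}

parse_count <- function(x) {
  n <- suppressWarnings(as.integer(stringr::str_squish(as.character(x))))
  n[!is.na(n) & n < 0] <- NA_integer_
  n
}

split_names <- function(x, sep = ";") {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(stringr::str_squish(s))) {
      return(character(0))
    }
    v <- stringr::str_squish(strsplit(s, sep, fixed = TRUE)[[1]])
    v[nzchar(v)]
  })
}

join_names <- function(lst, sep = "; ") {
  vapply(lst, function(v) {
    if (length(v) == 0) "" else paste(v, collapse = sep)
  }, character(1))
}

# canonical empty harmonized-record tibble; the single schema used throughout
empty_records <- function() {
  tibble::tibble(
    source = character(),
    source_id = character(),
    date = as.Date(character()),
    state = character(),
    city = character(),
    shooter_names = list(),
    n_shooters = integer(),
    killed_excl_perp = integer(),
    injured_excl_perp = integer(),
    perp_died = logical(),
    motive = character(),
    location_type = character(),
    low_confidence = logical()
  )
}

record_key <- function(records) {
  paste(records$source, records$source_id, sep = "/")
}

assert_records <- function(records, what = "records") {
  need <- setdiff(names(empty_records()), "low_confidence")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required columns: %s", what,
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(records)
}
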