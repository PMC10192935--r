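#' Source, motive and location vocabularies
#'
#' `ms_sources()` returns the five database identifiers in canonical merge
#' priority order (used for tie-breaking when sources disagree on a field):
#' SHR, ASR, EVERYTOWN, MJ, GVA. `ms_motives()` and `ms_location_types()`
#' return the controlled vocabularies used by the harmonized record schema.
#'
#' @return A character vector.
#' @export
ms_sources <- function() c("SHR", "ASR", "EVERYTOWN", "MJ", "GVA")

#' @rdname ms_sources
#' @export
ms_motives <- function() {
  c("GANG", "DRUG", "FAMILY_IPV", "ROBBERY", "TERROR", "OTHER", "UNKNOWN")
}

#' @rdname ms_sources
#' @export
ms_location_types <- function() {
  c("PUBLIC", "RESIDENCE", "MULTIPLE", "OTHER", "UNKNOWN")
}

# Default study window: the years for which all five databases have data.
STUDY_START <- as.Date("2013-01-01")
STUDY_END <- as.Date("2020-12-31")

# state lookup: full names (plus DC) -> USPS codes
state_table <- function() {
  tibble::tibble(
    name = c(datasets::state.name, "District of Columbia"),
    abb = c(datasets::state.abb, "DC")
  )
}

#' Normalize a state designation to a USPS code
#'
#' Accepts two-letter USPS codes (any case) or full state names (plus the
#' District of Columbia). Values that match neither are returned verbatim
#' with a warning attribute left to the caller; they are never dropped.
#'
#' @param x Character vector of state names or codes.
#' @return Character vector of USPS codes where matchable, input verbatim
#'   otherwise (trimmed).
#' @export
normalize_state <- function(x) {
  tab <- state_table()
  x <- stringr::str_squish(as.character(x))
  up <- toupper(x)
  out <- ifelse(up %in% tab$abb, up, NA_character_)
  byname <- tab$abb[match(tolower(x), tolower(tab$name))]
  out <- ifelse(is.na(out), byname, out)
  ifelse(is.na(out), x, out)
}

state_full_name <- function(abb) {
  tab <- state_table()
  nm <- tab$name[match(toupper(abb), tab$abb)]
  ifelse(is.na(nm), abb, nm)
}

# SHR weapon codes treated as firearms (configurable in subset_shr).
DEFAULT_FIREARM_CODES <- c(
  "Firearm, type not stated",
  "Handgun - pistol, revolver, etc",
  "Rifle",
  "Shotgun",
  "Other gun"
)

SHR_NONFIREARM_CODES <- c(
  "Knife or cutting instrument",
  "Blunt object - hammer, club, etc",
  "Personal weapons, includes beating",
  "Strangulation - hanging",
  "Fire",
  "Asphyxiation - includes death by gas"
)
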