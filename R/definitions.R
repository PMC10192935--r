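#' Declarative inclusion definitions
#'
#' A `definition` encodes one database's mass-shooting inclusion criteria as
#' evaluable rules: the victim-count basis (fatalities only, or fatalities +
#' injuries), a minimum count, shooter-count bounds, whether the shooter must
#' be identified, motives that disqualify an incident, and an optional
#' public-location restriction. An `allow_list` of record identifiers can
#' exempt specific incidents from all rules (the mechanism behind Mother
#' Jones's two documented two-shooter school-shooting exceptions; empty by
#' default).
#'
#' @param name Definition name.
#' @param count_basis `"FATALITIES"`, `"CASUALTIES"`, or `NA` when the
#'   definition has no victim-count threshold (the active-shooter case).
#' @param min_count Minimum count on `count_basis`; 0 disables the rule.
#' @param perp_excluded Logical; counts exclude the perpetrator (all five
#'   presets do).
#' @param min_shooters,max_shooters Integer bounds on the number of shooters
#'   (`NA` = unbounded).
#' @param shooter_must_be_known Logical; require at least one named shooter.
#' @param excluded_motives Character subset of `ms_motives()` that
#'   disqualifies an incident.
#' @param location_restriction `"NONE"` or `"PUBLIC_ONLY"`.
#' @param allow_list Character vector of record identifiers that are eligible
#'   regardless of the rules.
#' @return A `ms_definition` object.
#' @export
definition <- function(name, count_basis = "FATALITIES", min_count = 0L,
                       perp_excluded = TRUE, min_shooters = NA_integer_,
                       max_shooters = NA_integer_,
                       shooter_must_be_known = FALSE,
                       excluded_motives = character(),
                       location_restriction = c("NONE", "PUBLIC_ONLY"),
                       allow_list = character()) {
  location_restriction <- match.arg(location_restriction)
  if (!is.na(count_basis)) {
    count_basis <- match.arg(count_basis, c("FATALITIES", "CASUALTIES"))
  }
  min_count <- as.integer(min_count)
  stopifnot(min_count >= 0)
  if (!is.na(min_shooters) && !is.na(max_shooters)) {
    stopifnot(min_shooters <= max_shooters)
  }
  bad <- setdiff(excluded_motives, ms_motives())
  if (length(bad) > 0) stop("unknown motives: ", paste(bad, collapse = ", "))
  structure(
    list(
      name = name, count_basis = count_basis, min_count = min_count,
      perp_excluded = isTRUE(perp_excluded),
      min_shooters = as.integer(min_shooters),
      max_shooters = as.integer(max_shooters),
      shooter_must_be_known = isTRUE(shooter_must_be_known),
      excluded_motives = excluded_motives,
      location_restriction = location_restriction,
      allow_list = allow_list
    ),
    class = "ms_definition"
  )
}

#' @export
print.ms_definition <- function(x, ...) {
  thr <- if (is.na(x$count_basis)) {
    "no victim-count threshold"
  } else {
    sprintf("%d+ %s", x$min_count, tolower(x$count_basis))
  }
  cat(sprintf(
    "<definition %s: %s (perp %s); shooters [%s, %s]%s%s%s>\n",
    x$name, thr, if (x$perp_excluded) "excluded" else "included",
    ifelse(is.na(x$min_shooters), "any", x$min_shooters),
    ifelse(is.na(x$max_shooters), "any", x$max_shooters),
    if (x$shooter_must_be_known) "; shooter must be known" else "",
    if (length(x$excluded_motives) > 0) {
      paste0("; excludes ", paste(x$excluded_motives, collapse = "/"))
    } else {
      ""
    },
    if (x$location_restriction != "NONE") "; public only" else ""
  ))
  invisible(x)
}

#' The five bundled database definitions
#'
#' `preset_definition(source)` returns the inclusion criteria of one of the
#' five databases; `preset_definitions()` returns all five as a named list.
#' Presets are loaded from the human-editable file
#' `inst/extdata/definitions.yaml`:
#'
#' * **SHR** (mass-killing subset): 4+ killed (excluding shooter), exactly 1
#'   shooter, any motive or location.
#' * **ASR**: no victim-count threshold; excludes gang, drug and
#'   partner/family violence ("random" incidents only).
#' * **MJ**: 3+ killed (excluding shooter), 1 shooter who must be
#'   known/identified; excludes robbery, gang and partner/family violence.
#' * **EVERYTOWN**: 4+ killed (excluding shooter), any motive or location.
#' * **GVA**: 4+ injured or killed (excluding shooter), 1–2 shooters, any
#'   motive or location.
#'
#' @param source One of `ms_sources()`.
#' @param path Optional path to an alternative definitions YAML file.
#' @return A `ms_definition` (or named list of them).
#' @export
preset_definition <- function(source, path = NULL) {
  source <- match.arg(source, ms_sources())
  preset_definitions(path)[[source]]
}

#' @rdname preset_definition
#' @export
preset_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "definitions.yaml", package = "msdblink")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    d <- cfg[[nm]]
    definition(
      name = nm,
      count_basis = d$count_basis %||% NA_character_,
      min_count = d$min_count %||% 0L,
      perp_excluded = d$perp_excluded %||% TRUE,
      min_shooters = d$min_shooters %||% NA_integer_,
      max_shooters = d$max_shooters %||% NA_integer_,
      shooter_must_be_known = d$shooter_must_be_known %||% FALSE,
      excluded_motives = unlist(d$excluded_motives) %||% character(),
      location_restriction = d$location_restriction %||% "NONE",
      allow_list = unlist(d$allow_list) %||% character()
    )
  })
  setNames(out, names(cfg))
}

#' Evaluate records against a definition
#'
#' Applies every rule of a definition to each record and reports, per record,
#' eligibility and the identifiers of failed rules. Unknown fields fail
#' *closed* for count rules (a record with unknown fatalities cannot clear a
#' fatality threshold; rule id recorded) and fail *open* for motive/location
#' rules (an unknown motive is not treated as excluded); both policies are
#' configurable.
#'
#' For the casualty basis, a record with one unknown count is still eligible
#' when the known part alone reaches the threshold (the count can only grow).
#'
#' @param records Harmonized records (tibble).
#' @param def A [definition()].
#' @param unknown_counts `"fail_closed"` (default) or `"fail_open"`.
#' @param unknown_motive `"fail_open"` (default) or `"fail_closed"`.
#' @return A tibble with columns `eligible` (logical) and `failed_rules`
#'   (list of character vectors); `eligible` is `TRUE` iff `failed_rules` is
#'   empty. Rule ids: `MIN_FATALITIES`, `MIN_CASUALTIES`, `SHOOTER_COUNT`,
#'   `SHOOTER_KNOWN`, `MOTIVE_EXCLUDED`, `LOCATION`.
#' @export
evaluate_definition <- function(records, def,
                                unknown_counts = c("fail_closed", "fail_open"),
                                unknown_motive = c("fail_open", "fail_closed")) {
  stopifnot(inherits(def, "ms_definition"))
  unknown_counts <- match.arg(unknown_counts)
  unknown_motive <- match.arg(unknown_motive)
  n <- nrow(records)
  fails <- vector("list", n)
  add_fail <- function(which, rule) {
    for (i in which(which)) fails[[i]] <<- c(fails[[i]], rule)
  }

  killed <- records$killed_excl_perp
  injured <- records$injured_excl_perp

  if (!is.na(def$count_basis) && def$min_count > 0) {
    rule <- paste0("MIN_", def$count_basis)
    if (def$count_basis == "FATALITIES") {
      known_pass <- !is.na(killed) & killed >= def$min_count
      unknown <- is.na(killed)
    } else {
      # casualty lower bound from the known parts
      lower <- ifelse(is.na(killed), 0L, killed) +
        ifelse(is.na(injured), 0L, injured)
      known_pass <- lower >= def$min_count
      unknown <- (is.na(killed) | is.na(injured)) & !known_pass
    }
    fail <- !known_pass & (!unknown | unknown_counts == "fail_closed")
    add_fail(fail, rule)
  }

  if (!is.na(def$min_shooters) || !is.na(def$max_shooters)) {
    ns <- records$n_shooters
    ok <- !is.na(ns) &
      (is.na(def$min_shooters) | ns >= def$min_shooters) &
      (is.na(def$max_shooters) | ns <= def$max_shooters)
    fail <- !ok & (!is.na(ns) | unknown_counts == "fail_closed")
    add_fail(fail, "SHOOTER_COUNT")
  }

  if (def$shooter_must_be_known) {
    known <- vapply(records$shooter_names, length, integer(1)) > 0
    add_fail(!known, "SHOOTER_KNOWN")
  }

  if (length(def$excluded_motives) > 0) {
    motive <- records$motive
    motive[is.na(motive)] <- "UNKNOWN"
    excluded <- vapply(
      strsplit(motive, ";", fixed = TRUE),
      function(m) any(stringr::str_squish(m) %in% def$excluded_motives),
      logical(1)
    )
    unknown <- motive == "UNKNOWN"
    fail <- excluded | (unknown & unknown_motive == "fail_closed")
    add_fail(fail, "MOTIVE_EXCLUDED")
  }

  if (def$location_restriction == "PUBLIC_ONLY") {
    loc <- records$location_type
    loc[is.na(loc)] <- "UNKNOWN"
    unknown <- loc == "UNKNOWN"
    fail <- (!unknown & loc != "PUBLIC") | (unknown & unknown_motive == "fail_closed")
    add_fail(fail, "LOCATION")
  }

  if (length(def$allow_list) > 0 && "source_id" %in% names(records)) {
    allowed <- records$source_id %in% def$allow_list
    fails[allowed] <- list(character(0))
  }
  fails[vapply(fails, is.null, logical(1))] <- list(character(0))
  tibble::tibble(
    eligible = vapply(fails, length, integer(1)) == 0,
    failed_rules = fails
  )
}

#' Re-filter records or clusters at a common fatality threshold
#'
#' The sensitivity re-analysis applies the most conservative fatality
#' threshold used across the databases (four or more, perpetrator excluded)
#' to every record or incident cluster, so all sources are compared under a
#' single definition. Records with unknown fatality counts cannot clear the
#' threshold and are excluded with reason `UNKNOWN_FATALITIES`.
#'
#' @param x A tibble with a `killed_excl_perp` column (records or cluster
#'   canonical rows).
#' @param min_fatalities Threshold; retained iff
#'   `killed_excl_perp >= min_fatalities`.
#' @return A list with tibbles `retained` and `excluded`; the latter carries
#'   an `excluded_reason` column (`BELOW_THRESHOLD` / `UNKNOWN_FATALITIES`).
#' @export
apply_fatality_threshold <- function(x, min_fatalities = 4L) {
  min_fatalities <- as.integer(min_fatalities)
  stopifnot(min_fatalities >= 0)
  killed <- x$killed_excl_perp
  keep <- !is.na(killed) & killed >= min_fatalities
  excluded <- x[!keep, , drop = FALSE]
  excluded$excluded_reason <- ifelse(
    is.na(killed[!keep]), "UNKNOWN_FATALITIES", "BELOW_THRESHOLD"
  )
  list(retained = x[keep, , drop = FALSE], excluded = excluded)
}

#' Per-source exclusion accounting under a definitional filter
#'
#' Given each source's total incident count and the count surviving a filter,
#' returns the per-source excluded counts (`total - surviving`) — the
#' arithmetic relating a per-source totals table to its filtered counterpart.
#'
#' @param totals Named numeric vector of per-source totals.
#' @param surviving Named numeric vector of per-source surviving counts;
#'   names must match `totals`.
#' @return A tibble with columns `source`, `total`, `surviving`, `excluded`.
#' @export
filter_ledger <- function(totals, surviving) {
  if (!setequal(names(totals), names(surviving)) || is.null(names(totals))) {
    stop("totals and surviving must be named over the same sources", call. = FALSE)
  }
  surviving <- surviving[names(totals)]
  if (any(surviving > totals)) {
    stop("consistency error: surviving exceeds total for ",
      paste(names(totals)[surviving > totals], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    source = names(totals),
    total = as.numeric(totals),
    surviving = as.numeric(surviving),
    excluded = as.numeric(totals) - as.numeric(surviving)
  )
}
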