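#' Read one database export into harmonized incident records
#'
#' Parses a source CSV according to its dialect, harmonizes states to USPS
#' codes, converts perpetrator-inclusive killed counts to
#' perpetrator-exclusive ones where the perpetrator's death is known, and
#' collects (rather than silently drops) rows whose dates do not parse.
#'
#' Dates are parsed strictly against the dialect's format: impossible
#' calendar dates ("2013-02-30") and malformed strings are routed to the
#' error report. When the dialect counts the perpetrator among the dead
#' (`victim_count_basis == "INCLUDES_PERP"`), one is subtracted from the
#' killed count when the perpetrator is known to have died; when the
#' perpetrator's fate is unknown the count is kept as read and the record is
#' flagged `low_confidence`.
#'
#' For victim-level dialects (SHR) each CSV row is one victim; the returned
#' records are victim rows carrying `agency`, `incident_num` and `weapon`
#' columns, and [subset_shr()] performs the incident-level aggregation.
#'
#' @param path Path to the CSV file.
#' @param dialect A [source_dialect()].
#' @return A list with elements `records` (harmonized tibble; see Details)
#'   and `errors` (tibble with columns `row`, `field`, `value`, `problem`).
#'   `nrow(records) + nrow(errors)` equals the number of data rows in the
#'   file.
#' @export
load_source <- function(path, dialect) {
  stopifnot(inherits(dialect, "source_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path,
    delim = dialect$delim, col_types = readr::cols(.default = "c"),
    locale = readr::locale(encoding = dialect$encoding),
    progress = FALSE, show_col_types = FALSE
  )
  cmap <- dialect$column_map
  missing_cols <- setdiff(unlist(cmap), names(raw))
  if (nrow(raw) == 0 && length(missing_cols) == length(cmap)) {
    warning("empty file: ", path, call. = FALSE)
    return(list(records = empty_records(), errors = parse_error_tbl()))
  }
  if (length(missing_cols) > 0) {
    stop(
      "dialect error: columns not in file: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) {
    warning("empty file: ", path, call. = FALSE)
    return(list(records = empty_records(), errors = parse_error_tbl()))
  }

  col <- function(field) {
    if (!is.null(cmap[[field]])) raw[[cmap[[field]]]] else rep(NA_character_, nrow(raw))
  }

  date <- strict_parse_date(col("date"), dialect$date_format)
  bad <- is.na(date)
  errors <- tibble::tibble(
    row = which(bad),
    field = "date",
    value = as.character(col("date"))[bad],
    problem = "unparseable date"
  )

  city <- stringr::str_squish(col("city"))
  state <- stringr::str_squish(col("state"))
  if (dialect$combined_location) {
    # "City, State" in a single column
    loc <- stringr::str_match(city, "^(.*?),\\s*(.+)$")
    state <- ifelse(is.na(loc[, 3]), NA_character_, loc[, 3])
    city <- ifelse(is.na(loc[, 2]), city, loc[, 2])
  }
  state <- normalize_state(state)
  state[is.na(state) | state == ""] <- NA_character_
  city[city == ""] <- NA_character_

  killed <- parse_count(col("killed"))
  injured <- parse_count(col("injured"))
  perp_died <- parse_bool(col("perp_died"))
  low_confidence <- rep(FALSE, nrow(raw))
  if (dialect$victim_count_basis == "INCLUDES_PERP") {
    adj <- !is.na(killed) & !is.na(perp_died) & perp_died
    killed[adj] <- pmax(killed[adj] - 1L, 0L)
    low_confidence <- !is.na(killed) & is.na(perp_died)
  } else if (dialect$victim_count_basis == "UNKNOWN") {
    low_confidence <- !is.na(killed)
  }

  motive <- toupper(stringr::str_squish(col("motive")))
  motive[!(motive %in% ms_motives())] <- NA_character_
  motive[is.na(motive)] <- "UNKNOWN"
  loc_type <- toupper(stringr::str_squish(col("location_type")))
  loc_type[!(loc_type %in% ms_location_types())] <- NA_character_
  loc_type[is.na(loc_type)] <- "UNKNOWN"

  if (dialect$victim_level) {
    source_id <- paste0(
      stringr::str_squish(col("agency")), "-",
      stringr::str_squish(col("incident_num")), "#", seq_len(nrow(raw))
    )
  } else {
    source_id <- stringr::str_squish(col("source_id"))
  }

  records <- tibble::tibble(
    source = dialect$source,
    source_id = source_id,
    date = date,
    state = state,
    city = city,
    shooter_names = split_names(col("shooter_names"), dialect$list_sep),
    n_shooters = parse_count(col("n_shooters")),
    killed_excl_perp = if (dialect$victim_level) NA_integer_ else killed,
    injured_excl_perp = if (dialect$victim_level) NA_integer_ else injured,
    perp_died = perp_died,
    motive = motive,
    location_type = loc_type,
    low_confidence = low_confidence
  )
  if (dialect$victim_level) {
    records$agency <- stringr::str_squish(col("agency"))
    records$incident_num <- stringr::str_squish(col("incident_num"))
    records$weapon <- stringr::str_squish(col("weapon"))
  }
  records <- records[!bad, , drop = FALSE]
  if (anyDuplicated(records$source_id) > 0) {
    warning("duplicate source_id values within ", dialect$source, call. = FALSE)
  }
  list(records = records, errors = errors)
}

parse_error_tbl <- function() {
  tibble::tibble(
    row = integer(), field = character(),
    value = character(), problem = character()
  )
}

#' Subset victim-level SHR rows to mass-killing incidents
#'
#' The SHR is victim-level: one row per homicide victim. Rows are grouped
#' into incidents by (agency, incident number, date) — the standard SHR
#' convention, configurable via `group_cols` — and an incident is retained
#' when it has a single offender and four or more firearm fatalities
#' (perpetrator excluded, as SHR victims never include the offender).
#' Non-retained incidents carry a reason code; incidents with weapon codes
#' recognizable as neither firearm nor non-firearm are routed to a review
#' list rather than silently kept or dropped.
#'
#' @param records Victim-level SHR records from [load_source()] (must carry
#'   `agency`, `incident_num`, `weapon` columns).
#' @param min_fatalities Fatality threshold (default 4, the traditional
#'   mass-murder threshold).
#' @param firearm_codes Weapon-code strings treated as firearms.
#' @param nonfirearm_codes Weapon-code strings recognized as non-firearms;
#'   anything in neither set is an unknown weapon.
#' @param group_cols Columns defining an SHR incident.
#' @return A list: `records` (retained incident-level records with
#'   `killed_excl_perp` = firearm fatality count), `dropped` (incident-level
#'   tibble with a `reason` column: `SHOOTER_COUNT`, `FATALITY_THRESHOLD` or
#'   `NON_FIREARM`), `review` (incidents with unknown weapon codes).
#' @export
subset_shr <- function(records, min_fatalities = 4L,
                       firearm_codes = DEFAULT_FIREARM_CODES,
                       nonfirearm_codes = SHR_NONFIREARM_CODES,
                       group_cols = c("agency", "incident_num", "date")) {
  if (nrow(records) == 0) {
    return(list(
      records = empty_records(), dropped = empty_records(),
      review = empty_records()
    ))
  }
  stopifnot(all(records$source == "SHR"))
  need <- c(group_cols, "weapon")
  if (!all(need %in% names(records))) {
    stop(
      "subset_shr needs victim-level records with columns: ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  grp <- records %>%
    group_by(across(all_of(group_cols))) %>%
    summarise(
      source = first(.data$source),
      state = first(.data$state),
      city = first(.data$city),
      shooter_names = list(unique(unlist(.data$shooter_names))),
      n_shooters = first(.data$n_shooters),
      perp_died = first(.data$perp_died),
      motive = first(.data$motive),
      location_type = first(.data$location_type),
      n_victims = dplyr::n(),
      n_firearm = sum(.data$weapon %in% firearm_codes),
      n_unknown_weapon = sum(!(.data$weapon %in% c(firearm_codes, nonfirearm_codes))),
      .groups = "drop"
    ) %>%
    mutate(
      source_id = paste0(.data$agency, "-", .data$incident_num),
      killed_excl_perp = as.integer(.data$n_firearm),
      injured_excl_perp = NA_integer_,
      low_confidence = FALSE
    ) %>%
    arrange(.data$date, .data$state, .data$source_id)

  is_review <- grp$n_unknown_weapon > 0
  reason <- dplyr::case_when(
    is.na(grp$n_shooters) | grp$n_shooters != 1L ~ "SHOOTER_COUNT",
    grp$n_firearm == 0 & grp$n_victims > 0 ~ "NON_FIREARM",
    grp$killed_excl_perp < min_fatalities ~ "FATALITY_THRESHOLD",
    TRUE ~ NA_character_
  )
  keep <- !is_review & is.na(reason)
  cols <- c(names(empty_records()), "agency", "incident_num")
  list(
    records = grp[keep, cols, drop = FALSE],
    dropped = dplyr::bind_cols(
      grp[!is_review & !is.na(reason), cols, drop = FALSE],
      tibble::tibble(reason = reason[!is_review & !is.na(reason)])
    ),
    review = grp[is_review, cols, drop = FALSE]
  )
}

#' Restrict records to a study window
#'
#' Retains records whose date lies in the closed interval `[start, end]`.
#' Records with unknown dates never satisfy the window and are dropped.
#'
#' @param records Harmonized records.
#' @param start,end Window bounds (`Date` or parseable strings);
#'   `start <= end`. Defaults: 2013-01-01 to 2020-12-31, the years for which
#'   all five databases have data.
#' @return The retained records.
#' @export
filter_window <- function(records, start = STUDY_START, end = STUDY_END) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(start <= end)
  records[!is.na(records$date) & records$date >= start & records$date <= end, ,
    drop = FALSE
  ]
}
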