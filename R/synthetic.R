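#' Configuration of the synthetic incident universe
#'
#' The generator draws a ground-truth universe of shooting incidents whose
#' heterogeneity mirrors what the five databases disagree about: casualty
#' severity is overdispersed (zero-truncated negative binomial — mostly
#' small counts, rare large ones), motives span the categories some
#' databases exclude (gang, drug, family/intimate-partner, robbery, terror),
#' a minority of incidents have two shooters, and the perpetrator dies in a
#' configurable fraction of incidents. Means are the means of the
#' *truncated* distributions.
#'
#' @param n_incidents Number of ground-truth incidents.
#' @param start,end Date range (uniform sampling).
#' @param fatality_mean,fatality_dispersion Zero-truncated negative binomial
#'   parameters for fatalities (perpetrator excluded); dispersion is the NB
#'   size parameter.
#' @param injury_mean,injury_dispersion Same family, for injuries.
#' @param motive_probs Named probabilities over `ms_motives()` (no UNKNOWN:
#'   ground truth is fully observed); must sum to 1.
#' @param location_probs Named probabilities over location types.
#' @param p_perp_dies Probability the perpetrator dies.
#' @param p_two_shooters Probability of a two-shooter incident.
#' @param seed Integer seed; identical seeds give identical universes.
#' @return A `universe_config` list.
#' @export
universe_config <- function(n_incidents = 2000,
                            start = STUDY_START, end = STUDY_END,
                            fatality_mean = 2.0, fatality_dispersion = 1.0,
                            injury_mean = 3.0, injury_dispersion = 1.0,
                            motive_probs = c(
                              GANG = 0.25, FAMILY_IPV = 0.25, DRUG = 0.10,
                              ROBBERY = 0.05, TERROR = 0.02, OTHER = 0.33
                            ),
                            location_probs = c(
                              PUBLIC = 0.30, RESIDENCE = 0.40,
                              MULTIPLE = 0.05, OTHER = 0.25
                            ),
                            p_perp_dies = 0.2, p_two_shooters = 0.05,
                            seed = 1L) {
  if (abs(sum(motive_probs) - 1) > 1e-8 || any(motive_probs < 0)) {
    stop("config error: motive_probs must be nonnegative and sum to 1",
      call. = FALSE
    )
  }
  if (abs(sum(location_probs) - 1) > 1e-8 || any(location_probs < 0)) {
    stop("config error: location_probs must be nonnegative and sum to 1",
      call. = FALSE
    )
  }
  for (p in c(p_perp_dies, p_two_shooters)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(
    n_incidents >= 0, fatality_mean > 1, injury_mean > 1,
    fatality_dispersion > 0, injury_dispersion > 0
  )
  structure(
    list(
      n_incidents = as.integer(n_incidents),
      start = as.Date(start), end = as.Date(end),
      fatality_mean = fatality_mean,
      fatality_dispersion = fatality_dispersion,
      injury_mean = injury_mean, injury_dispersion = injury_dispersion,
      motive_probs = motive_probs, location_probs = location_probs,
      p_perp_dies = p_perp_dies, p_two_shooters = p_two_shooters,
      seed = as.integer(seed)
    ),
    class = "universe_config"
  )
}

# zero-truncated negative binomial with a target mean for the truncated
# distribution: solve for the underlying NB mu, then inverse-CDF sample
# conditional on > 0
ztnb_mu <- function(target_mean, size) {
  f <- function(mu) mu / (1 - (size / (size + mu))^size) - target_mean
  uniroot(f, c(1e-9, 10 * target_mean + 10), tol = 1e-10)$root
}

r_ztnbinom <- function(n, mean, dispersion) {
  if (n == 0) {
    return(integer(0))
  }
  mu <- ztnb_mu(mean, dispersion)
  p0 <- pnbinom(0, size = dispersion, mu = mu)
  u <- runif(n, min = p0, max = 1)
  as.integer(qnbinom(u, size = dispersion, mu = mu))
}

#' Generate the ground-truth incident universe
#'
#' @param cfg A [universe_config()].
#' @return A tibble in the harmonized record schema (with `source =
#'   "TRUTH"`, `source_id = incident_id`) plus an `incident_id` column.
#'   Reproducible: identical configs (including seed) give identical output.
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "universe_config"))
  n <- cfg$n_incidents
  if (n == 0) {
    out <- empty_records()
    out$incident_id <- character(0)
    return(out)
  }
  set.seed(cfg$seed)
  days <- seq(cfg$start, cfg$end, by = "day")
  cities <- us_cities()
  pick <- sample.int(nrow(cities), n, replace = TRUE)
  n_shooters <- 1L + rbinom(n, 1L, cfg$p_two_shooters)
  firsts <- synthetic_first_names()
  lasts <- synthetic_last_names()
  shooter_names <- lapply(n_shooters, function(k) {
    paste(sample(firsts, k, replace = TRUE), sample(lasts, k, replace = TRUE))
  })
  tibble::tibble(
    source = "TRUTH",
    source_id = sprintf("I%05d", seq_len(n)),
    date = sample(days, n, replace = TRUE),
    state = cities$state[pick],
    city = cities$city[pick],
    shooter_names = shooter_names,
    n_shooters = n_shooters,
    killed_excl_perp = r_ztnbinom(n, cfg$fatality_mean, cfg$fatality_dispersion),
    injured_excl_perp = r_ztnbinom(n, cfg$injury_mean, cfg$injury_dispersion),
    perp_died = rbinom(n, 1L, cfg$p_perp_dies) == 1L,
    motive = sample(names(cfg$motive_probs), n,
      replace = TRUE,
      prob = cfg$motive_probs
    ),
    location_type = sample(names(cfg$location_probs), n,
      replace = TRUE,
      prob = cfg$location_probs
    ),
    low_confidence = FALSE,
    incident_id = sprintf("I%05d", seq_len(n))
  )
}

#' Per-source emission model
#'
#' Describes how one database samples the incident universe: its inclusion
#' definition (an incident ineligible under the definition is never
#' emitted), an imperfect detection probability, and field-perturbation
#' rates that create imperfect duplicates (date shifted by one day, a
#' one-character city typo, casualty counts off by one, missing shooter
#' names).
#'
#' @param source One of `ms_sources()`.
#' @param definition Inclusion criteria; defaults to the source's preset.
#' @param detection_prob Probability an eligible incident is listed.
#' @param p_date_shift,p_city_typo,p_count_off_by_one,p_missing_name
#'   Per-record perturbation rates.
#' @return A `source_model` object.
#' @export
source_model <- function(source, definition = preset_definition(source),
                         detection_prob = 0.95, p_date_shift = 0.05,
                         p_city_typo = 0.05, p_count_off_by_one = 0.05,
                         p_missing_name = 0.05) {
  source <- match.arg(source, ms_sources())
  rates <- c(
    detection_prob, p_date_shift, p_city_typo,
    p_count_off_by_one, p_missing_name
  )
  if (any(is.na(rates) | rates < 0 | rates > 1)) {
    stop("config error: rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      source = source, definition = definition,
      detection_prob = detection_prob, p_date_shift = p_date_shift,
      p_city_typo = p_city_typo, p_count_off_by_one = p_count_off_by_one,
      p_missing_name = p_missing_name
    ),
    class = "source_model"
  )
}

#' @rdname source_model
#' @param perturb Logical; `FALSE` sets all perturbation rates to 0 and
#'   detection to 1 (a perfect-observation bundle for oracle tests).
#' @export
default_source_models <- function(detection_prob = 0.95, perturb = TRUE) {
  rate <- if (perturb) 0.05 else 0
  det <- if (perturb) detection_prob else 1
  setNames(lapply(ms_sources(), function(s) {
    source_model(s,
      detection_prob = det, p_date_shift = rate, p_city_typo = rate,
      p_count_off_by_one = rate, p_missing_name = rate
    )
  }), ms_sources())
}

# one random single-character edit (substitute / insert / delete)
make_typo <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  op <- sample(c("sub", "ins", "del"), 1)
  if (op == "del" && n > 1) {
    i <- sample.int(n, 1)
    return(paste(chars[-i], collapse = ""))
  }
  if (op == "ins") {
    i <- sample.int(n + 1, 1)
    return(paste(append(chars, sample(letters, 1), after = i - 1),
      collapse = ""
    ))
  }
  i <- sample.int(n, 1)
  chars[i] <- sample(letters, 1)
  paste(chars, collapse = "")
}

#' Emit one source's records from the universe
#'
#' Applies the model's definition to the ground-truth fields (eligibility is
#' recorded *pre-perturbation*: a listed count can later disagree with the
#' truth, as in real databases), thins eligible incidents by the detection
#' probability, then perturbs fields at the stated rates.
#'
#' @param incidents Universe tibble from [generate_universe()].
#' @param model A [source_model()].
#' @param seed Integer seed for detection and perturbation draws.
#' @return A list: `records` (harmonized records for the source; for SHR
#'   they carry `agency`, `incident_num` and `weapon` columns used by the
#'   victim-level writer), `links` (tibble `incident_id`, `source`,
#'   `source_id` — the ground truth), `n_eligible`.
#' @export
emit_source <- function(incidents, model, seed = 1L) {
  stopifnot(inherits(model, "source_model"))
  set.seed(as.integer(seed))
  verdict <- evaluate_definition(incidents, model$definition)
  eligible <- incidents[verdict$eligible, , drop = FALSE]
  n_eligible <- nrow(eligible)
  detected <- runif(n_eligible) <= model$detection_prob
  rec <- eligible[detected, , drop = FALSE]
  n <- nrow(rec)
  rec$source <- model$source
  rec$source_id <- paste0(model$source, "-", sub("^I", "", rec$incident_id))

  if (n > 0) {
    shift <- runif(n) < model$p_date_shift
    rec$date[shift] <- rec$date[shift] +
      sample(c(-1L, 1L), sum(shift), replace = TRUE)
    typo <- runif(n) < model$p_city_typo
    rec$city[typo] <- vapply(rec$city[typo], make_typo, character(1))
    for (fld in c("killed_excl_perp", "injured_excl_perp")) {
      off <- runif(n) < model$p_count_off_by_one
      delta <- sample(c(-1L, 1L), n, replace = TRUE)
      rec[[fld]][off] <- pmax(rec[[fld]][off] + delta[off], 0L)
    }
    drop_name <- runif(n) < model$p_missing_name
    rec$shooter_names[drop_name] <- list(character(0))
  }

  if (model$source == "SHR") {
    rec$agency <- paste0("AG-", rec$state)
    rec$incident_num <- sub("^SHR-", "", rec$source_id)
    rec$source_id <- paste0(rec$agency, "-", rec$incident_num)
    rec$weapon <- sample(DEFAULT_FIREARM_CODES, max(n, 1), replace = TRUE)[seq_len(n)]
    # the SHR export carries no injury information
    rec$injured_excl_perp <- NA_integer_
  }
  links <- tibble::tibble(
    incident_id = rec$incident_id, source = rec$source,
    source_id = rec$source_id
  )
  list(
    records = rec[, setdiff(names(rec), "incident_id"), drop = FALSE],
    links = links, n_eligible = n_eligible
  )
}

#' Write harmonized records as a source-dialect CSV
#'
#' The inverse of [load_source()]: formats dates with the dialect's format,
#' writes states as full names or USPS codes per the dialect, joins shooter
#' names, recombines "City, State" columns, adds the perpetrator back into
#' the killed count for perpetrator-inclusive dialects, and explodes
#' victim-level dialects (SHR) into one row per fatality.
#'
#' @param records Harmonized records (for victim-level dialects with
#'   `agency`, `incident_num`, `weapon` columns).
#' @param dialect A [source_dialect()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_source_csv <- function(records, dialect, path) {
  stopifnot(inherits(dialect, "source_dialect"))
  rec <- records
  if (dialect$victim_level) {
    reps <- ifelse(is.na(rec$killed_excl_perp), 0L, rec$killed_excl_perp)
    rec <- rec[rep(seq_len(nrow(rec)), reps), , drop = FALSE]
  }
  killed_out <- rec$killed_excl_perp
  if (dialect$victim_count_basis == "INCLUDES_PERP") {
    add <- !is.na(killed_out) & !is.na(rec$perp_died) & rec$perp_died
    killed_out[add] <- killed_out[add] + 1L
  }
  state_out <- if (dialect$state_style == "full") {
    state_full_name(rec$state)
  } else {
    rec$state
  }
  city_out <- if (dialect$combined_location) {
    paste0(rec$city, ", ", state_full_name(rec$state))
  } else {
    rec$city
  }
  value_for <- function(field) {
    switch(field,
      source_id = rec$source_id,
      agency = rec$agency,
      incident_num = rec$incident_num,
      weapon = rec$weapon,
      date = format(rec$date, dialect$date_format),
      state = state_out,
      city = city_out,
      shooter_names = join_names(rec$shooter_names, paste0(dialect$list_sep, " ")),
      n_shooters = rec$n_shooters,
      killed = killed_out,
      injured = rec$injured_excl_perp,
      perp_died = ifelse(is.na(rec$perp_died), "", as.character(rec$perp_died)),
      motive = rec$motive,
      location_type = rec$location_type,
      stop("no writer for field ", field)
    )
  }
  out <- lapply(names(dialect$column_map), value_for)
  names(out) <- unlist(dialect$column_map)
  out <- tibble::as_tibble(out)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a full five-source synthetic bundle
#'
#' Generates (or takes) a universe, emits all five source CSVs in their
#' bundled dialects, and writes the ground truth as a JSON-lines file (one
#' line per incident: true fields plus the per-source emitted record ids).
#'
#' @param incidents Universe from [generate_universe()].
#' @param models Named list of [source_model()]s (default: the five presets).
#' @param dir Output directory (created if needed).
#' @param seed Integer; per-source emission seeds are derived from it.
#' @return A list: `paths` (named CSV paths), `truth_path`, `links` (bound
#'   ground-truth links), `n_eligible` (named), `incidents`.
#' @export
write_source_bundle <- function(incidents, models = default_source_models(),
                                dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- character(0)
  links <- list()
  n_eligible <- integer(0)
  for (i in seq_along(models)) {
    model <- models[[i]]
    em <- emit_source(incidents, model, seed = seed + i)
    dialect <- bundled_dialect(model$source)
    p <- file.path(dir, paste0(tolower(model$source), ".csv"))
    write_source_csv(em$records, dialect, p)
    paths[model$source] <- p
    links[[model$source]] <- em$links
    n_eligible[model$source] <- em$n_eligible
  }
  links <- dplyr::bind_rows(links)
  truth_path <- file.path(dir, "ground_truth.jsonl")
  write_ground_truth(incidents, links, truth_path)
  list(
    paths = paths, truth_path = truth_path, links = links,
    n_eligible = n_eligible, incidents = incidents
  )
}

write_ground_truth <- function(incidents, links, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  by_inc <- split(links[, c("source", "source_id")], links$incident_id)
  for (i in seq_len(nrow(incidents))) {
    inc <- incidents[i, ]
    emits <- by_inc[[inc$incident_id]]
    line <- list(
      incident_id = inc$incident_id,
      date = format(inc$date, "%Y-%m-%d"),
      state = inc$state, city = inc$city,
      shooter_names = inc$shooter_names[[1]],
      n_shooters = inc$n_shooters,
      killed_excl_perp = inc$killed_excl_perp,
      injured_excl_perp = inc$injured_excl_perp,
      perp_died = inc$perp_died, motive = inc$motive,
      location_type = inc$location_type,
      emitted = if (is.null(emits)) {
        list()
      } else {
        setNames(as.list(emits$source_id), emits$source)
      }
    )
    writeLines(jsonlite::toJSON(line, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a ground-truth JSON-lines file
#'
#' @param path Path written by [write_source_bundle()].
#' @return A list: `incidents` (tibble in the universe schema), `links`
#'   (tibble `incident_id`, `source`, `source_id`).
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  parsed <- lapply(lines, jsonlite::fromJSON)
  incidents <- dplyr::bind_rows(lapply(parsed, function(p) {
    tibble::tibble(
      source = "TRUTH", source_id = p$incident_id,
      date = as.Date(p$date), state = p$state, city = p$city,
      shooter_names = list(unlist(p$shooter_names)),
      n_shooters = as.integer(p$n_shooters),
      killed_excl_perp = as.integer(p$killed_excl_perp),
      injured_excl_perp = as.integer(p$injured_excl_perp),
      perp_died = as.logical(p$perp_died), motive = p$motive,
      location_type = p$location_type, low_confidence = FALSE,
      incident_id = p$incident_id
    )
  }))
  links <- dplyr::bind_rows(lapply(parsed, function(p) {
    if (length(p$emitted) == 0) {
      return(NULL)
    }
    tibble::tibble(
      incident_id = p$incident_id,
      source = names(p$emitted),
      source_id = unlist(p$emitted, use.names = FALSE)
    )
  }))
  list(incidents = incidents, links = links)
}

#' Ground-truth overlap summary
#'
#' Computes the exclusive intersection counts directly from the generator's
#' ground-truth links, bypassing linkage entirely — the oracle against which
#' the pipeline's overlap output is checked.
#'
#' @param links Tibble `incident_id`, `source`, `source_id`.
#' @param sources Sources to include.
#' @return An `overlap_summary`.
#' @export
true_overlap <- function(links, sources = ms_sources()) {
  m <- build_membership(
    dplyr::rename(links, cluster_id = "incident_id"),
    sources
  )
  exclusive_intersections(m)
}
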