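#' Candidate pair generation by blocking
#'
#' All-pairs comparison over thousands of records is wasteful and risky;
#' blocking restricts candidate pairs to those that could plausibly be the
#' same incident: the two records come from *different* sources, agree on
#' state (when both states are known), and their dates differ by at most
#' `date_window` days (default 1, absorbing media-vs-report dating
#' disagreements). No pair meeting these conditions is omitted.
#'
#' @param records Harmonized records from all sources.
#' @param date_window Maximum absolute date difference, in days.
#' @return A tibble of candidate pairs (`key_a`, `key_b`, sources and ids),
#'   with `key_a < key_b` lexicographically.
#' @export
block_pairs <- function(records, date_window = 1L) {
  assert_records(records)
  if (nrow(records) < 2) {
    return(tibble::tibble(
      key_a = character(), key_b = character(),
      source_a = character(), id_a = character(),
      source_b = character(), id_b = character()
    ))
  }
  side <- tibble::tibble(
    key = record_key(records),
    source = records$source,
    source_id = records$source_id,
    date = records$date,
    state = records$state
  )
  offsets <- seq(-date_window, date_window)
  right <- tidyr::crossing(offset = offsets, side) %>%
    mutate(join_date = .data$date + .data$offset)
  pairs <- inner_join(
    side,
    right,
    by = c("date" = "join_date"),
    suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) %>%
    filter(
      .data$key_a < .data$key_b,
      .data$source_a != .data$source_b,
      is.na(.data$state_a) | is.na(.data$state_b) |
        .data$state_a == .data$state_b
    ) %>%
    distinct(.data$key_a, .data$key_b, .keep_all = TRUE) %>%
    select(
      "key_a", "key_b",
      "source_a", id_a = "source_id_a",
      "source_b", id_b = "source_id_b"
    ) %>%
    arrange(.data$key_a, .data$key_b)
  pairs
}

#' Default similarity component weights
#'
#' Date and state carry the most weight (they anchor an incident in space
#' and time), city and shooter name less (spelling variation), and the two
#' casualty counts least (sources legitimately disagree on counts). Weights
#' are renormalized over the components present for each pair.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_weights <- function() {
  c(
    date_sim = 0.25, state_sim = 0.20, city_sim = 0.20,
    name_sim = 0.15, killed_sim = 0.10, injured_sim = 0.10
  )
}

# normalized Levenshtein similarity, elementwise, NA when either side missing
norm_str_sim <- function(a, b) {
  a <- tolower(stringr::str_squish(as.character(a)))
  b <- tolower(stringr::str_squish(as.character(b)))
  out <- rep(NA_real_, length(a))
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  if (any(ok)) {
    key <- paste(a[ok], b[ok], sep = "\r")
    first <- !duplicated(key)
    ua <- a[ok][first]
    ub <- b[ok][first]
    d <- mapply(function(x, y) adist(x, y)[1, 1], ua, ub, USE.NAMES = FALSE)
    s <- pmax(1 - d / pmax(nchar(ua), nchar(ub), 1), 0)
    out[ok] <- s[match(key, key[first])]
  }
  out
}

# best cross-pair name similarity between two name lists
best_name_sim <- function(names_a, names_b) {
  mapply(function(na, nb) {
    if (length(na) == 0 || length(nb) == 0) {
      return(NA_real_)
    }
    na <- tolower(na)
    nb <- tolower(nb)
    d <- adist(na, nb)
    denom <- outer(nchar(na), nchar(nb), pmax)
    max(pmax(1 - d / pmax(denom, 1), 0))
  }, names_a, names_b, USE.NAMES = FALSE)
}

#' Score candidate pairs
#'
#' Computes per-field similarities in \[0, 1\] and their weighted mean:
#' * `date_sim`: `max(0, 1 - date_decay * |days apart|)` — exactly 1 only on
#'   the same day;
#' * `state_sim`: exact-match indicator;
#' * `city_sim`, `name_sim`: normalized Levenshtein similarity
#'   (`1 - distance / max length`, floored at 0); for names, the best
#'   cross-pairing of the two shooter-name lists;
#' * `killed_sim`, `injured_sim`: `max(0, 1 - |difference| / max(a, b, 1))`.
#'
#' A component is absent (`NA`) when either record's field is unknown;
#' `total` is the mean over present components with weights renormalized, so
#' missingness is neutral rather than penalized.
#'
#' @param pairs Candidate pairs from [block_pairs()].
#' @param records The harmonized records the pairs refer to.
#' @param weights Named component weights, see [default_weights()].
#' @param date_decay Similarity lost per day of date difference.
#' @return `pairs` with the six component columns and `total` appended.
#' @export
score_pairs <- function(pairs, records, weights = default_weights(),
                        date_decay = 0.2) {
  assert_records(records)
  stopifnot(all(names(default_weights()) %in% names(weights)))
  fields <- tibble::tibble(
    key = record_key(records),
    date = records$date,
    state = records$state,
    city = records$city,
    shooter_names = records$shooter_names,
    killed = records$killed_excl_perp,
    injured = records$injured_excl_perp
  )
  a <- fields[match(pairs$key_a, fields$key), ]
  b <- fields[match(pairs$key_b, fields$key), ]

  count_sim <- function(x, y) {
    s <- 1 - abs(x - y) / pmax(x, y, 1)
    pmax(s, 0)
  }
  comp <- tibble::tibble(
    date_sim = pmax(1 - date_decay * abs(as.numeric(a$date - b$date)), 0),
    state_sim = ifelse(is.na(a$state) | is.na(b$state), NA_real_,
      as.numeric(a$state == b$state)
    ),
    city_sim = norm_str_sim(a$city, b$city),
    name_sim = best_name_sim(a$shooter_names, b$shooter_names),
    killed_sim = count_sim(a$killed, b$killed),
    injured_sim = count_sim(a$injured, b$injured)
  )
  w <- weights[names(comp)]
  cm <- as.matrix(comp)
  wm <- matrix(w, nrow(cm), ncol(cm), byrow = TRUE)
  wm[is.na(cm)] <- 0
  cm[is.na(cm)] <- 0
  denom <- rowSums(wm)
  total <- ifelse(denom > 0, rowSums(cm * wm) / denom, 0)
  dplyr::bind_cols(pairs, comp, tibble::tibble(total = total))
}

#' Classify scored pairs
#'
#' Thresholds the total similarity into `MATCH` (auto-link), `REVIEW`
#' (queued for manual adjudication — the analogue of going through imperfect
#' duplicates individually) and `NONMATCH`. Both interval bounds are closed
#' below: `total >= t_match` is a `MATCH`, `t_review <= total < t_match` a
#' `REVIEW`.
#'
#' @param scores Scored pairs from [score_pairs()].
#' @param t_match,t_review Thresholds, `0 <= t_review <= t_match <= 1`.
#'   Defaults (0.90 / 0.70) auto-link exact and near-exact agreements and
#'   route pairs with a whole disagreeing field to review.
#' @return `scores` with `pair_id` and `label` columns.
#' @export
classify_pairs <- function(scores, t_match = 0.90, t_review = 0.70) {
  stopifnot(t_review >= 0, t_match <= 1, t_review <= t_match)
  scores$pair_id <- paste(scores$source_a, scores$id_a,
    scores$source_b, scores$id_b,
    sep = "|"
  )
  scores$label <- ifelse(scores$total >= t_match, "MATCH",
    ifelse(scores$total >= t_review, "REVIEW", "NONMATCH")
  )
  scores
}

#' Cluster match decisions into discrete incidents
#'
#' Builds incident clusters as the connected components of the graph whose
#' edges are `MATCH` decisions (plus `REVIEW` pairs resolved to `MATCH`);
#' records joined by any chain of matches form one cluster, and unmatched
#' records form singletons — every input record lands in exactly one
#' cluster. Unresolved `REVIEW` pairs default to `NONMATCH` and are returned
#' for inspection.
#'
#' Each cluster gets a canonical merged record: casualty counts are
#' per-field maxima across members (preserving "at least" semantics when
#' sources disagree), categorical fields take the majority value with ties
#' broken by source priority (`ms_sources()` order), and shooter names are
#' unioned. Clusters containing two members from the same source are flagged
#' `needs_review`. Output ordering (by canonical date, state, city, member
#' key) and cluster ids are deterministic.
#'
#' @param records All harmonized records that entered blocking.
#' @param decisions Classified pairs from [classify_pairs()].
#' @param review_resolutions Named character vector `pair_id -> "MATCH"` or
#'   `"NONMATCH"` (from [import_review()]); contradictory resolutions are an
#'   error.
#' @param source_priority Character vector ordering sources for tie-breaks.
#' @return A list: `clusters` (one row per incident: `cluster_id`, canonical
#'   fields, `n_members`, `needs_review`), `members` (`cluster_id`, `source`,
#'   `source_id`), `unresolved_review` (pair ids defaulted to `NONMATCH`).
#' @export
cluster_matches <- function(records, decisions, review_resolutions = NULL,
                            source_priority = ms_sources()) {
  assert_records(records)
  keys <- record_key(records)
  stopifnot(!anyDuplicated(keys))
  if (!is.null(review_resolutions) && length(review_resolutions) > 0) {
    if (is.null(names(review_resolutions))) {
      stop("review_resolutions must be named by pair_id", call. = FALSE)
    }
    bad <- !(review_resolutions %in% c("MATCH", "NONMATCH"))
    if (any(bad)) {
      stop("invalid review resolution for pair ",
        paste(names(review_resolutions)[bad], collapse = ", "),
        call. = FALSE
      )
    }
    dup <- names(review_resolutions)[duplicated(names(review_resolutions))]
    contradictory <- unique(dup[vapply(dup, function(p) {
      length(unique(review_resolutions[names(review_resolutions) == p])) > 1
    }, logical(1))])
    if (length(contradictory) > 0) {
      stop("contradictory resolution for pair ",
        paste(contradictory, collapse = ", "),
        call. = FALSE
      )
    }
  }

  label <- decisions$label
  if (!is.null(review_resolutions)) {
    res <- review_resolutions[match(decisions$pair_id, names(review_resolutions))]
    label <- ifelse(decisions$label == "REVIEW" & !is.na(res), res, label)
  }
  unresolved <- decisions$pair_id[label == "REVIEW"]
  edges <- decisions[label == "MATCH", c("key_a", "key_b"), drop = FALSE]

  g <- igraph::graph_from_data_frame(edges,
    directed = FALSE,
    vertices = data.frame(name = keys)
  )
  membership <- igraph::components(g)$membership[keys]

  members <- tibble::tibble(
    comp = as.integer(membership),
    key = keys,
    source = records$source,
    source_id = records$source_id
  )
  idx <- split(seq_len(nrow(records)), members$comp)
  canon <- lapply(idx, function(i) {
    merge_canonical(records[i, , drop = FALSE], source_priority)
  })
  clusters <- dplyr::bind_rows(canon)
  clusters$comp <- as.integer(names(idx))
  clusters$n_members <- lengths(idx)
  clusters$needs_review <- vapply(
    idx, function(i) anyDuplicated(records$source[i]) > 0, logical(1)
  )
  clusters$min_key <- vapply(
    idx, function(i) min(keys[i]), character(1)
  )
  ord <- order(
    clusters$date, clusters$state, clusters$city, clusters$min_key,
    na.last = TRUE, method = "radix"
  )
  clusters <- clusters[ord, , drop = FALSE]
  clusters$cluster_id <- sprintf("C%06d", seq_len(nrow(clusters)))
  members$cluster_id <- clusters$cluster_id[match(members$comp, clusters$comp)]
  members <- members %>%
    arrange(.data$cluster_id, .data$source, .data$source_id) %>%
    select("cluster_id", "source", "source_id", "key")
  clusters <- clusters %>%
    select(
      "cluster_id", "date", "state", "city", "shooter_names", "n_shooters",
      "killed_excl_perp", "injured_excl_perp", "perp_died", "motive",
      "location_type", "n_members", "needs_review"
    )
  list(
    clusters = tibble::as_tibble(clusters),
    members = members,
    unresolved_review = unresolved
  )
}

# canonical merged record for one cluster
merge_canonical <- function(recs, source_priority) {
  prio <- match(recs$source, source_priority)
  mode_prio <- function(values) {
    keep <- !is.na(values)
    if (!any(keep)) {
      return(values[1][NA])
    }
    v <- values[keep]
    p <- prio[keep]
    tab <- tapply(p, as.character(v), min)
    freq <- table(as.character(v))
    cand <- names(freq)[freq == max(freq)]
    cand <- cand[order(tab[cand], cand)]
    out <- v[match(cand[1], as.character(v))]
    out
  }
  max_or_na <- function(x) {
    if (all(is.na(x))) NA_integer_ else as.integer(max(x, na.rm = TRUE))
  }
  by_prio <- recs[order(prio), , drop = FALSE]
  pd <- by_prio$perp_died[!is.na(by_prio$perp_died)]
  motive <- recs$motive
  motive[motive == "UNKNOWN"] <- NA_character_
  loc <- recs$location_type
  loc[loc == "UNKNOWN"] <- NA_character_
  tibble::tibble(
    date = mode_prio(recs$date),
    state = mode_prio(recs$state),
    city = mode_prio(recs$city),
    shooter_names = list(unique(unlist(recs$shooter_names))),
    n_shooters = mode_prio(recs$n_shooters),
    killed_excl_perp = max_or_na(recs$killed_excl_perp),
    injured_excl_perp = max_or_na(recs$injured_excl_perp),
    perp_died = if (length(pd) > 0) pd[1] else NA,
    motive = {
      m <- mode_prio(motive)
      if (is.na(m)) "UNKNOWN" else m
    },
    location_type = {
      l <- mode_prio(loc)
      if (is.na(l)) "UNKNOWN" else l
    }
  )
}

#' Export and import the manual-review queue
#'
#' `export_review_queue()` writes `REVIEW`-labelled pairs to a CSV with one
#' row per pair (pair id, both record references, component similarities,
#' total, and an empty `resolution` column to be filled with `MATCH` or
#' `NONMATCH`). `import_review()` reads such a file back and returns the
#' non-empty resolutions; a malformed resolution value is an error naming
#' the offending row. The export/import/export cycle is a fixed point.
#'
#' @param decisions Classified pairs from [classify_pairs()].
#' @param path CSV path (for export, `NULL` returns the queue invisibly
#'   without writing).
#' @return `export_review_queue()`: the queue tibble, invisibly.
#'   `import_review()`: named character vector `pair_id -> resolution`.
#' @export
export_review_queue <- function(decisions, path = NULL) {
  queue <- decisions %>%
    filter(.data$label == "REVIEW") %>%
    select(
      "pair_id", "source_a", "id_a", "source_b", "id_b",
      "date_sim", "state_sim", "city_sim", "name_sim",
      "killed_sim", "injured_sim", "total"
    ) %>%
    arrange(desc(.data$total), .data$pair_id)
  if (!("resolution" %in% names(queue))) queue$resolution <- ""
  if (!is.null(path)) readr::write_csv(queue, path, na = "")
  invisible(queue)
}

#' @rdname export_review_queue
#' @export
import_review <- function(path) {
  queue <- readr::read_csv(path,
    col_types = readr::cols(.default = "c"),
    show_col_types = FALSE, progress = FALSE
  )
  if (!all(c("pair_id", "resolution") %in% names(queue))) {
    stop("review file must have pair_id and resolution columns", call. = FALSE)
  }
  res <- stringr::str_squish(ifelse(is.na(queue$resolution), "", queue$resolution))
  bad <- which(!(res %in% c("", "MATCH", "NONMATCH")))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "malformed resolution value %s in row %d (pair %s)",
        dQuote(res[bad[1]]), bad[1], queue$pair_id[bad[1]]
      ),
      call. = FALSE
    )
  }
  keep <- res != ""
  setNames(res[keep], queue$pair_id[keep])
}

#' Pairwise linkage quality against ground truth
#'
#' Compares predicted clusters with ground-truth incident groupings at the
#' record-pair level: a true-positive is an unordered record pair placed in
#' the same cluster that truly belongs to the same incident.
#'
#' @param members Cluster membership (`cluster_id`, `source`, `source_id`)
#'   from [cluster_matches()].
#' @param links Ground-truth links (`incident_id`, `source`, `source_id`)
#'   from [emit_source()] / [write_source_bundle()].
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (conventions: empty denominators give 1).
#' @export
linkage_metrics <- function(members, links) {
  pair_strings <- function(df, group) {
    df$key <- paste(df$source, df$source_id, sep = "/")
    grps <- split(df$key, df[[group]])
    grps <- grps[lengths(grps) > 1]
    if (length(grps) == 0) {
      return(character(0))
    }
    unlist(lapply(grps, function(k) {
      k <- sort(k)
      cmb <- utils::combn(k, 2)
      paste(cmb[1, ], cmb[2, ], sep = " || ")
    }), use.names = FALSE)
  }
  pred <- pair_strings(members, "cluster_id")
  truth <- pair_strings(links, "incident_id")
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  )
}
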