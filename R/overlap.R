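#' Incidents-by-sources membership matrix
#'
#' One row per incident cluster, one logical column per source: cell
#' `(c, s)` is `TRUE` iff cluster `c` has a member record from source `s`.
#' Restricting `sources` to a subset drops clusters with no member in the
#' subset — the basis of the "excluding one database" sensitivity analyses.
#'
#' @param members Cluster membership tibble (`cluster_id`, `source`) from
#'   [cluster_matches()] (or ground-truth links renamed accordingly).
#' @param sources Ordered character vector of sources to include.
#' @return A tibble: `cluster_id` plus one logical column per source; every
#'   row has at least one `TRUE`.
#' @export
build_membership <- function(members, sources = ms_sources()) {
  stopifnot(all(c("cluster_id", "source") %in% names(members)))
  m <- members %>%
    filter(.data$source %in% sources) %>%
    distinct(.data$cluster_id, .data$source) %>%
    mutate(present = TRUE) %>%
    tidyr::pivot_wider(
      names_from = "source", values_from = "present",
      values_fill = FALSE
    )
  for (s in setdiff(sources, names(m))) m[[s]] <- logical(nrow(m))
  m <- m[, c("cluster_id", sources), drop = FALSE]
  m[rowSums(as.matrix(m[, sources, drop = FALSE])) > 0, , drop = FALSE] %>%
    arrange(.data$cluster_id)
}

#' Exclusive intersection counts (UpSet analysis)
#'
#' Counts clusters by their *exact* membership pattern: each cluster counts
#' toward exactly one nonempty source subset — the UpSet convention — so the
#' counts partition the union and always sum to the number of unique
#' incidents.
#'
#' @param membership Membership matrix from [build_membership()].
#' @return An `overlap_summary`: list with `exclusive_counts` (tibble with
#'   one indicator column per source plus `count`), `union_total` (number of
#'   unique incidents), `full_intersection` (count in all sources) and
#'   `sources`.
#' @export
exclusive_intersections <- function(membership) {
  sources <- setdiff(names(membership), "cluster_id")
  if (nrow(membership) == 0) {
    empty <- membership[, sources, drop = FALSE]
    empty$count <- integer(0)
    return(structure(
      list(
        exclusive_counts = empty, union_total = 0L,
        full_intersection = 0L, sources = sources
      ),
      class = "overlap_summary"
    ))
  }
  mat <- as.matrix(membership[, sources, drop = FALSE])
  stopifnot(is.logical(mat), all(rowSums(mat) > 0))
  counts <- membership %>%
    count(across(all_of(sources)), name = "count")
  full <- counts$count[rowSums(as.matrix(counts[, sources, drop = FALSE])) ==
    length(sources)]
  structure(
    list(
      exclusive_counts = sort_upset(counts, sources),
      union_total = nrow(membership),
      full_intersection = if (length(full) == 0) 0L else as.integer(full),
      sources = sources
    ),
    class = "overlap_summary"
  )
}

# UpSet ordering: count descending, ties by subset size then pattern
sort_upset <- function(counts, sources) {
  size <- rowSums(as.matrix(counts[, sources, drop = FALSE]))
  subset_lab <- apply(
    as.matrix(counts[, sources, drop = FALSE]), 1,
    function(r) paste(sources[r], collapse = "+")
  )
  counts[order(-counts$count, size, subset_lab, method = "radix"), ,
    drop = FALSE
  ]
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "<overlap_summary: %d unique incidents across %s; %d in all %d sources>\n",
    x$union_total, paste(x$sources, collapse = "/"),
    x$full_intersection, length(x$sources)
  ))
  top <- head(x$exclusive_counts, 10)
  lab <- apply(
    as.matrix(top[, x$sources, drop = FALSE]), 1,
    function(r) paste(x$sources[r], collapse = "+")
  )
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-32s %6d\n", lab[i], top$count[i]))
  }
  if (nrow(x$exclusive_counts) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-source summary table
#'
#' Counts incidents, total fatalities and total injuries per source
#' (perpetrators excluded throughout). Unknown casualty counts are excluded
#' from the sums and reported as unknown-count tallies.
#'
#' @param records Harmonized records (possibly several sources bound
#'   together).
#' @param sources Sources to report, in order; sources with no records get
#'   zero rows.
#' @return A tibble: `source`, `incidents`, `fatalities`, `injured`,
#'   `unknown_fatalities`, `unknown_injured`.
#' @export
summarize_sources <- function(records, sources = ms_sources()) {
  assert_records(records)
  base <- tibble::tibble(source = sources)
  got <- records %>%
    filter(.data$source %in% sources) %>%
    group_by(.data$source) %>%
    summarise(
      incidents = dplyr::n(),
      fatalities = sum(.data$killed_excl_perp, na.rm = TRUE),
      injured = sum(.data$injured_excl_perp, na.rm = TRUE),
      unknown_fatalities = sum(is.na(.data$killed_excl_perp)),
      unknown_injured = sum(is.na(.data$injured_excl_perp)),
      .groups = "drop"
    )
  out <- left_join(base, got, by = "source")
  out[is.na(out)] <- 0
  out
}

#' Export/import UpSet-format intersection data
#'
#' Writes the exclusive intersection counts as a table consumable by
#' standard UpSet plotting tools: one row per nonempty source subset,
#' 0/1 indicator columns per source, a `count` column, and a `degree`
#' column (subset size); rows sorted by count descending, ties by subset
#' size then subset label. `import_upset_data()` reconstructs an
#' `overlap_summary` from such a file, so export/import round-trips.
#'
#' @param summary An `overlap_summary` from [exclusive_intersections()].
#' @param path CSV path, or `NULL` to return the table only.
#' @return The UpSet table (tibble), invisibly when written.
#' @export
export_upset_data <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "overlap_summary"))
  tab <- summary$exclusive_counts
  out <- tab
  for (s in summary$sources) out[[s]] <- as.integer(out[[s]])
  out$degree <- rowSums(as.matrix(tab[, summary$sources, drop = FALSE]))
  out <- out[, c(summary$sources, "degree", "count"), drop = FALSE]
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname export_upset_data
#' @export
import_upset_data <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sources <- setdiff(names(tab), c("degree", "count"))
  counts <- tab[, c(sources, "count")]
  for (s in sources) counts[[s]] <- as.logical(counts[[s]])
  full <- counts$count[rowSums(as.matrix(counts[, sources])) == length(sources)]
  structure(
    list(
      exclusive_counts = sort_upset(tibble::as_tibble(counts), sources),
      union_total = sum(counts$count),
      full_intersection = if (length(full) == 0) 0L else as.integer(full),
      sources = sources
    ),
    class = "overlap_summary"
  )
}
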