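#' Pipeline configuration
#'
#' Collects everything one reconciliation run needs: the per-source CSV
#' paths and dialects, the study window, linkage parameters, the common
#' fatality threshold for the sensitivity re-analysis, the source subset,
#' and an optional output directory.
#'
#' @param paths Named character vector of CSV paths (names in
#'   `ms_sources()`).
#' @param dialects Optional named list of [source_dialect()]s; bundled
#'   dialects are used for sources not listed.
#' @param start,end Study window (closed interval).
#' @param date_window Blocking window in days.
#' @param weights Similarity weights, see [default_weights()].
#' @param date_decay Per-day date-similarity decay, see [score_pairs()].
#' @param t_match,t_review Classification thresholds.
#' @param fatality_threshold Common threshold for the re-analysis.
#' @param sources Source subset to analyse (default: all in `paths`).
#' @param review_resolutions Optional resolutions from [import_review()].
#' @param out_dir Optional directory for the report CSVs.
#' @param quiet Suppress stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths, dialects = NULL,
                            start = STUDY_START, end = STUDY_END,
                            date_window = 1L, weights = default_weights(),
                            date_decay = 0.2, t_match = 0.90, t_review = 0.70,
                            fatality_threshold = 4L,
                            sources = names(paths),
                            review_resolutions = NULL, out_dir = NULL,
                            quiet = TRUE) {
  stopifnot(!is.null(names(paths)), all(names(paths) %in% ms_sources()))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input files not found: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(
    all(sources %in% names(paths)), t_review <= t_match,
    t_review >= 0, t_match <= 1, fatality_threshold >= 0
  )
  structure(
    list(
      paths = paths, dialects = dialects, start = as.Date(start),
      end = as.Date(end), date_window = as.integer(date_window),
      weights = weights, date_decay = date_decay, t_match = t_match,
      t_review = t_review,
      fatality_threshold = as.integer(fatality_threshold),
      sources = sources, review_resolutions = review_resolutions,
      out_dir = out_dir, quiet = isTRUE(quiet)
    ),
    class = "pipeline_config"
  )
}

#' Run the full reconciliation pipeline
#'
#' load -> harmonize -> (SHR subset) -> window filter -> block -> score ->
#' classify -> cluster -> overlap. The report bundle contains the
#' per-source summary table, the cluster and membership files, the
#' manual-review queue, and three overlap analyses: all configured sources,
#' the sources minus GVA (the injury-threshold outlier), and the subset of
#' incidents meeting the common fatality threshold. Deterministic: the same
#' inputs and configuration give identical reports.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `ms_report`: `per_source_summary`, `clusters`,
#'   `members`, `review_queue`, `decisions`, `overlaps` (list `all`,
#'   `excl_gva`, `fatality_threshold`), `threshold_excluded`,
#'   `parse_errors`, `shr_dropped`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!cfg$quiet) message(sprintf(...))
  log <- list()
  note <- function(stage, source, count) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, source = source, count = as.integer(count)
    )
    say("[%s] %s: %d", stage, source, count)
  }

  records <- list()
  errors <- list()
  shr_dropped <- NULL
  for (s in cfg$sources) {
    dialect <- cfg$dialects[[s]] %||% bundled_dialect(s)
    loaded <- tryCatch(
      load_source(cfg$paths[[s]], dialect),
      error = function(e) {
        stop(sprintf("stage load (%s): %s", s, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
    note("load", s, nrow(loaded$records))
    errs <- loaded$errors
    if (nrow(errs) > 0) errs$source <- s
    errors[[s]] <- errs
    recs <- loaded$records
    if (s == "SHR") {
      sub <- subset_shr(recs, min_fatalities = 4L)
      shr_dropped <- sub$dropped
      recs <- sub$records
      note("shr_subset", s, nrow(recs))
    }
    recs <- filter_window(recs, cfg$start, cfg$end)
    note("window", s, nrow(recs))
    records[[s]] <- recs[, names(empty_records()), drop = FALSE]
  }
  all_records <- dplyr::bind_rows(records)
  note("harmonized", "ALL", nrow(all_records))

  pairs <- block_pairs(all_records, cfg$date_window)
  note("blocked_pairs", "ALL", nrow(pairs))
  scores <- score_pairs(pairs, all_records, cfg$weights, cfg$date_decay)
  decisions <- classify_pairs(scores, cfg$t_match, cfg$t_review)
  note("match_pairs", "ALL", sum(decisions$label == "MATCH"))
  note("review_pairs", "ALL", sum(decisions$label == "REVIEW"))
  clustering <- cluster_matches(
    all_records, decisions,
    cfg$review_resolutions
  )
  note("clusters", "ALL", nrow(clustering$clusters))
  stopifnot(sum(clustering$clusters$n_members) == nrow(all_records))

  per_source <- summarize_sources(all_records, cfg$sources)
  review_queue <- export_review_queue(decisions)

  membership_all <- build_membership(clustering$members, cfg$sources)
  overlap_all <- exclusive_intersections(membership_all)
  overlaps <- list(all = overlap_all)
  if ("GVA" %in% cfg$sources && length(cfg$sources) > 1) {
    m2 <- build_membership(clustering$members, setdiff(cfg$sources, "GVA"))
    overlaps$excl_gva <- exclusive_intersections(m2)
  }
  thr <- apply_fatality_threshold(clustering$clusters, cfg$fatality_threshold)
  kept_ids <- thr$retained$cluster_id
  m3 <- build_membership(
    clustering$members[clustering$members$cluster_id %in% kept_ids, ],
    cfg$sources
  )
  overlaps$fatality_threshold <- exclusive_intersections(m3)
  note("threshold_clusters", "ALL", length(kept_ids))

  report <- structure(
    list(
      per_source_summary = per_source,
      clusters = clustering$clusters,
      members = clustering$members,
      review_queue = review_queue,
      decisions = decisions,
      overlaps = overlaps,
      threshold_excluded = thr$excluded,
      parse_errors = dplyr::bind_rows(errors),
      shr_dropped = shr_dropped,
      log = dplyr::bind_rows(log)
    ),
    class = "ms_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.ms_report <- function(x, ...) {
  cat("<ms_report>\n")
  cat(sprintf(
    "  %d unique incidents; %d in all sources; %d meet the fatality threshold\n",
    x$overlaps$all$union_total, x$overlaps$all$full_intersection,
    x$overlaps$fatality_threshold$union_total
  ))
  cat(sprintf("  %d pairs queued for review\n", nrow(x$review_queue)))
  invisible(x)
}

# flatten and write the report bundle as CSVs
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name), na = "")
  w(report$per_source_summary, "per_source_summary.csv")
  cl <- report$clusters
  cl$shooter_names <- join_names(cl$shooter_names)
  w(cl, "clusters.csv")
  w(report$members[, c("cluster_id", "source", "source_id")], "members.csv")
  w(report$review_queue, "review_queue.csv")
  export_upset_data(report$overlaps$all, file.path(dir, "upset_all.csv"))
  if (!is.null(report$overlaps$excl_gva)) {
    export_upset_data(
      report$overlaps$excl_gva,
      file.path(dir, "upset_excl_gva.csv")
    )
  }
  export_upset_data(
    report$overlaps$fatality_threshold,
    file.path(dir, "upset_fatality_threshold.csv")
  )
  if (nrow(report$parse_errors) > 0) w(report$parse_errors, "parse_errors.csv")
  w(report$log, "stage_log.csv")
  invisible(dir)
}
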