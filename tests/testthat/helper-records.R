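# Builders and independent oracles shared across the test files.

# harmonized-record tibble with sensible defaults; any field overridable
mk_records <- function(...) {
  supplied <- tibble::tibble(...)
  n <- nrow(supplied)
  out <- tibble::tibble(
    source = rep("GVA", n),
    source_id = sprintf("R%03d", seq_len(n)),
    date = rep(as.Date("2015-06-01"), n),
    state = rep("TX", n),
    city = rep("Houston", n),
    shooter_names = replicate(n, "John Doe", simplify = FALSE),
    n_shooters = rep(1L, n),
    killed_excl_perp = rep(4L, n),
    injured_excl_perp = rep(0L, n),
    perp_died = rep(FALSE, n),
    motive = rep("OTHER", n),
    location_type = rep("PUBLIC", n),
    low_confidence = rep(FALSE, n)
  )
  for (nm in names(supplied)) out[[nm]] <- supplied[[nm]]
  out
}

# expand incident-level rows into victim-level SHR rows (one per fatality)
mk_shr_victims <- function(incidents) {
  reps <- incidents$killed_excl_perp
  rows <- incidents[rep(seq_len(nrow(incidents)), reps), , drop = FALSE]
  rows$source <- "SHR"
  rows
}

# O(n^2) blocking oracle: different sources, same state when both known,
# dates within the window
oracle_block <- function(records, date_window = 1L) {
  keys <- paste(records$source, records$source_id, sep = "/")
  out <- character(0)
  n <- nrow(records)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (records$source[i] == records$source[j]) next
      dd <- abs(as.numeric(records$date[i] - records$date[j]))
      if (is.na(dd) || dd > date_window) next
      si <- records$state[i]
      sj <- records$state[j]
      if (!is.na(si) && !is.na(sj) && si != sj) next
      k <- sort(c(keys[i], keys[j]))
      out <- c(out, paste(k[1], k[2]))
    }
  }
  sort(out)
}

# independent union-find used for brute-force all-pairs clustering
uf_cluster <- function(keys, edges_a, edges_b) {
  parent <- stats::setNames(keys, keys)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i])
    rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(keys, find, character(1))
  unname(split(keys, roots))
}

# canonical form of a partition: sorted list of sorted member vectors
partition_signature <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","),
    character(1)
  )))
}

# cluster signature from a members table
members_signature <- function(members) {
  keys <- paste(members$source, members$source_id, sep = "/")
  partition_signature(split(keys, members$cluster_id))
}
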