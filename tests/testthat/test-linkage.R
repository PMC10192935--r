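test_that("blocking keeps exactly the plausible cross-source pairs", {
  recs <- mk_records(
    source = c("GVA", "MJ", "ASR", "EVERYTOWN"),
    source_id = c("g1", "m1", "a1", "e1"),
    date = as.Date(c("2015-06-01", "2015-06-01", "2015-06-01", "2015-06-01")),
    state = c("TX", "TX", "CA", "TX")
  )
  pairs <- block_pairs(recs)
  keys <- paste(pairs$key_a, pairs$key_b)
  # same state same day pair together; the CA record pairs with nobody
  expect_setequal(keys, c(
    "EVERYTOWN/e1 GVA/g1", "EVERYTOWN/e1 MJ/m1", "GVA/g1 MJ/m1"
  ))
  # same source never pairs
  two <- mk_records(source = c("GVA", "GVA"), source_id = c("x", "y"))
  expect_equal(nrow(block_pairs(two)), 0)
})

test_that("blocking equals the exhaustive pair oracle on synthetic records", {
  u <- generate_universe(universe_config(n_incidents = 60, seed = 13))
  bundle_dir <- withr::local_tempdir()
  b <- write_source_bundle(u, default_source_models(), dir = bundle_dir, seed = 3)
  recs <- list()
  for (s in ms_sources()) {
    loaded <- load_source(b$paths[[s]], bundled_dialect(s))$records
    if (s == "SHR") loaded <- subset_shr(loaded)$records
    recs[[s]] <- loaded[, names(msdblink:::empty_records())]
  }
  recs <- dplyr::bind_rows(recs)
  got <- block_pairs(recs)
  expect_equal(sort(paste(got$key_a, got$key_b)), oracle_block(recs))
})

test_that("pair scores follow the stated component formulas", {
  recs <- mk_records(
    source = c("GVA", "MJ", "ASR", "EVERYTOWN"),
    source_id = c("g", "m", "a", "e"),
    date = as.Date(c("2015-06-01", "2015-06-01", "2015-06-02", "2015-06-01")),
    city = c("Houston", "Houston", "Houstin", "Houston"),
    killed_excl_perp = c(4L, 5L, 4L, NA)
  )
  pairs <- block_pairs(recs)
  scores <- score_pairs(pairs, recs)
  pick <- function(a, b) {
    scores[scores$key_a == a & scores$key_b == b, ]
  }
  # identical records -> total 1
  gm <- pick("GVA/g", "MJ/m")
  expect_equal(gm$killed_sim, 1 - 1 / 5) # 4 vs 5 killed
  em <- pick("EVERYTOWN/e", "MJ/m")
  expect_true(is.na(em$killed_sim)) # unknown count -> component absent
  expect_equal(em$total, 1) # weights renormalize over present components
  ag <- pick("ASR/a", "GVA/g")
  expect_equal(ag$date_sim, 0.8) # one day apart
  expect_equal(ag$city_sim, 1 - 1 / 7) # one-character typo
  # perturbed twin (one day + one typo) still exceeds the match threshold
  expect_gte(ag$total, 0.90)
  # exact duplicates score exactly 1
  ident <- pick("EVERYTOWN/e", "GVA/g")
  expect_true(is.na(ident$killed_sim))
  expect_equal(ident$total, 1)
})

test_that("classification is interval membership with closed lower bounds", {
  base <- mk_records(
    source = c("GVA", "MJ"), source_id = c("g", "m")
  )
  scores <- score_pairs(block_pairs(base), base)
  for (tot in c(1, 0.9, 0.85, 0.7, 0.69, 0)) {
    scores$total <- tot
    lab <- classify_pairs(scores, t_match = 0.9, t_review = 0.7)$label
    expect_equal(lab, if (tot >= 0.9) "MATCH" else if (tot >= 0.7) "REVIEW" else "NONMATCH")
  }
  set.seed(8)
  totals <- runif(1000)
  scores1000 <- scores[rep(1, 1000), ]
  scores1000$total <- totals
  labs <- classify_pairs(scores1000, 0.9, 0.7)$label
  expect_equal(labs, ifelse(totals >= 0.9, "MATCH",
    ifelse(totals >= 0.7, "REVIEW", "NONMATCH")
  ))
  expect_error(classify_pairs(scores, 0.5, 0.9))
})

test_that("clustering is the transitive closure and a partition", {
  recs <- mk_records(
    source = c("GVA", "MJ", "ASR", "EVERYTOWN", "SHR"),
    source_id = c("g", "m", "a", "e", "s"),
    date = as.Date("2015-06-01") + c(0, 0, 1, 0, 5)
  )
  pairs <- block_pairs(recs)
  scores <- classify_pairs(score_pairs(pairs, recs))
  # force a chain g-m, m-a MATCH; everything else NONMATCH
  scores$label <- "NONMATCH"
  scores$label[scores$key_a == "GVA/g" & scores$key_b == "MJ/m"] <- "MATCH"
  scores$label[scores$key_a == "ASR/a" & scores$key_b == "MJ/m"] <- "MATCH"
  got <- cluster_matches(recs, scores)
  expect_equal(sum(got$clusters$n_members), nrow(recs))
  sig <- members_signature(got$members)
  expect_true("ASR/a,GVA/g,MJ/m" %in% sig)
  expect_true("SHR/s" %in% sig) # singleton survives as its own cluster
  # no edges at all -> all singletons
  scores$label <- "NONMATCH"
  lonely <- cluster_matches(recs, scores)
  expect_equal(nrow(lonely$clusters), nrow(recs))
})

test_that("canonical records take count maxima and flag same-source merges", {
  recs <- mk_records(
    source = c("GVA", "MJ", "GVA"),
    source_id = c("g1", "m1", "g2"),
    killed_excl_perp = c(4L, 6L, NA),
    injured_excl_perp = c(2L, 0L, 11L),
    city = c("Houston", "Houston", "Austin")
  )
  pairs <- block_pairs(recs)
  scores <- classify_pairs(score_pairs(pairs, recs))
  scores$label <- "MATCH"
  got <- cluster_matches(recs, scores)
  expect_equal(nrow(got$clusters), 1)
  expect_equal(got$clusters$killed_excl_perp, 6L)
  expect_equal(got$clusters$injured_excl_perp, 11L)
  expect_equal(got$clusters$city, "Houston") # majority city wins
  expect_true(got$clusters$needs_review) # two GVA members
})

test_that("review resolutions are honored and contradictions rejected", {
  recs <- mk_records(
    source = c("GVA", "MJ"), source_id = c("g", "m"),
    city = c("Houston", "Dallas")
  )
  scores <- classify_pairs(score_pairs(block_pairs(recs), recs))
  expect_equal(scores$label, "REVIEW")
  asis <- cluster_matches(recs, scores)
  expect_equal(nrow(asis$clusters), 2) # unresolved defaults to NONMATCH
  expect_equal(asis$unresolved_review, scores$pair_id)
  merged <- cluster_matches(
    recs, scores,
    stats::setNames("MATCH", scores$pair_id)
  )
  expect_equal(nrow(merged$clusters), 1)
  expect_error(
    cluster_matches(recs, scores, stats::setNames(
      c("MATCH", "NONMATCH"), rep(scores$pair_id, 2)
    )),
    "contradictory"
  )
  expect_error(
    cluster_matches(recs, scores, stats::setNames("MAYBE", scores$pair_id)),
    "invalid review resolution"
  )
})

test_that("review queue round-trips through CSV", {
  recs <- mk_records(
    source = c("GVA", "MJ", "ASR", "EVERYTOWN", "SHR", "GVA"),
    source_id = c("g", "m", "a", "e", "s", "g2"),
    city = c("Houston", "Dallas", "Huston", "Houston", "Dalas", "Austin")
  )
  decisions <- classify_pairs(score_pairs(block_pairs(recs), recs))
  path <- withr::local_tempfile(fileext = ".csv")
  queue <- export_review_queue(decisions, path)
  expect_true(file.exists(path))
  n_review <- sum(decisions$label == "REVIEW")
  expect_equal(nrow(queue), n_review)
  # unresolved rows import as an empty mapping
  expect_length(import_review(path), 0)
  # resolve everything, re-import, re-export: fixed point
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$resolution <- rep(c("MATCH", "NONMATCH"), length.out = nrow(tab))
  readr::write_csv(tab, path, na = "")
  res <- import_review(path)
  expect_length(res, n_review)
  expect_setequal(names(res), queue$pair_id)
  # malformed values name the row
  tab$resolution[1] <- "DUNNO"
  readr::write_csv(tab, path, na = "")
  expect_error(import_review(path), "malformed resolution value .* row 1")
})

test_that("empty review queue still writes a header-only file", {
  recs <- mk_records(source = c("GVA", "MJ"), source_id = c("g", "m"))
  decisions <- classify_pairs(score_pairs(block_pairs(recs), recs))
  path <- withr::local_tempfile(fileext = ".csv")
  export_review_queue(decisions, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("pair_id", "total", "resolution") %in% names(tab)))
})

test_that("pipeline clustering equals all-pairs brute force on small instances", {
  for (seed in 1:3) {
    u <- generate_universe(universe_config(n_incidents = 70, seed = seed))
    dir <- withr::local_tempdir()
    b <- write_source_bundle(u, default_source_models(), dir = dir, seed = seed + 50)
    recs <- list()
    for (s in ms_sources()) {
      loaded <- load_source(b$paths[[s]], bundled_dialect(s))$records
      if (s == "SHR") loaded <- subset_shr(loaded)$records
      recs[[s]] <- loaded[, names(msdblink:::empty_records())]
    }
    recs <- dplyr::bind_rows(recs)
    expect_lte(nrow(recs), 500)

    got <- cluster_matches(
      recs,
      classify_pairs(score_pairs(block_pairs(recs), recs))
    )

    # brute force: every cross-source pair, no blocking, same scorer and
    # thresholds, clustered by an independent union-find
    keys <- paste(recs$source, recs$source_id, sep = "/")
    all_pairs <- expand.grid(i = seq_len(nrow(recs)), j = seq_len(nrow(recs)))
    all_pairs <- all_pairs[all_pairs$i < all_pairs$j &
      recs$source[all_pairs$i] != recs$source[all_pairs$j], ]
    bp <- tibble::tibble(
      key_a = pmin(keys[all_pairs$i], keys[all_pairs$j]),
      key_b = pmax(keys[all_pairs$i], keys[all_pairs$j]),
      source_a = recs$source[all_pairs$i], id_a = recs$source_id[all_pairs$i],
      source_b = recs$source[all_pairs$j], id_b = recs$source_id[all_pairs$j]
    )
    bs <- classify_pairs(score_pairs(bp, recs))
    match_edges <- bs[bs$label == "MATCH", ]
    bf <- uf_cluster(keys, match_edges$key_a, match_edges$key_b)
    expect_equal(members_signature(got$members), partition_signature(bf))
  }
})

test_that("cluster output is deterministic across reruns", {
  u <- generate_universe(universe_config(n_incidents = 100, seed = 17))
  dir <- withr::local_tempdir()
  b <- write_source_bundle(u, default_source_models(), dir = dir, seed = 9)
  run_once <- function() {
    recs <- list()
    for (s in ms_sources()) {
      loaded <- load_source(b$paths[[s]], bundled_dialect(s))$records
      if (s == "SHR") loaded <- subset_shr(loaded)$records
      recs[[s]] <- loaded[, names(msdblink:::empty_records())]
    }
    recs <- dplyr::bind_rows(recs)
    cluster_matches(recs, classify_pairs(score_pairs(block_pairs(recs), recs)))
  }
  a <- run_once()
  b2 <- run_once()
  expect_identical(a$clusters, b2$clusters)
  expect_identical(a$members, b2$members)
})
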