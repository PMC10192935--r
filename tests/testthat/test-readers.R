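gva_dialect <- bundled_dialect("GVA")

write_gva_csv <- function(rows, path) {
  header <- "incident_id,incident_date,state,city_or_county,n_killed,n_injured,n_shooters,shooter_name,shooter_died,location_type"
  writeLines(c(header, rows), path)
}

test_that("valid rows each yield one record and fields harmonize", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gva_csv(c(
    'G1,06/03/15,Texas,Houston,4,2,1,John Doe,TRUE,PUBLIC',
    'G2,01/01/13,CA,Fresno,0,5,2,"Al Poe; Bo Roe",FALSE,RESIDENCE',
    'G3,12/31/20,Ohio,Dayton,6,0,1,,TRUE,PUBLIC'
  ), path)
  got <- load_source(path, gva_dialect)
  expect_equal(nrow(got$records), 3)
  expect_equal(nrow(got$errors), 0)
  expect_equal(got$records$date, as.Date(c("2015-06-03", "2013-01-01", "2020-12-31")))
  expect_equal(got$records$state, c("TX", "CA", "OH"))
  expect_equal(got$records$killed_excl_perp, c(4L, 0L, 6L))
  expect_equal(got$records$shooter_names[[2]], c("Al Poe", "Bo Roe"))
  expect_equal(got$records$shooter_names[[3]], character(0))
  expect_equal(got$records$perp_died, c(TRUE, FALSE, TRUE))
  # no motive column in this dialect -> unknown, never dropped
  expect_equal(unique(got$records$motive), "UNKNOWN")
})

test_that("impossible dates go to the error report, not the records", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gva_csv(c(
    'G1,02/30/13,Texas,Houston,4,2,1,John Doe,TRUE,PUBLIC',
    'G2,not a date,Texas,Houston,4,2,1,John Doe,TRUE,PUBLIC',
    'G3,06/03/15,Texas,Houston,4,2,1,John Doe,TRUE,PUBLIC'
  ), path)
  got <- load_source(path, gva_dialect)
  expect_equal(nrow(got$records), 1)
  expect_equal(nrow(got$errors), 2)
  expect_equal(got$errors$row, c(1L, 2L))
  expect_equal(got$errors$problem, rep("unparseable date", 2))
  # conservation: records + errors = data rows
  expect_equal(nrow(got$records) + nrow(got$errors), 3)
})

test_that("missing mandatory columns are a dialect error; empty file warns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("incident_id,who_knows", path)
  writeLines(c("incident_id,who_knows", "a,b"), path)
  expect_error(load_source(path, gva_dialect), "dialect error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    "incident_id,incident_date,state,city_or_county,n_killed,n_injured,n_shooters,shooter_name,shooter_died,location_type",
    empty
  )
  expect_warning(got <- load_source(empty, gva_dialect), "empty")
  expect_equal(nrow(got$records), 0)
})

test_that("perpetrator-inclusive counts are adjusted when the fate is known", {
  asr <- bundled_dialect("ASR")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,incident_date,state,city,shooter,num_shooters,killed,wounded,shooter_deceased,circumstance,location",
    "A1,06/03/2015,TX,Houston,John Doe,1,5,2,TRUE,OTHER,PUBLIC",
    "A2,06/04/2015,TX,Houston,Jane Doe,1,5,2,FALSE,OTHER,PUBLIC",
    "A3,06/05/2015,TX,Houston,Jim Doe,1,5,2,,OTHER,PUBLIC"
  ), path)
  got <- load_source(path, asr)$records
  expect_equal(got$killed_excl_perp, c(4L, 5L, 5L))
  expect_equal(got$low_confidence, c(FALSE, FALSE, TRUE))
})

test_that("combined City, State columns split and normalize", {
  mj <- bundled_dialect("MJ")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "case_id,location,date,fatalities,injured,shooter,num_shooters,shooter_died,motive,venue",
    'M1,"Santa Fe, New Mexico","June 17, 2015",3,1,John Doe,1,TRUE,OTHER,PUBLIC'
  ), path)
  got <- load_source(path, mj)$records
  expect_equal(got$city, "Santa Fe")
  expect_equal(got$state, "NM")
  expect_equal(got$date, as.Date("2015-06-17"))
})

test_that("all five dialects round-trip generator output", {
  u <- generate_universe(universe_config(n_incidents = 80, seed = 42))
  dir <- withr::local_tempdir()
  bundle <- write_source_bundle(u, default_source_models(perturb = FALSE),
    dir = dir, seed = 5
  )
  for (s in ms_sources()) {
    loaded <- load_source(bundle$paths[[s]], bundled_dialect(s))
    expect_equal(nrow(loaded$errors), 0)
    recs <- if (s == "SHR") subset_shr(loaded$records)$records else loaded$records
    links <- bundle$links[bundle$links$source == s, ]
    expect_setequal(recs$source_id, links$source_id)
    truth <- u[match(
      links$incident_id[match(recs$source_id, links$source_id)],
      u$incident_id
    ), ]
    expect_equal(recs$date, truth$date)
    expect_equal(recs$state, truth$state)
    expect_equal(recs$city, truth$city)
    expect_equal(recs$killed_excl_perp, truth$killed_excl_perp)
    expect_equal(recs$n_shooters, truth$n_shooters)
    expect_equal(
      lapply(recs$shooter_names, sort),
      lapply(truth$shooter_names, sort)
    )
    if (s != "SHR") {
      expect_equal(recs$injured_excl_perp, truth$injured_excl_perp)
      expect_equal(recs$perp_died, truth$perp_died)
    }
  }
})

test_that("shr subset matches a brute-force predicate oracle and is idempotent", {
  set.seed(99)
  n <- 200
  inc <- mk_records(
    source = rep("SHR", n),
    source_id = sprintf("S%03d", seq_len(n)),
    date = as.Date("2015-01-01") + sample(0:300, n, TRUE),
    n_shooters = sample(1:3, n, TRUE, prob = c(.7, .2, .1)),
    killed_excl_perp = sample(1:8, n, TRUE)
  )
  inc$agency <- paste0("AG-", inc$state)
  inc$incident_num <- sprintf("%05d", seq_len(n))
  inc$weapon <- sample(
    c(msdblink:::DEFAULT_FIREARM_CODES, "Knife or cutting instrument"),
    n, TRUE
  )
  victims <- mk_shr_victims(inc)
  got <- subset_shr(victims)
  firearm <- inc$weapon %in% msdblink:::DEFAULT_FIREARM_CODES
  keep <- inc$n_shooters == 1L & inc$killed_excl_perp >= 4L & firearm
  expect_setequal(
    got$records$source_id,
    paste0(inc$agency, "-", inc$incident_num)[keep]
  )
  expect_equal(got$records$killed_excl_perp,
    inc$killed_excl_perp[match(
      got$records$source_id,
      paste0(inc$agency, "-", inc$incident_num)
    )],
    ignore_attr = TRUE
  )
  # multi-shooter incidents report SHOOTER_COUNT as the reason
  multi <- got$dropped[got$dropped$n_shooters > 1, ]
  expect_true(all(multi$reason == "SHOOTER_COUNT"))
  # everything lands in exactly one of retained / dropped / review
  expect_equal(
    nrow(got$records) + nrow(got$dropped) + nrow(got$review), sum(keep | !keep)
  )
  # order-independence and idempotence on the retained incident level
  shuffled <- victims[sample(nrow(victims)), ]
  again <- subset_shr(shuffled)
  expect_setequal(again$records$source_id, got$records$source_id)
})

test_that("unknown weapon codes route incidents to review", {
  inc <- mk_records(
    source = c("SHR", "SHR"), source_id = c("a", "b"),
    killed_excl_perp = c(5L, 5L)
  )
  inc$agency <- "AG-TX"
  inc$incident_num <- c("00001", "00002")
  inc$weapon <- c("Rifle", "Mystery device")
  got <- subset_shr(mk_shr_victims(inc))
  expect_equal(nrow(got$records), 1)
  expect_equal(nrow(got$review), 1)
  expect_equal(got$review$incident_num, "00002")
})

test_that("window filtering is a closed interval and matches brute force", {
  recs <- mk_records(
    date = as.Date(c("2012-12-31", "2013-01-01", "2020-12-31", "2021-01-01")),
    source_id = sprintf("W%d", 1:4)
  )
  kept <- filter_window(recs)
  expect_setequal(kept$source_id, c("W2", "W3"))

  set.seed(4)
  rand <- mk_records(
    date = as.Date("2010-01-01") + sample(0:4500, 100, TRUE),
    source_id = sprintf("R%03d", 1:100)
  )
  start <- as.Date("2013-01-01")
  end <- as.Date("2020-12-31")
  expect_setequal(
    filter_window(rand, start, end)$source_id,
    rand$source_id[rand$date >= start & rand$date <= end]
  )
})

test_that("state normalization accepts codes and names, keeps strays verbatim", {
  expect_equal(
    normalize_state(c("tx", "Texas", "District of Columbia", "Atlantis")),
    c("TX", "TX", "DC", "Atlantis")
  )
})
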