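test_that("read_survey parses valid rows and rejects bad ones with reasons", {
  records <- make_records(
    rec("Tree Sparrow", count = 5, group = 5),
    rec("Common Magpie", zone = "A", count = 2, group = 2, crossed = TRUE),
    rec("Ruddy Shelduck", zone = "C", count = 30, group = 30, height = 60)
  )
  path <- write_survey_csv(records)
  out <- read_survey(path)
  expect_equal(nrow(out), 3)
  expect_equal(nrow(rejected_rows(out)), 0)
  expect_s3_class(out$date, "Date")
  expect_type(out$crossed_runway, "logical")

  # corrupt rows one at a time: each is dropped individually, rest survive
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  raw$zone[1] <- "D"
  raw$count[2] <- "many"
  raw$date[3] <- "not-a-date"
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, bad)
  out2 <- read_survey(bad)
  expect_equal(nrow(out2), 0)
  rej <- rejected_rows(out2)
  expect_equal(rej$row, 1:3)
  expect_match(rej$reason[1], "unknown zone")
  expect_match(rej$reason[2], "count")
  expect_match(rej$reason[3], "date")
})

test_that("read_survey enforces required columns and allows remapped headers", {
  records <- make_records(rec("X"))
  path <- write_survey_csv(dplyr::rename(records, bird = species))
  expect_error(read_survey(path), "species")
  schema <- survey_schema()
  schema["species"] <- "bird"
  expect_equal(read_survey(path, schema)$species, "X")
})

test_that("header-only survey file yields an empty record set, not an error", {
  path <- write_survey_csv(make_records(rec("X"))[0, ])
  out <- read_survey(path)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(rejected_rows(out)), 0)
})

test_that("group size larger than the sighting count is rejected", {
  path <- write_survey_csv(rec("X", count = 2, group = 5))
  out <- read_survey(path)
  expect_equal(nrow(out), 0)
  expect_match(rejected_rows(out)$reason, "group size exceeds count")
})

test_that("assign_season follows the calendar-quarter default scheme", {
  expect_equal(assign_season(as.Date("2019-04-15")), "spring")
  expect_equal(assign_season(as.Date("2019-12-01")), "winter")
  expect_equal(assign_season(as.Date("2019-08-31")), "summer")
  expect_equal(assign_season(as.Date(c("2019-02-28", "2019-09-01"))),
               c("winter", "autumn"))
  # a custom scheme is honoured
  southern <- rep(c("summer", "autumn", "winter", "spring"), each = 3)
  expect_equal(assign_season(as.Date("2019-01-15"), southern), "summer")
})

test_that("aggregate_profiles computes totals, extremes and season sets", {
  records <- make_records(
    rec("X", count = 5, group = 2, zone = "B", height = 10, date = "2019-04-01"),
    rec("X", count = 10, group = 7, zone = "C", height = 80, date = "2019-07-01"),
    rec("X", count = 40, group = 40, zone = "C", height = 10,
        date = "2019-07-15", crossed = TRUE),
    rec("Y", count = 1, group = 1, zone = "A", height = 3, date = "2019-12-01")
  )
  traits <- make_traits(c("X", "Y"), mass_g = c(20, 500))
  prof <- aggregate_profiles(records, traits)
  x <- prof[prof$species == "X", ]
  expect_equal(x$total_count, 55)
  expect_equal(x$total_biomass_g, 55 * 20)
  expect_equal(x$max_cluster, 40L)
  expect_equal(x$nearest_zone, "B")
  expect_equal(x$runway_crossings, 1L)
  expect_setequal(x$seasons[[1]], c("spring", "summer"))
  # count-weighted median height: weights 5@10, 10@80, 40@10 -> 10
  expect_equal(x$height_m, 10)
  y <- prof[prof$species == "Y", ]
  expect_equal(y$nearest_zone, "A")
  expect_equal(y$seasons[[1]], "winter")
})

test_that("species missing from the trait table is a hard error naming it", {
  records <- make_records(rec("X"), rec("Mystery Bird"))
  expect_error(aggregate_profiles(records, make_traits("X")), "Mystery Bird")
})

test_that("aggregation is permutation-invariant and conserves individuals", {
  set.seed(42)
  records <- make_records(
    rec(sample(c("A sp.", "B sp.", "C sp."), 30, replace = TRUE),
        zone = sample(c("A", "B", "C"), 30, replace = TRUE),
        count = sample(1:50, 30, replace = TRUE), group = 1L,
        date = sprintf("2019-%02d-10", sample(1:12, 30, replace = TRUE)))
  )
  traits <- make_traits(c("A sp.", "B sp.", "C sp."))
  prof1 <- aggregate_profiles(records, traits)
  prof2 <- aggregate_profiles(records[sample(nrow(records)), ], traits)
  expect_equal(prof1, prof2)
  expect_equal(sum(prof1$total_count), sum(records$count))
  # adding a zone-A record pulls the nearest zone to A for that species
  prof3 <- aggregate_profiles(
    dplyr::bind_rows(records, rec("C sp.", zone = "A")), traits)
  expect_equal(prof3$nearest_zone[prof3$species == "C sp."], "A")
})

test_that("mean height and cluster quantile aggregation are configurable", {
  records <- make_records(
    rec("X", count = 1, group = 2, height = 10),
    rec("X", count = 3, group = 40, height = 50),
    rec("X", count = 1, group = 7, height = 10)
  )
  traits <- make_traits("X")
  cfg_mean <- risk_config(height_stat = "mean")
  prof <- aggregate_profiles(records, traits, cfg_mean)
  expect_equal(prof$height_m, (10 + 3 * 50 + 10) / 5)
  cfg_q <- risk_config(cluster_stat = 0.5)
  prof_q <- aggregate_profiles(records, traits, cfg_q)
  expect_equal(prof_q$max_cluster, 7L)  # type-1 median of {2, 7, 40}
})
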