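test_that("read_records parses, sorts, validates and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,species,timestamp",
               "s2,leopard,2015-06-03 10:00:00",
               "s1,leopard,2015-06-04T08:30:00",
               "s1,leopard,2015-06-02 07:00:00"), f)
  r <- read_records(f)
  expect_s3_class(r, "detection_records")
  expect_equal(nrow(r), 3)
  expect_equal(r$station_id, c("s1", "s1", "s2"))
  expect_true(!is.unsorted(r$timestamp[r$station_id == "s1"]))

  # empty file with header
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("station_id,species,timestamp", f2)
  expect_equal(nrow(read_records(f2)), 0)

  # unparseable timestamp aborts with the row number, or drops permissively
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,species,timestamp",
               "s1,leopard,2015-06-02 07:00:00",
               "s1,leopard,not-a-date"), f3)
  expect_error(read_records(f3), "row")
  expect_warning(r3 <- read_records(f3, permissive = TRUE), "dropping")
  expect_equal(nrow(r3), 1)

  # schema errors
  expect_error(read_records(f, schema = c(station_id = "cam", species = "sp",
                                          timestamp = "ts")), "missing")
  expect_error(read_records(f, species_list = c("lion")), "species")
})

test_that("independence filter follows the chained strict >5 min rule", {
  base <- "2015-06-02 "
  one <- make_records("s1", "leopard", paste0(base, "10:00:00"))
  expect_equal(nrow(filter_independent(one)), 1)

  # 0, 3, 7 minutes: 3 dropped (gap 3 <= 5 from t=0), 7 kept (gap 7 > 5)
  r <- make_records(rep("s1", 3), rep("leopard", 3),
                    paste0(base, c("10:00:00", "10:03:00", "10:07:00")))
  kept <- filter_independent(r, 5)
  expect_equal(format(kept$timestamp, "%H:%M"), c("10:00", "10:07"))

  # exactly 5 minutes is NOT independent (strict inequality)
  r5 <- make_records(rep("s1", 2), rep("leopard", 2),
                     paste0(base, c("10:00:00", "10:05:00")))
  expect_equal(nrow(filter_independent(r5, 5)), 1)
  # one second past the window is independent
  r5b <- make_records(rep("s1", 2), rep("leopard", 2),
                      paste0(base, c("10:00:00", "10:05:01")))
  expect_equal(nrow(filter_independent(r5b, 5)), 2)

  # groups are independent across station and species
  rg <- make_records(c("s1", "s2", "s1"), c("leopard", "leopard", "impala"),
                     rep(paste0(base, "10:00:00"), 3))
  expect_equal(nrow(filter_independent(rg)), 3)

  expect_error(filter_independent(one, -1), "non-negative")
})

test_that("independence filter is idempotent and monotone in the window", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    r <- make_records(sample(c("s1", "s2"), n, TRUE),
                      sample(c("leopard", "impala"), n, TRUE),
                      "2015-06-02 00:00:00")
    r$timestamp <- r$timestamp + sort(sample.int(3600, n))
    f1 <- filter_independent(r, 5)
    expect_identical(filter_independent(f1, 5)$timestamp, f1$timestamp)
    # larger window never retains more
    kept <- vapply(c(0, 2, 5, 10, 30), function(w)
      nrow(filter_independent(r, w)), numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("effort counts active days per occasion", {
  st <- tiny_stations()
  eff <- compute_effort(st, as.Date("2015-06-01"), n_occasions = 6)
  # windows span exactly occasions 1-4
  expect_equal(unname(eff["s1", ]), c(7, 7, 7, 7, 0, 0))
  expect_equal(sum(eff["s1", ]), 28)

  # window covering only 3 days of occasion 1
  w <- data.frame(station_id = "s1", start = as.Date("2015-06-03"),
                  end = as.Date("2015-06-06"))
  eff3 <- compute_effort(st[1, ], as.Date("2015-06-01"), n_occasions = 2,
                         windows = w)
  expect_equal(unname(eff3[1, ]), c(3, 0))

  # two disjoint windows within one occasion totalling 6 days;
  # oracle: enumerate the days one by one
  w2 <- data.frame(station_id = "s1",
                   start = as.Date(c("2015-06-01", "2015-06-04")),
                   end = as.Date(c("2015-06-03", "2015-06-08")))
  eff6 <- compute_effort(st[1, ], as.Date("2015-06-01"), n_occasions = 2,
                         windows = w2)
  days <- seq(as.Date("2015-06-01"), as.Date("2015-06-14"), by = 1)
  active <- vapply(days, function(d) {
    any(w2$start <= d & d < w2$end)
  }, logical(1))
  occ <- rep(1:2, each = 7)
  expect_equal(unname(eff6[1, ]), as.vector(tapply(active, occ, sum)))
  expect_equal(unname(eff6[1, 1]), 6)

  # station with no window: zero row and a warning
  st2 <- tiny_stations()
  w3 <- data.frame(station_id = c("s1", "s2"),
                   start = as.Date("2015-06-01"), end = as.Date("2015-06-08"))
  expect_warning(effz <- compute_effort(st2, as.Date("2015-06-01"),
                                        n_occasions = 2, windows = w3),
                 "zero effort")
  expect_equal(unname(effz["s3", ]), c(0, 0))
})

test_that("station table validation catches malformed input", {
  df <- as.data.frame(tiny_stations())
  bad <- df; bad$trail_type[1] <- "XX"
  expect_error(as_station_table(bad), "trail_type")
  bad2 <- df; bad2$zone[3] <- "national_park"; bad2$area[3] <- "A"
  bad2$zone[1] <- "wma"   # area A now maps to two zones
  expect_error(as_station_table(bad2), "exactly one zone")
  bad3 <- df; bad3$active_end[1] <- bad3$active_start[1]
  expect_error(as_station_table(bad3), "start < end")
})

test_that("detection history bins, binarizes and flags inconsistencies", {
  st <- tiny_stations()
  start <- as.Date("2015-06-01")

  # no records: all zero on effort cells, NA beyond the windows
  h0 <- build_detection_history(make_records(character(0), character(0),
                                             character(0)),
                                st, start, n_occasions = 6)
  expect_true(all(h0$y[, 1:4] == 0))
  expect_true(all(is.na(h0$y[, 5:6])))

  # three records in one (site, occasion) cell collapse to a single 1
  r <- make_records(rep("s1", 3), rep("leopard", 3),
                    c("2015-06-02 08:00:00", "2015-06-03 09:00:00",
                      "2015-06-04 10:00:00"))
  h <- build_detection_history(r, st, start, n_occasions = 6)
  expect_equal(unname(h$y["s1", 1]), 1L)
  expect_equal(sum(h$y == 1, na.rm = TRUE), 1)
  expect_equal(unname(h$n_events["s1"]), 3L)

  # record at an unknown station
  rbad <- make_records("s9", "leopard", "2015-06-02 08:00:00")
  expect_error(build_detection_history(rbad, st, start, n_occasions = 6),
               "s9")

  # record inside a zero-effort occasion is inconsistent input
  rlate <- make_records("s1", "leopard", "2015-07-10 08:00:00")
  expect_error(build_detection_history(rlate, st, start, n_occasions = 6),
               "zero effort")
})

test_that("zone tabulation matches hand counts and conserves totals", {
  st <- tiny_stations()
  start <- as.Date("2015-06-01")
  r <- make_records(c("s1", "s1", "s2"), rep("leopard", 3),
                    c("2015-06-02 08:00:00", "2015-06-10 08:00:00",
                      "2015-06-02 09:00:00"))
  h <- build_detection_history(r, st, start, n_occasions = 4)
  tab <- tabulate_by_zone(h, r, st)
  np <- tab[tab$zone == "national_park", ]
  wma <- tab[tab$zone == "wma", ]
  expect_equal(np$n_stations, 2)
  expect_equal(np$n_detected, 2)
  expect_equal(np$n_events, 3)
  expect_equal(wma$n_detected, 0)       # zero events, station still tallied
  expect_equal(wma$n_stations, 1)
  # conservation
  expect_equal(sum(tab$n_stations), nrow(st))
  expect_equal(sum(tab$effort_days), sum(h$effort))
  # binarization: 1-cells never exceed independent events
  expect_lte(sum(h$y == 1, na.rm = TRUE), nrow(r))
})
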