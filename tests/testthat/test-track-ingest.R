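mkFixes <- function(ts, x = 0, y = 0, speed = 0, id = "A", pop = "pop1",
                    season = NULL) {
  df <- data.frame(individual_id = id, population = pop,
                   timestamp = as.POSIXct(ts, tz = "UTC"),
                   x = x, y = y, speed_ms = speed)
  if (!is.null(season)) df$season <- season
  df
}

test_that("the null-velocity filter removes moving fixes", {
  fx <- mkFixes(c("2018-05-02 10:00:00", "2018-05-02 11:00:00"),
                speed = c(0, 8))
  out <- filterFixes(fx)
  expect_equal(nrow(out), 1)
  expect_equal(out$speed_ms, 0)
  expect_equal(attr(out, "exclusions")$reason, "nonzero_speed")
})

test_that("daylight windows use local clock hours per season", {
  # breeding window is 06-17 local; with UTC+1 a 04:30 UTC fix is 05:30
  # local (removed) and 05:00 UTC is 06:00 local (retained)
  fx <- mkFixes(c("2018-05-02 04:30:00", "2018-05-02 05:00:00",
                  "2018-08-02 18:30:00", "2018-08-02 20:00:00"),
                season = c("breeding", "breeding",
                           "post_breeding", "post_breeding"))
  out <- filterFixes(fx, tzOffset = 1)
  lh <- localHour(out$timestamp, 1)
  # 05:30 local (breeding) and 21:00 local (post-breeding) removed
  expect_equal(nrow(out), 2)
  expect_true(all(lh[out$season == "breeding"] >= 6))
  expect_true(any(lh[out$season == "post_breeding"] == 19))
  expect_false(any(lh == 21))
  expect_setequal(attr(out, "log")[c("outside_daylight")], 2)
})

test_that("filtering is idempotent, conserves records, and handles empties", {
  cfg <- testWorldConfig(seed = 44, individualsPerPopulation = 2)
  w <- simulateWorld(cfg)
  f1 <- filterFixes(w$fixes)
  expect_equal(nrow(f1) + nrow(attr(f1, "exclusions")), nrow(w$fixes))
  f2 <- filterFixes(f1)
  expect_equal(f2[, names(w$fixes)], f1[, names(w$fixes)])
  expect_equal(nrow(attr(f2, "exclusions")), 0)
  e <- filterFixes(w$fixes[0, ])
  expect_equal(nrow(e), 0)
})

test_that("missing speed column falls back to step speeds with a warning", {
  fx <- mkFixes(sprintf("2018-05-02 %02d:00:00", 8:11),
                x = c(0, 0, 5000, 5000), y = 0)
  fx$speed_ms <- NULL
  expect_warning(out <- filterFixes(fx), "speed")
  # the 0 -> 5000 m jump in one hour implies ~1.4 m/s > 0: removed
  expect_equal(nrow(out), 3)
})

## A hand-built individual for the departure rule: May at the origin,
## then optionally away. dayFixes() plants 6 daylight ground fixes/day.
dayFixes <- function(dates, x, y, id = "A") {
  do.call(rbind, lapply(seq_along(dates), function(i)
    mkFixes(paste(dates[i], sprintf("%02d:00:00", c(7, 9, 10, 12, 14, 16))),
            x = x[i] + c(-40, 25, 0, 10, -15, 30),
            y = y[i] + c(10, -35, 20, 0, 25, -10), id = id)))
}

test_that("a clean departure is dated to the first away day", {
  d1 <- seq(as.Date("2018-05-01"), as.Date("2018-06-19"), by = 1)
  d2 <- seq(as.Date("2018-06-20"), as.Date("2018-08-31"), by = 1)
  fx <- rbind(dayFixes(d1, rep(0, length(d1)), rep(0, length(d1))),
              dayFixes(d2, rep(20000, length(d2)), rep(0, length(d2))))
  res <- detectDeparture(fx)
  expect_equal(res$assignment$status, "migrant")
  expect_equal(res$assignment$departure_date, as.Date("2018-06-20"))
  expect_equal(res$assignment$post_end, as.Date("2018-09-15"))
})

test_that("an individual that never leaves is resident with the fixed window", {
  d <- seq(as.Date("2018-05-01"), as.Date("2018-09-10"), by = 1)
  fx <- dayFixes(d, rep(0, length(d)), rep(0, length(d)))
  res <- detectDeparture(fx)
  expect_equal(res$assignment$status, "resident")
  expect_equal(res$assignment$post_start, as.Date("2018-07-15"))
  expect_equal(res$assignment$post_end, as.Date("2018-09-15"))
})

test_that("a 20-day excursion with return does not count as departure", {
  d1 <- seq(as.Date("2018-05-01"), as.Date("2018-06-09"), by = 1)
  dAway <- seq(as.Date("2018-06-10"), as.Date("2018-06-29"), by = 1)  # 20 days
  dBack <- seq(as.Date("2018-06-30"), as.Date("2018-09-10"), by = 1)
  fx <- rbind(dayFixes(d1, rep(0, length(d1)), rep(0, length(d1))),
              dayFixes(dAway, rep(20000, length(dAway)), rep(0, length(dAway))),
              dayFixes(dBack, rep(0, length(dBack)), rep(0, length(dBack))))
  res <- detectDeparture(fx)
  # brute-force oracle: longest away run is 20 < 30 days
  expect_equal(res$assignment$status, "resident")

  # the same away run without return, but tracking ending early, is
  # indeterminate rather than a departure
  fx2 <- rbind(dayFixes(d1, rep(0, length(d1)), rep(0, length(d1))),
               dayFixes(dAway, rep(20000, length(dAway)), rep(0, length(dAway))))
  res2 <- detectDeparture(fx2)
  expect_equal(res2$assignment$status, "indeterminate")
})

test_that("inclusion rules enforce capture date, 7-day rule and last year", {
  a <- data.frame(
    individual_id = c("A", "B", "C", "C", "D"),
    year = c(2018, 2018, 2017, 2018, 2018),
    status = c("migrant", "migrant", "migrant", "migrant", "migrant"),
    departure_date = as.Date(c("2018-05-10", "2018-05-03",
                               "2017-06-10", "2018-06-10", "2018-06-10")),
    post_start = as.Date("2018-06-10"), post_end = as.Date("2018-09-15"),
    capture_date = as.Date(c("2018-04-20", "2018-04-28",
                             "2017-04-15", "2018-04-15", "2018-05-02")))
  out <- applyInclusionRules(a)
  expect_true(out$included[out$individual_id == "A"])          # 20 days
  expect_false(out$included[out$individual_id == "B"])         # 5 days
  expect_equal(out$exclusion_reason[out$individual_id == "B"],
               "lt7days_predeparture")
  expect_equal(out$included[out$individual_id == "C"], c(FALSE, TRUE))
  expect_equal(out$exclusion_reason[out$individual_id == "C" &
                                    out$year == 2017], "not_last_year")
  expect_false(out$included[out$individual_id == "D"])         # captured May 2
  expect_equal(out$exclusion_reason[out$individual_id == "D"],
               "captured_after_may1")
})

test_that("season labels partition retained fixes", {
  cfg <- testWorldConfig(seed = 55)
  w <- simulateWorld(cfg)
  sp <- filterFixes(w$fixes)
  sa <- seasonAssignments(sp)
  a <- applyInclusionRules(sa$assignments)
  lab <- assignSeasons(sp, a)
  expect_equal(nrow(lab), nrow(sp))
  expect_true(all(lab$season %in% c("breeding", "post_breeding", "excluded")))
  # per-fix dates respect the windows
  d <- as.Date(lab$timestamp, tz = "UTC")
  inc <- a[a$included, ]
  for (i in seq_len(nrow(inc))) {
    li <- lab[lab$individual_id == inc$individual_id[i], ]
    di <- as.Date(li$timestamp, tz = "UTC")
    b <- li$season == "breeding"
    expect_true(all(di[b] >= as.Date("2018-05-01")))
    if (inc$status[i] == "migrant")
      expect_true(all(di[b] < inc$departure_date[i]))
  }
})
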