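test_that("daylength follows standard solar geometry", {
  expect_equal(daylength(0, 100), 12, tolerance = 0.2)
  expect_equal(daylength(43.91, 80), 12, tolerance = 0.3)
  expect_gt(daylength(51.8, 172), daylength(51.8, 355))
  expect_error(daylength(70, 100), "polar")
})

test_that("generated series are complete calendars obeying the invariants", {
  cfg <- site_preset("CF", seed = 11)
  w <- generate_weather(cfg, 1, 1971)
  expect_equal(nrow(w), 365L)
  w <- generate_weather(cfg, 1, 1972)  # leap year
  expect_equal(nrow(w), 366L)
  w4 <- generate_weather(cfg, 4, 1970)
  expect_true(all(diff(w4$date) == 1))
  expect_true(all(w4$tmax >= w4$tmin))
  expect_true(all(w4$srad >= 0), all(w4$rain >= 0))
  expect_false(any(!is.finite(as.matrix(w4[-1]))))
})

test_that("generation is deterministic and year k is invariant to length", {
  cfg <- site_preset("AV", seed = 5)
  a <- generate_weather(cfg, 3, 1970)
  b <- generate_weather(cfg, 3, 1970)
  expect_identical(a, b)
  long <- generate_weather(cfg, 6, 1970)
  expect_equal(long[seq_len(nrow(a)), ], a, ignore_attr = TRUE)
})

test_that("site presets reproduce the intended climate contrasts", {
  av <- site_preset("AV")
  rr <- site_preset("RR")
  # Mediterranean: summer (JJA) drier than winter (DJF)
  wet_frac <- function(cfg, s)
    cfg$p_wet_dry[s] / (1 - cfg$p_wet_wet[s] + cfg$p_wet_dry[s])
  expect_lt(wet_frac(av, 3) * av$rain_mean[3],
            wet_frac(av, 1) * av$rain_mean[1])
  # realized: RR wetter than AV pre-anthesis (Nov-May totals)
  wav <- site_weather("AV", 11, seed = 2)
  wrr <- site_weather("RR", 11, seed = 2)
  pre <- function(w) {
    m <- as.integer(format(w$date, "%m"))
    sum(w$rain[m %in% c(11, 12, 1:5)])
  }
  expect_gt(pre(wrr), pre(wav))
  expect_error(site_preset("XX"), "unknown")
})

test_that("long-run occurrence and seasonal statistics match the config", {
  cfg <- site_preset("CF", seed = 1)
  w <- generate_weather(cfg, 40, 1970)
  mon <- as.integer(format(w$date, "%m"))
  sea <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[mon]
  wet <- w$rain > 0
  # realized p(wet|wet) within 0.05 of configured, per season
  for (s in 1:4) {
    i <- which(sea[-1] == s) + 1L
    i <- i[wet[i - 1]]
    expect_lt(abs(mean(wet[i]) - cfg$p_wet_wet[s]), 0.055)
  }
  # seasonal mean temperature within 10% tolerance band of the sinusoid
  doy <- as.integer(format(w$date, "%j"))
  tmean <- (w$tmin + w$tmax) / 2
  base <- cfg$tmean_annual + cfg$tamp * cos(2 * pi * (doy - 201) / 365.25)
  for (s in 1:4)
    expect_lt(abs(mean(tmean[sea == s]) - mean(base[sea == s])), 0.6)
  # seasonal wet-day amounts within 10% of the configured gamma means
  for (s in 1:4) {
    amt <- w$rain[sea == s & wet]
    expect_lt(abs(mean(amt) - cfg$rain_mean[s]), 0.10 * cfg$rain_mean[s])
  }
})

test_that("AV pre-anthesis mean temperature calibrates near 9 degC", {
  # run the crop with nominal parameters over 20 synthetic AV years and
  # average daily mean temperature between emergence and anthesis
  w <- generate_weather(site_preset("AV", seed = 1), 21, 1970)
  tm <- (w$tmin + w$tmax) / 2
  means <- c()
  for (s in 1:20) {
    res <- run_scenario_season(nominal, w, "AV", "HN", s)
    if (!res$completed) next
    sow <- as.Date(sprintf("%d-11-15", 1969 + s))
    i0 <- match(sow, w$date)
    em <- i0 + res$phen$day_emergence - 1L
    an <- i0 + res$anthesis_day - 1L
    means <- c(means, mean(tm[em:an]))
  }
  expect_gt(length(means), 15)
  expect_equal(mean(means), 9.0, tolerance = 1.0)
})

test_that("weather CSV round-trips and malformed files are rejected by line", {
  w <- generate_weather(site_preset("RR", seed = 3), 1, 1980)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weather(w, f)
  back <- read_weather(f, site = "RR", latitude = 51.8)
  expect_equal(back$tmin, w$tmin, tolerance = 1e-6)
  expect_equal(back$srad, w$srad, tolerance = 1e-6)
  expect_equal(back$date, w$date)

  txt <- readLines(f)
  parts <- strsplit(txt[7], ",")[[1]]
  parts[2:3] <- c("10", "5")   # tmax < tmin on line 7
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(txt[1:6], paste(parts, collapse = ","), txt[8:length(txt)]),
             bad)
  expect_error(read_weather(bad), "line\\(s\\) 7")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("date,tmin,tmax,srad,rain", empty)
  expect_error(read_weather(empty), "no records")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin,tmax", "1970-01-01,1,2"), miss)
  expect_error(read_weather(miss), "missing column")
})
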