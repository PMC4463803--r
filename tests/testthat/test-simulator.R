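test_that("management plans encode the two N treatments", {
  hn <- management_plan("HN")
  expect_equal(sum(hn$events$n), 20)
  expect_equal(nrow(hn$events), 4L)
  ln <- management_plan("LN")
  expect_equal(sum(ln$events$n), 4)
  expect_equal(ln$events$stage, "GS30")
})

test_that("stage triggers map onto the phenology trace", {
  w <- site_weather("CF", 3, seed = 13)
  res <- run_season(nominal, w, site_soil("CF"), management_plan("HN"),
                    "1970-11-01", trace = TRUE, engine = "r")
  trig <- resolve_stage_triggers(res$trace, nominal)
  expect_equal(unname(trig["GS65"]), res$anthesis_day)
  expect_true(all(is.finite(trig)))
  expect_true(all(diff(trig[c("GS21", "GS30", "GS37", "GS65")]) >= 0))
})

test_that("no light means no biomass and no yield", {
  w <- constant_weather(tmean = 12, days = 420, srad = 0, rain = 2)
  res <- run_season(nominal, w, soil_profile(awc = 150),
                    management_plan("HN"), "1970-10-01", engine = "r")
  expect_lt(res$crop_dm_maturity, 15)  # only the seed reserve
  expect_lt(res$grain_dm_maturity, 5)
})

test_that("runs are deterministic and the two engines agree", {
  w <- site_weather("AV", 3, seed = 14)
  a <- run_season(nominal, w, site_soil("AV"), management_plan("HN"),
                  "1970-11-15")
  b <- run_season(nominal, w, site_soil("AV"), management_plan("HN"),
                  "1970-11-15")
  expect_identical(a[names(a) != "phen"], b[names(b) != "phen"])

  set.seed(2024)
  flds <- c("anthesis_day", "gai_anthesis", "crop_dm_maturity",
            "crop_n_maturity", "grain_dm_maturity", "grain_n_maturity",
            "post_anthesis_n_uptake", "gpc", "grain_number")
  for (site in c("AV", "RR")) {
    w <- site_weather(site, 3, seed = 15)
    for (i in 1:8) {
      p <- rescale_unit_vector(nominal, random_unit_vector(names(nominal)))
      ntr <- if (i %% 2) "HN" else "LN"
      r1 <- run_scenario_season(p, w, site, ntr, 1, engine = "r")
      r2 <- run_scenario_season(p, w, site, ntr, 1, engine = "cpp")
      expect_equal(r1$completed, r2$completed)
      if (r1$completed)
        for (f in flds)
          expect_equal(r1[[f]], r2[[f]], tolerance = 1e-9,
                       info = paste(site, ntr, i, f))
    }
  }
})

test_that("the first simulated days match a hand-stepped loop", {
  # step the exported module functions by hand over the pre-emergence and
  # early post-emergence window and compare with the full simulator trace
  w <- constant_weather(tmean = 16, days = 420, srad = 12, rain = 0)
  prof <- soil_profile(awc = 120)
  res <- run_season(nominal, w, prof, management_plan("LN"), "1970-10-01",
                    trace = TRUE, engine = "r")
  phen <- phenology_init()
  lat <- attr(w, "latitude")
  for (d in 1:12) {
    doy <- as.integer(format(w$date[d], "%j"))
    phen <- phenology_step(phen, 16, 16, daylength(lat, doy), d, nominal)
    expect_equal(phen$tt_cum, res$trace$tt_cum[d], info = paste("day", d))
    expect_equal(min(phen$clock, Inf), res$trace$clock[d])
  }
  expect_equal(phen$day_emergence, 10)  # 150 / 16 rounds up to day 10
})

test_that("yield responds to N supply and site climate in the right direction", {
  p <- nominal
  for (site in c("AV", "CF", "RR")) {
    w <- site_weather(site, 4, seed = 16)
    gy <- function(ntr) stats::median(vapply(1:3, function(s)
      run_scenario_season(p, w, site, ntr, s)$grain_dm_maturity,
      numeric(1)))
    expect_gt(gy("HN"), gy("LN"))
  }
  wav <- site_weather("AV", 4, seed = 16)
  wrr <- site_weather("RR", 4, seed = 16)
  gy_site <- function(w, site) stats::median(vapply(1:3, function(s)
    run_scenario_season(p, w, site, "HN", s)$grain_dm_maturity,
    numeric(1)))
  expect_gt(gy_site(wrr, "RR"), gy_site(wav, "AV"))
})

test_that("output invariants hold over random parameter draws", {
  set.seed(31)
  w <- site_weather("CF", 4, seed = 17)
  n_checked <- 0
  for (i in 1:60) {
    p <- rescale_unit_vector(nominal, random_unit_vector(names(nominal)))
    res <- run_scenario_season(p, w, "CF", if (i %% 2) "HN" else "LN",
                               1 + i %% 3)
    if (!res$completed) next
    n_checked <- n_checked + 1
    expect_lte(res$grain_dm_maturity, res$crop_dm_maturity + 1e-9)
    expect_lte(res$grain_n_maturity, res$crop_n_maturity + 1e-9)
    expect_gte(res$gai_anthesis, 0)
    expect_gt(res$gpc, 0)
    expect_gte(res$post_anthesis_n_uptake, 0)
  }
  expect_gt(n_checked, 50)
})
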