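test_that("thermal time clamps at the base temperature", {
  expect_equal(thermal_time(20), 20)
  expect_equal(thermal_time(-5), 0)
  expect_equal(thermal_time(0), 0)
})

test_that("vernalization rate follows the published two-segment response", {
  expect_equal(vernalization_rate(0, nominal), 0.009)
  expect_equal(vernalization_rate(8, nominal), 0.017)   # VBEE + VAI * 8
  expect_equal(vernalization_rate(17, nominal), 0)       # MaxTvern endpoint
  expect_equal(vernalization_rate(-2, nominal), 0)
  expect_equal(vernalization_rate(25, nominal), 0)
  # peak at IntTvern, declining above
  expect_gt(vernalization_rate(8, nominal), vernalization_rate(13, nominal))
})

test_that("final leaf number responds to vernalization and daylength", {
  expect_equal(final_leaf_number(1, 16, nominal), 8.7)
  # shorter days add SLDL leaves per hour below the 16 h reference
  expect_equal(final_leaf_number(1, 12, nominal) -
                 final_leaf_number(1, 16, nominal), 0.6)
  # always inside the absolute bounds
  for (v in seq(0, 1, 0.2)) for (dlh in c(8, 12, 16, 20))
    expect_true(final_leaf_number(v, dlh, nominal) >= 8.7 &&
                  final_leaf_number(v, dlh, nominal) <= 18)
  # monotone non-increasing in daylength
  flns <- vapply(8:16, function(d) final_leaf_number(0.5, d, nominal),
                 numeric(1))
  expect_true(all(diff(flns) <= 0))
})

test_that("leaf appearance runs at the phyllochron with end-range factors", {
  phen <- phenology_init()
  phen$emerged <- TRUE
  phen$haun <- 5; phen$clock <- 5
  # mid-range: one leaf per 100 degCd = 5 days at 20 degC
  for (i in 1:5) phen <- leaf_appearance_step(phen, 20, nominal)
  expect_equal(phen$haun, 6, tolerance = 1e-12)
  # juvenile leaves appear faster (phyllochron x 0.75)
  phen$haun <- 1; phen$clock <- 1
  p1 <- leaf_appearance_step(phen, 20, nominal)
  expect_equal(p1$clock - 1, 20 / 75)
  # late leaves slower (x 1.25)
  phen$haun <- 10; phen$clock <- 10
  p2 <- leaf_appearance_step(phen, 20, nominal)
  expect_equal(p2$clock - 10, 20 / 125)
})

test_that("phase events fall at the published thermal-time boundaries", {
  w <- constant_weather(tmean = 15, days = 420)
  res <- run_season(nominal, w, soil_profile(awc = 150),
                    management_plan("HN"), "1970-10-01",
                    trace = TRUE, engine = "r")
  phen <- res$phen
  expect_equal(phen$day_emergence, 10)  # 150 degCd / 15 degCd per day
  expect_true(res$completed)
  # anthesis = flag leaf ligule + PFLLAnth phyllochrons
  tt_fll <- res$trace$tt_cum[phen$day_fll]
  tt_anth <- res$trace$tt_cum[phen$day_anthesis]
  expect_equal(tt_anth - tt_fll, 3 * 100, tolerance = 15)  # daily resolution
  # maturity = anthesis + Dgf
  tt_mat <- res$trace$tt_cum[nrow(res$trace)]
  expect_equal(tt_mat - tt_anth, 750, tolerance = 15)
  # ordering of all events
  days <- c(phen$day_emergence, phen$day_floral_init, phen$day_fll,
            phen$day_anthesis, phen$day_end_cd, phen$day_end_er,
            phen$day_maturity)
  expect_true(all(diff(days) >= 0))
})

test_that("anthesis advances when the phyllochron shortens", {
  w <- site_weather("CF", 3, seed = 6)
  anth <- vapply(c(0.8, 1.0, 1.2), function(m) {
    p <- nominal
    p[["P"]] <- 100 * m
    run_season(p, w, site_soil("CF"), management_plan("HN"),
               "1970-11-01")$anthesis_day
  }, numeric(1))
  expect_true(all(diff(anth) >= 0))
  expect_lt(anth[1], anth[3])
})

test_that("FLN decreases with more vernalizing exposure", {
  # colder winters vernalize earlier, freezing FLN with higher v_eff
  run_fln <- function(shift) {
    w <- constant_weather(tmean = 6 + shift, days = 420)
    res <- run_season(nominal, w, soil_profile(awc = 150),
                      management_plan("HN"), "1970-10-01",
                      trace = TRUE, engine = "r")
    res$phen$fln
  }
  expect_lte(run_fln(0), run_fln(6))
})
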