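test_that("layer geometry follows the published areas and culm layout", {
  lay <- build_layers(nominal, fln = 11, shoots_per_m2 = 500)
  expect_equal(lay$n, 11L)
  scale <- 500 * 1e-4
  # flag leaf area = RatioFLPL * AreaPL = 31 cm2 per shoot
  expect_equal(lay$lam_pot[11] / scale, 31)
  # penultimate leaf reaches AreaPL
  expect_equal(lay$lam_pot[10] / scale, 31)
  # pre-floral layers carry the small constant areas
  expect_equal(lay$lam_pot[1] / scale, 2.56)
  expect_equal(lay$sh_pot[1] / scale, 1.83)
  # NLL = 4.5: four full culm layers plus a half-weighted earliest one
  expect_equal(lay$fi_rank, 6.5)
  expect_equal(sum(lay$is_culm), 5L)  # ranks 8..11 fully culm + blended rank 7
  expect_equal(lay$lag[11], nominal[["PlagLL"]])
  expect_equal(lay$lag[3], nominal[["PlagSL"]])
  # half-weighted earliest culm layer blends the two duration sets
  expect_equal(lay$lag[7],
               0.5 * nominal[["PlagSL"]] + 0.5 * nominal[["PlagLL"]])
  expect_equal(length(lay$rank), ceiling(11))
  expect_error(build_layers(nominal, fln = 5), "degenerate")
})

test_that("light interception follows the turbid-medium law", {
  expect_equal(intercepted_par(0, 20, nominal)$ipar, 0)
  out <- intercepted_par(5, 20, nominal)
  expect_equal(out$cover, 1 - exp(-2), tolerance = 1e-12)
  expect_equal(out$ipar, 0.5 * 20 * (1 - exp(-2)))
  covers <- vapply(seq(0, 8, 0.5),
                   function(g) intercepted_par(g, 20, nominal)$cover,
                   numeric(1))
  expect_true(all(diff(covers) > 0))
})

test_that("actual RUE multiplies the five modifiers as published", {
  p <- nominal
  # all factors at their reference: potential RUE
  expect_equal(rue_actual(p, 18, 350, p[["MaxSLN"]], 1, 1), 3.4)
  expect_equal(rue_actual(p, 50, 350, p[["MaxSLN"]], 1, 1), 0)
  expect_equal(rue_actual(p, 18, 350, 0.35, 1, 1), 0)
  expect_equal(rue_actual(p, 18, 350, p[["MaxSLN"]], 1, 0.1),
               3.4 * drought_response(0.1, 0.3, 0))
  # CO2 sensitivity is logarithmic with the 350 ppm reference
  expect_equal(rue_actual(p, 18, 700, p[["MaxSLN"]], 1, 1),
               3.4 * (1 + 0.3 * log(2)))
  expect_error(rue_actual(p, 18, -10, 2, 1, 1), "co2")
})

test_that("biomass allocation conserves mass and feeds the ear window", {
  pools <- pools_init()
  out <- allocate_biomass(pools, 0, 0, 0, FALSE, nominal)
  expect_equal(out[c("dm_lam", "dm_stem", "dm_ear")],
               pools[c("dm_lam", "dm_stem", "dm_ear")])
  out <- allocate_biomass(pools, 10, 3, 2, TRUE, nominal)
  expect_equal(out$dm_ear, 0.5 * 5)   # FracBEAR of the post-leaf surplus
  expect_equal(out$dm_lam + out$dm_sheath + out$dm_stem + out$dm_ear -
                 (pools$dm_lam + pools$dm_sheath + pools$dm_stem +
                    pools$dm_ear), 10, tolerance = 1e-9)
})

test_that("N uptake caps at the root potential and declines after anthesis", {
  pools <- pools_init()
  pools$dm_lam <- 40; pools$dm_stem <- 60  # crop DM 100 = DMmaxNuptake
  pools$n_lam <- 0.5
  out <- nitrogen_step(pools, 2, 0.5, soil_mineral_n = 10,
                       tt_since_anthesis = -1, nominal)
  expect_equal(out$uptake, 0.5)   # MaxNuptake
  out <- nitrogen_step(pools, 2, 0.5, 10, tt_since_anthesis = 750, nominal)
  expect_equal(out$uptake, 0)     # decline factor endpoint at Dgf
  out <- nitrogen_step(pools, 2, 0.5, 0, -1, nominal)
  expect_equal(out$uptake, 0)     # empty soil
})

test_that("grain initiation and filling follow the published rules", {
  pools <- pools_init()
  pools$dm_ear <- 1.5
  out <- grain_step(pools, "cell_division", 10, 10, 0, TRUE, nominal)
  expect_equal(out$pools$grain_number, 150)  # EarGR * ear DM

  # with zero first-order transfer rates, grain N stays structural only
  p0 <- nominal
  p0[["MaxLeafRRND"]] <- 0
  p0[["MaxStemRRND"]] <- 0
  w <- site_weather("CF", 3, seed = 9)
  res <- run_season(p0, w, site_soil("CF"), management_plan("HN"),
                    "1970-11-01")
  # structural grain N is AlphaNC per unit structural DM, which is itself
  # bounded by total grain DM
  expect_lte(res$grain_n_maturity,
             nominal[["AlphaNC"]] * res$grain_dm_maturity + 1e-9)
  res_full <- run_season(nominal, w, site_soil("CF"), management_plan("HN"),
                         "1970-11-01")
  expect_lt(res$grain_n_maturity, res_full$grain_n_maturity)
  expect_lte(res$grain_n_maturity, res$crop_n_maturity)
})

test_that("canopy expansion and senescence respond to their drivers", {
  lay <- build_layers(nominal, fln = 11)
  canopy <- canopy_init(nominal)
  canopy <- canopy_install_layers(canopy, lay)
  # grow the first three leaves with no limits
  cs <- canopy_step(canopy, 0, 3, 1, 1, Inf, nominal)
  g0 <- canopy_gai(cs$canopy)$gai
  expect_gt(g0, 0)
  # zero expansion factor: gai can only decrease
  cs2 <- canopy_step(cs$canopy, 3, 4, 0, 1, Inf, nominal)
  expect_lte(canopy_gai(cs2$canopy)$gai, g0)
  # accelerated senescence shortens the senescence window MaxDSF-fold
  base <- canopy_step(cs$canopy, 4.8, 4.9, 0, 1, Inf, nominal)
  fast <- canopy_step(cs$canopy, 4.8, 4.9, 0, 3.25, Inf, nominal)
  expect_equal(fast$sen_lam, base$sen_lam * 3.25, tolerance = 1e-9)
  # running the clock far out senesces everything
  end <- canopy_step(cs$canopy, 4, 200, 1, 1, Inf, nominal)
  expect_equal(canopy_gai(end$canopy)$gai, 0, tolerance = 1e-9)
})

test_that("GAI at anthesis rises with the potential culm leaf size", {
  w <- site_weather("RR", 3, seed = 10)
  gais <- vapply(c(0.8, 1.2), function(m) {
    p <- nominal
    p[["AreaPL"]] <- 31 * m
    run_season(p, w, site_soil("RR"), management_plan("HN"),
               "1970-10-10")$gai_anthesis
  }, numeric(1))
  expect_gt(gais[2], gais[1])
})

test_that("crop DM at maturity increases strictly with potential RUE", {
  for (site in c("AV", "CF", "RR")) {
    w <- site_weather(site, 3, seed = 12)
    for (ntr in c("HN", "LN")) {
      dms <- vapply(c(0.8, 1.0, 1.2), function(m) {
        p <- nominal
        p[["RUE"]] <- 3.4 * m
        run_scenario_season(p, w, site, ntr, 1)$crop_dm_maturity
      }, numeric(1))
      expect_true(all(diff(dms) > 0), info = paste(site, ntr))
    }
  }
})
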