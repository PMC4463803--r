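#' Management plans
#'
#' The two N treatments: `HN` applies 20 g N m-2 as four split dressings
#' (GS21 4, GS31 8, GS37 6, GS65 2 g N m-2); `LN` applies 4 g N m-2 once at
#' GS30. A 10 mm irrigation is applied at sowing and 5 mm with every N
#' dressing (fertilizer dissolution water; it has no other role).
#'
#' @param n_treatment `"HN"` or `"LN"`.
#' @return A `management_plan` list: `n_treatment`, `sowing_irrigation_mm`
#'   and data.frame `events` (`stage`, `n`, `water`).
#' @export
management_plan <- function(n_treatment = c("HN", "LN")) {
  n_treatment <- match.arg(n_treatment)
  events <- if (n_treatment == "HN")
    data.frame(stage = c("GS21", "GS31", "GS37", "GS65"),
               n = c(4, 8, 6, 2), water = c(5, 5, 5, 5))
  else
    data.frame(stage = "GS30", n = 4, water = 5)
  structure(list(n_treatment = n_treatment, sowing_irrigation_mm = 10,
                 events = events),
            class = "management_plan")
}

#' Sowing dates used at the three sites
#'
#' @param site `"AV"`, `"CF"` or `"RR"`.
#' @return `"MM-DD"` string: 15 Nov (AV), 1 Nov (CF), 10 Oct (RR).
#' @export
site_sowing_date <- function(site) {
  switch(site, AV = "11-15", CF = "11-01", RR = "10-10",
         stop("site_sowing_date: unknown site '", site, "'"))
}

#' Growth-stage trigger mapping
#'
#' Maps the Zadoks stages used by the management plans onto the phenology
#' state: GS21 at Haun index 3, GS30 at floral initiation, GS31 at the start
#' of expansion of the first culm leaf, GS37 at Haun index FLN - 1, GS65 at
#' anthesis. Used day by day inside [run_season()]; each management event
#' fires once, on the first day its stage is reached.
#'
#' @param phen Phenology state for the day.
#' @param p Named parameter set.
#' @return Named logical vector over GS21, GS30, GS31, GS37, GS65.
#' @export
stage_reached <- function(phen, p) {
  fln <- phen$fln
  gs31 <- if (is.na(fln)) FALSE else {
    first_culm <- floor(fln - p[["NLL"]]) + 1
    phen$clock >= first_culm - p[["PexpL"]]
  }
  c(GS21 = phen$clock >= 3,
    GS30 = !is.na(phen$day_floral_init),
    GS31 = gs31,
    GS37 = if (is.na(fln)) FALSE else phen$haun >= fln - 1,
    GS65 = !is.na(phen$day_anthesis))
}

#' Resolve growth-stage trigger dates from a daily trace
#'
#' @param trace Daily trace data.frame from [run_season()] (`trace = TRUE`).
#' @param p Named parameter set.
#' @return Named integer vector of day indices (NA when never reached).
#' @export
resolve_stage_triggers <- function(trace, p) {
  first_day <- function(cond) {
    i <- which(cond)
    if (length(i)) i[1] else NA_integer_
  }
  fln <- trace$fln[nrow(trace)]
  c(GS21 = first_day(trace$clock >= 3),
    GS30 = first_day(trace$floral_init > 0),
    GS31 = if (is.na(fln)) NA_integer_ else
      first_day(trace$clock >= floor(fln - p[["NLL"]]) + 1 - p[["PexpL"]]),
    GS37 = if (is.na(fln)) NA_integer_ else first_day(trace$haun >= fln - 1),
    GS65 = first_day(trace$anthesis > 0))
}

#' Simulate one crop season
#'
#' Runs the daily loop from sowing to physiological maturity (or a 400-day
#' cap), coupling the weather series, the bucket soil water and mineral-N
#' balance, thermal-time phenology, the leaf-layer canopy, RUE-based biomass
#' production with its five modifiers, dry-matter and N allocation, and
#' grain filling. Management (fertilizer + irrigation) fires on growth-stage
#' triggers. Deterministic: identical inputs give identical outputs.
#'
#' Daily order of operations: canopy temperature and phenology; management
#' triggers; root extension; soil water balance (demand from yesterday's
#' canopy cover) and FTSW; biomass production (RUE x intercepted PAR from
#' yesterday's green area); canopy expansion / senescence under the drought,
#' C and N gates; DM allocation (leaves, ear window, stem / grain); crop N
#' demand and uptake; soil mineral N balance.
#'
#' @param p Named parameter set (75 entries; see [nominal_parameters()]).
#' @param weather A `weather_series` covering sowing to maturity.
#' @param soil A [soil_profile()].
#' @param mgmt A [management_plan()].
#' @param sowing_date Date (or string) of sowing.
#' @param co2 Air CO2 concentration, ppm.
#' @param shoots_per_m2 Ear-bearing shoot density.
#' @param trace Keep the daily trace? (returns data.frame `trace`)
#' @return A `simulation_outputs` list: `anthesis_day` (days after sowing),
#'   `anthesis_date`, `gai_anthesis`, `crop_dm_maturity`, `crop_n_maturity`,
#'   `grain_dm_maturity`, `grain_n_maturity`, `post_anthesis_n_uptake`,
#'   `gpc` (% of grain DM), `grain_number`, `completed`, `ledger` (season
#'   water / C / N balance residuals and throughputs).
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference R
#'   implementation; required for `trace = TRUE`). The two engines implement
#'   the identical daily arithmetic and are asserted equal in the tests.
#' @export
run_season <- function(p, weather, soil, mgmt, sowing_date,
                       co2 = 360, shoots_per_m2 = 500, trace = FALSE,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp" && !trace)
    return(run_season_cpp(p, weather, soil, mgmt, sowing_date, co2,
                          shoots_per_m2))
  run_season_r(p, weather, soil, mgmt, sowing_date, co2, shoots_per_m2,
               trace)
}

run_season_r <- function(p, weather, soil, mgmt, sowing_date,
                         co2 = 360, shoots_per_m2 = 500, trace = FALSE) {
  sowing_date <- as.Date(sowing_date)
  dates <- weather$date
  i0 <- match(sowing_date, dates)
  if (is.na(i0)) stop("run_season: sowing date not covered by weather")
  n_days <- min(400L, length(dates) - i0 + 1L)
  if (n_days < 150L) stop("run_season: weather series too short after sowing")
  idx <- i0:(i0 + n_days - 1L)
  tmin <- weather$tmin[idx]; tmax <- weather$tmax[idx]
  srad <- weather$srad[idx]; rain <- weather$rain[idx]
  lat <- attr(weather, "latitude")
  doy <- as.integer(format(dates[idx], "%j"))
  tmean <- (tmin + tmax) / 2
  ra <- extraterrestrial_radiation(lat, doy)
  dl <- daylength(lat, doy)
  pet <- hargreaves_et(tmin, tmax, ra)
  fdif <- ifelse(rain > 0.1, 1.0, 0.5)  # overcast on wet days

  # clip the cross-parameter orderings the modules need (validation is
  # advisory; perturbations are sampled independently)
  p <- clip_orderings(p)

  phen <- phenology_init()
  soil_state <- soil_init(soil)
  canopy <- canopy_init(p, shoots_per_m2)
  pools <- pools_init()
  seed_dm0 <- pools$seed_dm
  seed_n0 <- pools$n_lam

  fired <- c(GS21 = FALSE, GS30 = FALSE, GS31 = FALSE, GS37 = FALSE,
             GS65 = FALSE)
  ev_stage <- mgmt$events$stage
  ev_n <- mgmt$events$n
  ev_water <- mgmt$events$water

  water_in <- 0; water_out <- 0
  n_in <- 0; n_out_leach <- 0; crop_n_uptake_cum <- 0
  dm_prod_cum <- 0; seed_dm_used <- 0
  soil_water0 <- soil_state$water
  soil_n0 <- soil_state$mineral_n

  gai <- 0; gai_lam <- 0; gai_sh <- 0
  gai_anthesis <- NA_real_
  anth_done <- FALSE

  tr <- if (trace) vector("list", n_days) else NULL

  for (d in seq_len(n_days)) {
    t_air <- tmean[d]
    t_can <- if (phen$haun < p[["MaxLeafSoil"]])
      mean(tmean[max(1, d - 4):d]) else t_air

    phen <- phenology_step(phen, t_can, t_air, dl[d], d, p)
    tt <- phen$daily_tt
    if (!is.na(phen$day_maturity)) break  # filling stops at maturity

    if (!canopy$built && !is.na(phen$fln))
      canopy <- canopy_install_layers(canopy,
                                      build_layers(p, phen$fln, shoots_per_m2))

    irrigation <- if (d == 1L) mgmt$sowing_irrigation_mm else 0
    fertilizer <- 0
    reached <- stage_reached(phen, p)
    for (s in which(reached & !fired)) {
      fired[s] <- TRUE
      hit <- which(ev_stage == names(fired)[s])
      if (length(hit)) {
        fertilizer <- fertilizer + sum(ev_n[hit])
        irrigation <- irrigation + sum(ev_water[hit])
      }
    }

    if (phen$emerged) {
      re <- root_extension(soil_state, soil, tt, p)
      soil_state <- re$state
      water_in <- water_in + re$water_added
    }

    cover <- 1 - exp(-p[["Kl"]] * gai)
    transp_demand <- pet[d] * cover
    # soil evaporation shuts down as the surface dries
    ftsw_pre <- ftsw(soil_state, soil)
    evap_demand <- 0.6 * pet[d] * (1 - cover) * min(1, 3 * ftsw_pre)
    sw <- step_water(soil_state, soil, rain[d] + irrigation, transp_demand,
                     evap_demand, p)
    soil_state <- sw$state
    water_in <- water_in + rain[d] + irrigation
    water_out <- water_out + sw$transpiration + sw$evaporation + sw$drainage
    ftsw_d <- ftsw(soil_state, soil)

    daily_dm <- 0; uptake <- 0
    if (phen$emerged) {
      f_exp <- drought_response(ftsw_d, p[["UpperFTSWexp"]],
                                p[["LowerFTSWexp"]])
      accel <- senescence_acceleration(ftsw_d, p)

      ip <- intercepted_par(gai, srad[d], p)
      sln_mean <- if (gai_lam > 1e-9) pools$n_lam / gai_lam else p[["MaxSLN"]]
      rue <- rue_actual(p, t_air, co2, sln_mean, fdif[d], ftsw_d)
      daily_dm <- rue * ip$ipar
      dm_prod_cum <- dm_prod_cum + daily_dm

      since_anth <- if (anth_done) phen$tt_cum - phen$tt_anthesis else -1
      filling <- anth_done && since_anth > p[["Dcd"]]

      # N available for new lamina area (expansion gate)
      decline <- if (since_anth <= 0) 1 else max(0, 1 - since_anth / p[["Dgf"]])
      crop_dm_tot <- pools$dm_lam + pools$dm_sheath + pools$dm_stem +
        pools$dm_ear + pools$dm_grain
      sup <- p[["MaxNuptake"]] * min(1, crop_dm_tot / p[["DMmaxNuptake"]]) *
        decline
      n_for_exp <- min(soil_state$mineral_n, sup) +
        max(0, pools$n_lam - p[["CritSLN"]] * gai_lam)
      max_area_n <- n_for_exp / p[["CritSLN"]]

      # canopy expansion is development-driven; its dry-matter cost is
      # booked afterwards from today's production, the seed reserve and
      # the stem WSC pool (in that order). Under source limitation the
      # leaves run below their target specific weight.
      cs <- canopy_step(canopy, phen$clock_prev, phen$clock, f_exp, accel,
                        max_area_n, p)
      canopy <- cs$canopy
      wsc_avail <- min(pools$wsc, pools$dm_stem)
      paid <- if (anth_done) 0 else
        min(cs$dm_demand, daily_dm + pools$seed_dm + wsc_avail)
      from_prod <- min(paid, if (anth_done) 0 else daily_dm)
      seed_draw <- min(paid - from_prod, pools$seed_dm)
      wsc_draw <- max(0, paid - from_prod - seed_draw)
      pools$seed_dm <- pools$seed_dm - seed_draw
      seed_dm_used <- seed_dm_used + seed_draw
      pools$wsc <- pools$wsc - wsc_draw
      pools$dm_stem <- pools$dm_stem - wsc_draw
      lam_cost <- cs$d_lam * p[["SLWp"]]
      sh_cost <- cs$d_sh * p[["SSWp"]]
      lam_share <- if (lam_cost + sh_cost > 0)
        lam_cost / (lam_cost + sh_cost) else 0

      # senesced tissue moves to the dead pools (with its structural N)
      dead_lam <- min(pools$dm_lam, cs$sen_lam * p[["SLWp"]])
      dead_sh <- min(pools$dm_sheath, cs$sen_sh * p[["SSWp"]])
      dn_lam_dead <- min(pools$n_lam, p[["StrucLeafN"]] * dead_lam)
      dn_sh_dead <- min(pools$n_sheath, p[["StrucStemN"]] * dead_sh)
      pools$dm_lam <- pools$dm_lam - dead_lam
      pools$dm_sheath <- pools$dm_sheath - dead_sh
      pools$dm_dead <- pools$dm_dead + dead_lam + dead_sh
      pools$n_lam <- pools$n_lam - dn_lam_dead
      pools$n_sheath <- pools$n_sheath - dn_sh_dead
      pools$n_dead <- pools$n_dead + dn_lam_dead + dn_sh_dead

      at_anth <- !anth_done && !is.na(phen$day_anthesis)
      if (!anth_done) {
        in_ear <- !is.na(phen$tt_fll) &&
          phen$tt_cum >= phen$tt_fll + p[["Deg"]] * p[["PFLLAnth"]] * p[["P"]]
        pools <- allocate_biomass(pools, daily_dm + seed_draw + wsc_draw,
                                  paid * lam_share, paid * (1 - lam_share),
                                  in_ear, p)
      }
      if (at_anth) {
        anth_done <- TRUE
        gai_anthesis <- canopy_gai(canopy)$gai
      }
      if (anth_done && is.na(phen$day_maturity)) {
        since_anth <- phen$tt_cum - phen$tt_anthesis
        phase <- if (since_anth <= p[["Dcd"]]) "cell_division" else "filling"
        # on the anthesis day itself the production was already allocated
        gs <- grain_step(pools, phase, since_anth, tt,
                         if (at_anth) 0 else daily_dm, at_anth, p)
        pools <- gs$pools
        if (phase == "cell_division" && gs$unused_dm > 0) {
          # assimilate in excess of the young grains banks as labile stem
          # carbohydrate, remobilized during effective grain filling
          pools$dm_stem <- pools$dm_stem + gs$unused_dm
          pools$wsc <- pools$wsc + gs$unused_dm
        }

        # LLOSS: lamina N withdrawal senesces green area
        glam <- sum(canopy$a_exp_lam - canopy$a_sen_lam)
        if (gs$lam_n_withdrawn > 0 && glam > 1e-9) {
          sln <- max(pools$n_lam / glam, 0.2)
          extra <- min(p[["LLOSS"]] * gs$lam_n_withdrawn / sln, glam)
          green <- canopy$a_exp_lam - canopy$a_sen_lam
          tot <- sum(green)
          if (tot > 1e-12 && extra > 0) {
            canopy$a_sen_lam <- canopy$a_sen_lam + extra * green / tot
            dead <- min(extra * p[["SLWp"]], pools$dm_lam)
            dn <- min(pools$n_lam, p[["StrucLeafN"]] * dead)
            pools$dm_lam <- pools$dm_lam - dead
            pools$dm_dead <- pools$dm_dead + dead
            pools$n_lam <- pools$n_lam - dn
            pools$n_dead <- pools$n_dead + dn
          }
        }
      }

      g <- canopy_gai(canopy)
      gai <- g$gai; gai_lam <- g$gai_lam; gai_sh <- g$gai_sh
      ns <- nitrogen_step(pools, gai_lam, gai_sh, soil_state$mineral_n,
                          if (anth_done) phen$tt_cum - phen$tt_anthesis else -1,
                          p)
      pools <- ns$pools
      uptake <- ns$uptake
      crop_n_uptake_cum <- crop_n_uptake_cum + uptake
    }

    sn <- step_nitrogen(soil_state, soil, t_air, fertilizer, uptake,
                        sw$drainage)
    soil_state <- sn$state
    n_in <- n_in + sn$mineralization + fertilizer
    n_out_leach <- n_out_leach + sn$leaching

    if (trace) {
      tr[[d]] <- c(day = d, tmean = t_air, tt_cum = phen$tt_cum,
                   clock = phen$clock, haun = phen$haun, vern = phen$vern,
                   fln = if (is.na(phen$fln)) NA_real_ else phen$fln,
                   ftsw = ftsw_d, gai = gai, dm_lam = pools$dm_lam,
                   dm_sheath = pools$dm_sheath, dm_stem = pools$dm_stem,
                   dm_ear = pools$dm_ear, dm_grain = pools$dm_grain,
                   dm_dead = pools$dm_dead, wsc = pools$wsc,
                   dm_prod_cum = dm_prod_cum, seed_used_cum = seed_dm_used,
                   n_grain = pools$n_grain, mineral_n = soil_state$mineral_n,
                   floral_init = as.numeric(!is.na(phen$day_floral_init)),
                   anthesis = as.numeric(!is.na(phen$day_anthesis)))
    }
    if (!is.na(phen$day_maturity)) break
  }

  completed <- !is.na(phen$day_maturity)
  crop_dm <- pools$dm_lam + pools$dm_sheath + pools$dm_stem + pools$dm_ear +
    pools$dm_grain + pools$dm_dead
  crop_n <- pools$n_lam + pools$n_sheath + pools$n_stem + pools$n_grain +
    pools$n_dead
  out <- list(
    anthesis_day = phen$day_anthesis,
    anthesis_date = if (!is.na(phen$day_anthesis))
      dates[i0 + phen$day_anthesis - 1L] else as.Date(NA),
    anthesis_doy = if (!is.na(phen$day_anthesis))
      doy[phen$day_anthesis] else NA_real_,
    gai_anthesis = gai_anthesis,
    crop_dm_maturity = crop_dm,
    crop_n_maturity = crop_n,
    grain_dm_maturity = pools$dm_grain,
    grain_n_maturity = pools$n_grain,
    post_anthesis_n_uptake = pools$post_anth_n_uptake,
    gpc = if (pools$dm_grain > 0) 100 * 5.7 * pools$n_grain / pools$dm_grain
          else NA_real_,
    grain_number = pools$grain_number,
    completed = completed,
    ledger = list(
      water_residual = (soil_state$water - soil_water0) -
        (water_in - water_out),
      water_throughput = water_in + water_out,
      c_residual = crop_dm - dm_prod_cum - seed_dm_used,
      dm_produced = dm_prod_cum,
      soil_n_residual = (soil_state$mineral_n - soil_n0) -
        (n_in - n_out_leach - crop_n_uptake_cum),
      n_throughput = n_in + n_out_leach + crop_n_uptake_cum,
      crop_n_residual = crop_n - crop_n_uptake_cum - seed_n0,
      uptake_cum = crop_n_uptake_cum),
    phen = phen)
  if (trace) {
    keep <- !vapply(tr, is.null, logical(1))
    out$trace <- as.data.frame(do.call(rbind, tr[keep]))
  }
  class(out) <- "simulation_outputs"
  out
}

clip_orderings <- function(p) {
  if (p[["CritSLN"]] > p[["MaxSLN"]]) p[["CritSLN"]] <- p[["MaxSLN"]]
  for (s in c("exp", "gs", "rue", "sen")) {
    u <- paste0("UpperFTSW", s); l <- paste0("LowerFTSW", s)
    if (p[[l]] > p[[u]]) p[[l]] <- p[[u]]
  }
  p
}

run_season_cpp <- function(p, weather, soil, mgmt, sowing_date, co2,
                           shoots_per_m2) {
  sowing_date <- as.Date(sowing_date)
  dates <- weather$date
  i0 <- match(sowing_date, dates)
  if (is.na(i0)) stop("run_season: sowing date not covered by weather")
  n_days <- min(400L, length(dates) - i0 + 1L)
  if (n_days < 150L) stop("run_season: weather series too short after sowing")
  idx <- i0:(i0 + n_days - 1L)
  tmin <- weather$tmin[idx]; tmax <- weather$tmax[idx]
  lat <- attr(weather, "latitude")
  doy <- as.integer(format(dates[idx], "%j"))
  tmean <- (tmin + tmax) / 2
  ra <- extraterrestrial_radiation(lat, doy)
  dl <- daylength(lat, doy)
  pet <- hargreaves_et(tmin, tmax, ra)
  fdif <- ifelse(weather$rain[idx] > 0.1, 1.0, 0.5)

  par <- p[parameter_table()$name]
  stages <- c("GS21", "GS30", "GS31", "GS37", "GS65")
  fert <- irr <- stats::setNames(numeric(5), stages)
  for (i in seq_len(nrow(mgmt$events))) {
    s <- mgmt$events$stage[i]
    fert[s] <- fert[s] + mgmt$events$n[i]
    irr[s] <- irr[s] + mgmt$events$water[i]
  }
  res <- .season_core(unname(par), tmean, weather$srad[idx],
                      weather$rain[idx], pet, dl, fdif,
                      soil$awc, soil$max_root_depth, soil$percolation_coeff,
                      soil$mineralization_k, soil$organic_n,
                      soil$initial_inorganic_n, unname(fert), unname(irr),
                      mgmt$sowing_irrigation_mm, co2, shoots_per_m2)
  if (!is.null(res$error)) stop("run_season: ", res$error)
  res$anthesis_date <- if (!is.na(res$anthesis_day))
    dates[i0 + res$anthesis_day - 1L] else as.Date(NA)
  res$anthesis_doy <- if (!is.na(res$anthesis_day))
    doy[res$anthesis_day] else NA_real_
  res$phen <- list(day_emergence = if (res$day_emergence > 0)
                     res$day_emergence else NA_integer_,
                   day_floral_init = if (res$day_floral_init > 0)
                     res$day_floral_init else NA_integer_,
                   day_fll = if (res$day_fll > 0) res$day_fll else NA_integer_,
                   day_anthesis = res$anthesis_day,
                   day_end_cd = if (res$day_end_cd > 0)
                     res$day_end_cd else NA_integer_,
                   day_end_er = if (res$day_end_er > 0)
                     res$day_end_er else NA_integer_,
                   day_maturity = if (res$day_maturity > 0)
                     res$day_maturity else NA_integer_,
                   fln = res$fln)
  class(res) <- "simulation_outputs"
  res
}

#' Run one site x N-treatment scenario for one season
#'
#' Convenience wrapper binding a site's weather preset, soil, sowing date
#' and a management plan. The sowing falls in calendar year
#' `start_year + season - 1`; the weather series must cover it.
#'
#' @param p Named parameter set.
#' @param weather Weather series for the site (e.g. from
#'   [generate_weather()] with [site_preset()]).
#' @param site `"AV"`, `"CF"` or `"RR"`.
#' @param n_treatment `"HN"` or `"LN"`.
#' @param season Season index (1-based).
#' @param start_year First calendar year of the weather series.
#' @param ... Passed to [run_season()].
#' @return [run_season()] outputs.
#' @export
run_scenario_season <- function(p, weather, site, n_treatment, season,
                                start_year = 1970L, ...) {
  sow <- as.Date(sprintf("%d-%s", start_year + season - 1L,
                         site_sowing_date(site)))
  run_season(p, weather, site_soil(site), management_plan(n_treatment),
             sow, ...)
}
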