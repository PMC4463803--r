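#' Build the leaf-layer geometry of a canopy
#'
#' The canopy is a stack of `ceil(fln)` leaf layers per shoot. Layers up to
#' the floral-initiation rank (`fln - NLL`) carry the small pre-floral lamina
#' (`AreaSL`) and sheath (`AreaSS`) areas; the `NLL` culm layers ramp
#' linearly from `AreaSL` up to `AreaPL` at the penultimate rank, the flag
#' leaf is `RatioFLPL * AreaPL`, and culm sheath areas follow the quadratic
#' `AreaSS * (1 + aSheath * (j/NLL)^2)` in the culm index j. A fractional
#' `NLL` weights the earliest culm layer between the two geometries. Areas
#' are returned per unit ground area (m2 m-2), i.e. already multiplied by
#' shoot density.
#'
#' @param p Named parameter set.
#' @param fln Final leaf number (real, fixed).
#' @param shoots_per_m2 Ear-bearing shoot density (default 500 = 2 shoots x
#'   250 plants m-2).
#' @return List of per-rank vectors: `rank`, `lam_pot`, `sh_pot` (m2 m-2),
#'   `lag`, `sen` (phyllochrons), `is_culm`, plus `fi_rank` and `n`.
#' @export
build_layers <- function(p, fln, shoots_per_m2 = 500) {
  fi_rank <- fln - p[["NLL"]]
  if (fi_rank < 1) stop("build_layers: degenerate canopy (fln - NLL < 1)")
  n <- ceiling(fln)
  rank <- seq_len(n)
  scale <- shoots_per_m2 * 1e-4  # cm2 per shoot -> m2 per m2 ground

  lam <- rep(p[["AreaSL"]], n)
  sh <- rep(p[["AreaSS"]], n)
  lag <- rep(p[["PlagSL"]], n)
  sen <- rep(p[["PsenSL"]], n)

  culm <- rank > fi_rank
  j <- rank - fi_rank                     # culm index (j > 0 where culm)
  w <- pmin(1, j)                         # earliest culm layer is fractional
  # lamina ramp reaching AreaPL at the penultimate rank
  denom <- max((n - 1) - fi_rank, 1e-9)
  ramp <- p[["AreaSL"]] + (p[["AreaPL"]] - p[["AreaSL"]]) * pmin(1, j / denom)
  ramp[n] <- p[["RatioFLPL"]] * p[["AreaPL"]]
  sh_culm <- p[["AreaSS"]] * (1 + p[["aSheath"]] * (j / p[["NLL"]])^2)

  lam[culm] <- (1 - w[culm]) * p[["AreaSL"]] + w[culm] * ramp[culm]
  sh[culm] <- (1 - w[culm]) * p[["AreaSS"]] + w[culm] * sh_culm[culm]
  lag[culm] <- (1 - w[culm]) * p[["PlagSL"]] + w[culm] * p[["PlagLL"]]
  sen[culm] <- (1 - w[culm]) * p[["PsenSL"]] + w[culm] * p[["PsenLL"]]

  list(rank = rank, lam_pot = lam * scale, sh_pot = sh * scale,
       lag = lag, sen = sen, is_culm = culm, fi_rank = fi_rank, n = n)
}

#' Initialize a canopy state
#'
#' Starts with provisional pre-floral geometry for the first few ranks; the
#' full layout is installed by [canopy_install_layers()] when the final leaf
#' number is fixed (ranks already expanding keep their provisional
#' geometry).
#'
#' @param p Named parameter set.
#' @param shoots_per_m2 Shoot density.
#' @param n_provisional Number of provisional pre-floral ranks.
#' @return A `canopy_state` list with per-layer vectors `lam_pot`, `sh_pot`,
#'   `lag`, `sen`, `a_exp_lam`, `a_sen_lam`, `a_exp_sh`, `a_sen_sh`.
#' @export
canopy_init <- function(p, shoots_per_m2 = 500, n_provisional = 8L) {
  scale <- shoots_per_m2 * 1e-4
  n <- n_provisional
  list(n = n, built = FALSE, shoots_per_m2 = shoots_per_m2,
       rank = seq_len(n),
       lam_pot = rep(p[["AreaSL"]] * scale, n),
       sh_pot = rep(p[["AreaSS"]] * scale, n),
       lag = rep(p[["PlagSL"]], n), sen = rep(p[["PsenSL"]], n),
       a_exp_lam = numeric(n), a_sen_lam = numeric(n),
       a_exp_sh = numeric(n), a_sen_sh = numeric(n),
       fi_rank = NA_real_)
}

#' @rdname canopy_init
#' @param canopy Canopy state.
#' @param layers Result of [build_layers()].
#' @export
canopy_install_layers <- function(canopy, layers) {
  n <- layers$n
  started <- canopy$a_exp_lam > 0
  keep <- which(started[seq_len(min(canopy$n, n))])
  grow <- function(x, fill) { y <- fill; y[keep] <- x[keep]; y }
  canopy$lam_pot <- grow(canopy$lam_pot, layers$lam_pot)
  canopy$sh_pot <- grow(canopy$sh_pot, layers$sh_pot)
  canopy$lag <- grow(canopy$lag, layers$lag)
  canopy$sen <- grow(canopy$sen, layers$sen)
  pad <- function(x, n) { length(x) <- n; x[is.na(x)] <- 0; x }
  canopy$a_exp_lam <- pad(canopy$a_exp_lam, n)
  canopy$a_sen_lam <- pad(canopy$a_sen_lam, n)
  canopy$a_exp_sh <- pad(canopy$a_exp_sh, n)
  canopy$a_sen_sh <- pad(canopy$a_sen_sh, n)
  canopy$rank <- layers$rank
  canopy$n <- n
  canopy$fi_rank <- layers$fi_rank
  canopy$built <- TRUE
  canopy
}

#' Green area index of a canopy state
#'
#' @param canopy Canopy state.
#' @return List: `gai` (laminae + sheaths), `gai_lam`, `gai_sh`, all
#'   m2 m-2.
#' @export
canopy_gai <- function(canopy) {
  gl <- sum(canopy$a_exp_lam - canopy$a_sen_lam)
  gs <- sum(canopy$a_exp_sh - canopy$a_sen_sh)
  list(gai = gl + gs, gai_lam = gl, gai_sh = gs)
}

#' One day of canopy expansion and senescence
#'
#' Each layer's lamina and sheath expand linearly over `PexpL` phyllochrons
#' (clock window \[rank - PexpL, rank\]), scaled by the drought expansion
#' factor and capped by the lamina area the day's N supply can furnish with
#' the critical specific leaf N (`max_lam_area_n`). Expansion is driven by
#' development, not by carbon: the dry-matter cost of the realized growth
#' (`dm_demand`, at the `SLWp` / `SSWp` target specific weights) is booked
#' by the caller up to the assimilate actually available, so under source
#' limitation leaves run below their target specific weight rather than
#' stalling. After its lag each layer senesces linearly over
#' `sen / sen_accel` phyllochrons.
#'
#' @param canopy Canopy state.
#' @param clock_old,clock_new Phyllochron clock before/after today.
#' @param expansion_factor Drought factor for expansion in \[0, 1\].
#' @param sen_accel Senescence acceleration factor (>= 1).
#' @param max_lam_area_n Maximum new lamina area permitted by N supply,
#'   m2 m-2 (`Inf` to disable).
#' @param p Named parameter set.
#' @return List: updated `canopy`, realized `d_lam`, `d_sh` (new areas,
#'   m2 m-2), `sen_lam`, `sen_sh` (areas senesced today), `dm_demand`
#'   (g m-2 at target specific weights).
#' @export
canopy_step <- function(canopy, clock_old, clock_new, expansion_factor,
                        sen_accel, max_lam_area_n, p) {
  texp <- p[["PexpL"]]
  rank <- canopy$rank
  win <- pmax(0, pmin(clock_new, rank) - pmax(clock_old, rank - texp))
  d_lam <- canopy$lam_pot * win / texp * expansion_factor
  d_sh <- canopy$sh_pot * win / texp * expansion_factor

  tot_lam <- sum(d_lam)
  if (is.finite(max_lam_area_n) && tot_lam > max_lam_area_n && tot_lam > 0) {
    f <- max(0, max_lam_area_n) / tot_lam
    d_lam <- d_lam * f
    d_sh <- d_sh * f    # sheath growth follows its lamina
    tot_lam <- sum(d_lam)
  }
  demand <- tot_lam * p[["SLWp"]] + sum(d_sh) * p[["SSWp"]]
  canopy$a_exp_lam <- canopy$a_exp_lam + d_lam
  canopy$a_exp_sh <- canopy$a_exp_sh + d_sh

  sen_start <- rank + canopy$lag
  dsen_clock <- pmax(0, clock_new - pmax(clock_old, sen_start))
  rate <- dsen_clock * sen_accel / canopy$sen
  sen_lam <- pmin(canopy$a_exp_lam * rate,
                  canopy$a_exp_lam - canopy$a_sen_lam)
  sen_sh <- pmin(canopy$a_exp_sh * rate,
                 canopy$a_exp_sh - canopy$a_sen_sh)
  canopy$a_sen_lam <- canopy$a_sen_lam + sen_lam
  canopy$a_sen_sh <- canopy$a_sen_sh + sen_sh

  list(canopy = canopy, d_lam = sum(d_lam), d_sh = sum(d_sh),
       sen_lam = sum(sen_lam), sen_sh = sum(sen_sh), dm_demand = demand)
}

#' Light interception
#'
#' Turbid-medium canopy cover `1 - exp(-Kl * gai)`; intercepted
#' photosynthetically active radiation is half the global radiation times
#' cover.
#'
#' @param gai Green area index, m2 m-2.
#' @param srad Daily global radiation, MJ m-2.
#' @param p Named parameter set (uses `Kl`).
#' @return List: `ipar` (MJ m-2), `cover` (fraction).
#' @export
intercepted_par <- function(gai, srad, p) {
  cover <- 1 - exp(-p[["Kl"]] * gai)
  list(ipar = 0.5 * srad * cover, cover = cover)
}

#' Actual radiation use efficiency
#'
#' Potential RUE (defined under overcast conditions) multiplied by five
#' factors: temperature (piecewise linear, 0 at 0 degC, 1 at `Topt`, 0 at
#' `Tmax`), CO2 (`1 + FacCO2 * log(co2/350)`), leaf N
#' (saturating exponential in mean specific leaf N between `MinSLN` and
#' `MaxSLN`), diffuse-light ratio (`(1 + SlopeFR * fdif) / (1 + SlopeFR)`,
#' equal to 1 under fully diffuse light) and soil water deficit
#' ([drought_response()] with the `UpperFTSWrue` / `LowerFTSWrue`
#' thresholds).
#'
#' @param p Named parameter set.
#' @param tmean Daily mean temperature, degC.
#' @param co2 Air CO2 concentration, ppm (> 0).
#' @param mean_sln Mean specific leaf N of the green laminae, g N m-2.
#' @param diffuse_fraction Ratio of diffuse to total radiation, in \[0, 1\].
#' @param ftsw_value FTSW.
#' @return g DM MJ-1 (intercepted PAR).
#' @export
rue_actual <- function(p, tmean, co2, mean_sln, diffuse_fraction, ftsw_value) {
  if (co2 <= 0) stop("rue_actual: co2 must be > 0")
  topt <- p[["Topt"]]; tmax <- p[["Tmax"]]
  if (topt >= tmax) topt <- tmax - 1e-6   # clip inverted draw
  ft <- if (tmean <= 0 || tmean >= tmax) 0
        else if (tmean <= topt) tmean / topt
        else (tmax - tmean) / (tmax - topt)
  fco2 <- 1 + p[["FacCO2"]] * log(co2 / 350)
  kn <- p[["TauSLN"]]
  span <- max(p[["MaxSLN"]] - p[["MinSLN"]], 1e-9)
  fn <- (1 - exp(-kn * (mean_sln - p[["MinSLN"]]))) / (1 - exp(-kn * span))
  fn <- min(1, max(0, fn))
  fr <- (1 + p[["SlopeFR"]] * diffuse_fraction) / (1 + p[["SlopeFR"]])
  fw <- drought_response(ftsw_value, p[["UpperFTSWrue"]], p[["LowerFTSWrue"]])
  p[["RUE"]] * ft * fco2 * fn * fr * fw
}

#' Initialize the carbon and nitrogen pools
#'
#' Pools in g m-2 ground: dry matter of green laminae, green sheaths, stem
#' (with its water-soluble carbohydrate subpool), ear, grain and dead
#' tissue; N in laminae, sheaths, stem(+ear), grain and dead tissue; the
#' post-anthesis N uptake counter; and grain bookkeeping (`grain_number`,
#' structural grain DM, reserve pool).
#'
#' @param seed_n Seed-borne N starting the lamina pool, g N m-2.
#' @param seed_dm Seed carbohydrate reserve that bootstraps early leaf
#'   growth before the canopy intercepts light, g m-2 (250 seeds x ~40 mg).
#' @return A `cn_pools` list.
#' @export
pools_init <- function(seed_n = 0.15, seed_dm = 10) {
  list(dm_lam = 0, dm_sheath = 0, dm_stem = 0, dm_ear = 0, dm_grain = 0,
       dm_dead = 0, wsc = 0, seed_dm = seed_dm,
       n_lam = seed_n, n_sheath = 0, n_stem = 0, n_grain = 0, n_dead = 0,
       post_anth_n_uptake = 0,
       grain_number = 0, grain_struct_dm = 0,
       reserve_pool = NA_real_, reserve_released = 0,
       anth_dm_lam = NA_real_, anth_dm_sheath = NA_real_, anth_wsc = NA_real_)
}

#' Allocate the day's biomass production
#'
#' Lamina and sheath growth take what the day's expansion realized (at
#' `SLWp` / `SSWp` cost); during the ear-growth window a fraction `FracBEAR`
#' of the remainder goes to the ear; the rest goes to the stem, of which
#' `FracStemWSC` is tracked as labile water-soluble carbohydrate. Mass is
#' conserved exactly; the caller guarantees `dm_leaf + dm_sheath <=
#' daily_dm`.
#'
#' @param pools `cn_pools`.
#' @param daily_dm Biomass produced today, g m-2.
#' @param dm_leaf,dm_sheath DM consumed by today's lamina / sheath growth.
#' @param in_ear_window Logical: is today inside the ear-growth window?
#' @param p Named parameter set.
#' @return Updated pools.
#' @export
allocate_biomass <- function(pools, daily_dm, dm_leaf, dm_sheath,
                             in_ear_window, p) {
  rest <- daily_dm - dm_leaf - dm_sheath
  if (rest < -1e-9) stop("allocate_biomass: leaf demand exceeds production")
  rest <- max(0, rest)
  pools$dm_lam <- pools$dm_lam + dm_leaf
  pools$dm_sheath <- pools$dm_sheath + dm_sheath
  ear <- if (in_ear_window) p[["FracBEAR"]] * rest else 0
  stem <- rest - ear
  pools$dm_ear <- pools$dm_ear + ear
  pools$dm_stem <- pools$dm_stem + stem
  pools$wsc <- pools$wsc + p[["FracStemWSC"]] * stem
  pools
}

#' Critical N concentration and N nutrition index
#'
#' Critical shoot N percentage follows the dilution curve
#' `AlphaNNI * DM^-BetaNNI` (DM in t ha-1, constant below 1 t ha-1); the N
#' nutrition index is the ratio of the actual to the critical percentage.
#'
#' @param shoot_dm Above-ground DM, g m-2.
#' @param shoot_n Above-ground N, g m-2.
#' @param p Named parameter set.
#' @return List: `n_crit_pct`, `n_act_pct`, `nni`.
#' @export
nni_status <- function(shoot_dm, shoot_n, p) {
  dm_t <- max(shoot_dm, 1e-9) / 100      # g m-2 -> t ha-1
  ncrit <- if (dm_t <= 1) p[["AlphaNNI"]] else p[["AlphaNNI"]] * dm_t^(-p[["BetaNNI"]])
  nact <- 100 * shoot_n / max(shoot_dm, 1e-9)
  list(n_crit_pct = ncrit, n_act_pct = nact,
       nni = if (ncrit > 0) nact / ncrit else 1)
}

#' One day of crop N demand, uptake and allocation
#'
#' Lamina N capacity integrates the exponential vertical N profile whose
#' extinction ratio is `AlphaKn * NNI^BetaKn` times the light extinction
#' coefficient, with the top-layer ceiling `MaxSLN`; sheath capacity follows
#' the lamina allometry (`AlphaSSN`, `BetaSSN`); stem (+ ear) capacity is
#' `MaxStemN` per unit DM. Uptake is the minimum of demand, soil mineral N
#' and the potential root uptake rate `MaxNuptake`, scaled by
#' `min(1, DM / DMmaxNuptake)` and declining linearly with thermal time
#' after anthesis (zero at `Dgf`). Allocation priority: laminae, sheaths,
#' stem.
#'
#' @param pools `cn_pools`.
#' @param gai_lam,gai_sh Green lamina / sheath area, m2 m-2.
#' @param soil_mineral_n Mineral N available today, g N m-2.
#' @param tt_since_anthesis degCd since anthesis (negative before).
#' @param p Named parameter set.
#' @return List: updated `pools`, `uptake` (g N m-2), `nni`, `supply_cap`
#'   (today's root-limited potential uptake).
#' @export
nitrogen_step <- function(pools, gai_lam, gai_sh, soil_mineral_n,
                          tt_since_anthesis, p) {
  shoot_dm <- pools$dm_lam + pools$dm_sheath + pools$dm_stem + pools$dm_ear +
    pools$dm_grain
  shoot_n <- pools$n_lam + pools$n_sheath + pools$n_stem + pools$n_grain
  st <- nni_status(shoot_dm, shoot_n, p)

  # vertical N profile follows the light profile over relative canopy
  # depth; the N-to-light extinction ratio steepens with crop N status
  # (AlphaKn * NNI^BetaKn), so a well-fed crop concentrates N at the top
  # and the per-area capacity self-limits (stabilizing feedback)
  kappa <- p[["AlphaKn"]] * max(st$nni, 0.05)^p[["BetaKn"]] * p[["Kl"]]
  cap_lam <- p[["MaxSLN"]] * gai_lam * (1 - exp(-kappa)) / max(kappa, 1e-9)
  sln_mean <- if (gai_lam > 1e-9) pools$n_lam / gai_lam else 0
  cap_sh <- gai_sh * p[["AlphaSSN"]] * max(sln_mean, 0)^p[["BetaSSN"]]
  cap_stem <- p[["MaxStemN"]] * (pools$dm_stem + pools$dm_ear)

  def_lam <- max(0, cap_lam - pools$n_lam)
  def_sh <- max(0, cap_sh - pools$n_sheath)
  def_stem <- max(0, cap_stem - pools$n_stem)
  demand <- def_lam + def_sh + def_stem

  decline <- if (tt_since_anthesis <= 0) 1
             else max(0, 1 - tt_since_anthesis / p[["Dgf"]])
  supply_cap <- p[["MaxNuptake"]] *
    min(1, max(shoot_dm, 0) / p[["DMmaxNuptake"]]) * decline
  uptake <- min(demand, soil_mineral_n, supply_cap)

  if (uptake > 0) {
    u <- uptake
    a <- min(u, def_lam); pools$n_lam <- pools$n_lam + a; u <- u - a
    a <- min(u, def_sh); pools$n_sheath <- pools$n_sheath + a; u <- u - a
    pools$n_stem <- pools$n_stem + min(u, def_stem)
  }
  if (tt_since_anthesis > 0)
    pools$post_anth_n_uptake <- pools$post_anth_n_uptake + uptake
  list(pools = pools, uptake = uptake, nni = st$nni, supply_cap = supply_cap)
}

#' One day of grain filling
#'
#' At anthesis the grain number is set to `EarGR` grains per g of ear DM and
#' a small structural seed mass is transferred from the ear. During the
#' endosperm cell-division phase structural grain DM grows exponentially at
#' relative rate `Kcd` per degCd (funded from the day's production, then
#' WSC), with structural grain N `AlphaNC` times structural DM drawn from
#' labile lamina/stem N. After cell division all new biomass goes to the
#' grain together with a reserve pool (fractions `FracLaminaBGR` /
#' `FracSheathBGR` of the anthesis lamina / sheath DM plus the anthesis WSC)
#' released linearly in thermal time until `Dgf`. Grain N transfer follows
#' first-order kinetics in the labile lamina and stem+sheath N pools (rates
#' `MaxLeafRRND`, `MaxStemRRND` per degCd), tapering linearly to zero
#' between the end of endoreduplication and maturity. Lamina N withdrawal
#' additionally senesces green area via the `LLOSS` coupling (applied by
#' the caller through the returned `lam_n_withdrawn`).
#'
#' @param pools `cn_pools`.
#' @param phase One of `"cell_division"`, `"filling"` (post cell-division,
#'   pre maturity).
#' @param tt_since_anthesis degCd since anthesis at end of day.
#' @param daily_tt degCd today.
#' @param daily_new_dm Biomass produced today and not claimed by leaves,
#'   g m-2.
#' @param at_anthesis Logical: is this the anthesis day (sets grain number)?
#' @param p Named parameter set.
#' @return List: updated `pools`, `dm_to_grain`, `lam_n_withdrawn`,
#'   `unused_dm` (production not sunk into grain during cell division, to be
#'   allocated to stem).
#' @export
grain_step <- function(pools, phase, tt_since_anthesis, daily_tt,
                       daily_new_dm, at_anthesis, p) {
  if (at_anthesis) {
    pools$grain_number <- p[["EarGR"]] * pools$dm_ear
    seed <- min(1e-4 * pools$grain_number, pools$dm_ear)  # 0.1 mg per grain
    pools$dm_ear <- pools$dm_ear - seed
    pools$dm_grain <- pools$dm_grain + seed
    pools$grain_struct_dm <- seed
    pools$anth_dm_lam <- pools$dm_lam
    pools$anth_dm_sheath <- pools$dm_sheath
    pools$anth_wsc <- pools$wsc
  }
  lam_n_withdrawn <- 0
  unused <- 0

  if (phase == "cell_division") {
    growth <- pools$grain_struct_dm * expm1(p[["Kcd"]] * daily_tt)
    pay_dm <- min(growth, daily_new_dm)
    pay_wsc <- min(growth - pay_dm, pools$wsc, pools$dm_stem)
    growth <- pay_dm + pay_wsc
    pools$wsc <- pools$wsc - pay_wsc
    pools$dm_stem <- pools$dm_stem - pay_wsc
    pools$dm_grain <- pools$dm_grain + growth
    pools$grain_struct_dm <- pools$grain_struct_dm + growth
    unused <- daily_new_dm - pay_dm
    # structural grain N in fixed ratio to structural DM
    n_need <- p[["AlphaNC"]] * growth
    lab_lam <- max(0, pools$n_lam - p[["StrucLeafN"]] * pools$dm_lam)
    lab_stem <- max(0, pools$n_stem - p[["StrucStemN"]] * pools$dm_stem)
    a <- min(n_need, lab_lam)
    pools$n_lam <- pools$n_lam - a
    lam_n_withdrawn <- a
    b <- min(n_need - a, lab_stem)
    pools$n_stem <- pools$n_stem - b
    pools$n_grain <- pools$n_grain + a + b
    dm_to_grain <- growth
  } else {
    # reserve pool snapshot on entry to the filling phase: fractions of the
    # anthesis lamina / sheath DM plus the labile stem carbohydrate held at
    # the end of the cell-division phase
    if (is.na(pools$reserve_pool)) {
      pools$reserve_pool <- p[["FracLaminaBGR"]] * pools$anth_dm_lam +
        p[["FracSheathBGR"]] * pools$anth_dm_sheath +
        min(pools$wsc, pools$dm_stem)
      pools$reserve_released <- 0
    }
    span <- max(p[["Dgf"]] - p[["Dcd"]], 1e-9)
    target <- pools$reserve_pool * min(1, (tt_since_anthesis - p[["Dcd"]]) / span)
    rel <- max(0, target - pools$reserve_released)
    # debit released reserves from laminae, sheaths and WSC proportionally
    avail <- c(lam = pools$dm_lam, sheath = pools$dm_sheath,
               wsc = min(pools$wsc, pools$dm_stem))
    rel <- min(rel, sum(avail))
    if (rel > 0 && sum(avail) > 0) {
      take <- rel * avail / sum(avail)
      pools$dm_lam <- pools$dm_lam - take[["lam"]]
      pools$dm_sheath <- pools$dm_sheath - take[["sheath"]]
      pools$wsc <- pools$wsc - take[["wsc"]]
      pools$dm_stem <- pools$dm_stem - take[["wsc"]]
      pools$reserve_released <- pools$reserve_released + rel
    }
    dm_to_grain <- daily_new_dm + rel
    pools$dm_grain <- pools$dm_grain + dm_to_grain

    # first-order N transfer with linear taper after endoreduplication
    tt_er <- min(p[["Dcd"]] + p[["Der"]], p[["Dgf"]])
    taper <- if (tt_since_anthesis <= tt_er) 1
             else max(0, (p[["Dgf"]] - tt_since_anthesis) /
                        max(p[["Dgf"]] - tt_er, 1e-9))
    lab_lam <- max(0, pools$n_lam - p[["StrucLeafN"]] * pools$dm_lam)
    lab_stem <- max(0, pools$n_stem - p[["StrucStemN"]] * pools$dm_stem) +
      max(0, pools$n_sheath - p[["StrucStemN"]] * pools$dm_sheath)
    dn_lam <- min(p[["MaxLeafRRND"]] * lab_lam * daily_tt * taper, lab_lam)
    dn_stem_tot <- min(p[["MaxStemRRND"]] * lab_stem * daily_tt * taper, lab_stem)
    # split the stem-rate withdrawal between stem and sheath labile pools
    lab_st <- max(0, pools$n_stem - p[["StrucStemN"]] * pools$dm_stem)
    lab_shh <- max(0, pools$n_sheath - p[["StrucStemN"]] * pools$dm_sheath)
    tot <- lab_st + lab_shh
    dn_st <- if (tot > 0) dn_stem_tot * lab_st / tot else 0
    dn_sh <- dn_stem_tot - dn_st
    pools$n_lam <- pools$n_lam - dn_lam
    pools$n_stem <- pools$n_stem - dn_st
    pools$n_sheath <- pools$n_sheath - dn_sh
    pools$n_grain <- pools$n_grain + dn_lam + dn_stem_tot
    lam_n_withdrawn <- dn_lam
  }
  list(pools = pools, dm_to_grain = dm_to_grain,
       lam_n_withdrawn = lam_n_withdrawn, unused_dm = unused)
}
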