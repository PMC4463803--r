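#' Soil profiles
#'
#' Single-bucket rooted-zone soil description. `awc` is the plant-available
#' water capacity of the profile when fully rooted; the transpirable capacity
#' at any time is `awc * root_depth / max_root_depth` (root-tracking bucket).
#'
#' @param site Label.
#' @param max_root_depth m.
#' @param awc Plant-available water capacity at full rooting depth, mm.
#' @param percolation_coeff Fraction of above-capacity (gravitational) water
#'   draining per day, in \[0, 1\].
#' @param mineralization_k First-order mineralization constant, d-1.
#' @param organic_n Top-soil organic N, g N m-2.
#' @param initial_inorganic_n Root-zone inorganic N at sowing, g N m-2.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(site = "XX", max_root_depth = 1, awc = 150,
                         percolation_coeff = 0.5, mineralization_k = 2e-5,
                         organic_n = 1000, initial_inorganic_n = 4) {
  if (awc <= 0) stop("soil_profile: awc must be > 0")
  if (percolation_coeff < 0 || percolation_coeff > 1)
    stop("soil_profile: percolation_coeff must be in [0, 1]")
  structure(list(site = site, max_root_depth = max_root_depth, awc = awc,
                 percolation_coeff = percolation_coeff,
                 mineralization_k = mineralization_k, organic_n = organic_n,
                 initial_inorganic_n = initial_inorganic_n),
            class = "soil_profile")
}

#' @rdname soil_profile
#' @details `site_soil()` returns the site configurations used throughout:
#'   a sandy profile at AV (awc 80 mm, percolation 0.7), sandy loam at CF
#'   (150 mm, 0.4) and loam at RR (190 mm, 0.3); N characteristics are shared
#'   (mineralization constant 2e-5 d-1, 1000 g m-2 organic N, 4 g m-2
#'   initial inorganic N, 1 m maximum rooting depth).
#' @export
site_soil <- function(site) {
  switch(site,
    AV = soil_profile("AV", 1, 80, 0.7),
    CF = soil_profile("CF", 1, 150, 0.4),
    RR = soil_profile("RR", 1, 190, 0.3),
    stop("site_soil: unknown site '", site, "'"))
}

#' Initial soil state
#'
#' @param profile A [soil_profile()].
#' @param root_depth Initial rooting depth, m.
#' @param wetness Initial wetness fraction of the rooted zone.
#' @return A `soil_state` list: `water` (mm, plant-available plus transient
#'   gravitational water), `mineral_n` (g N m-2), `root_depth` (m),
#'   `drainage_cum` (mm).
#' @export
soil_init <- function(profile, root_depth = 0.05, wetness = 1) {
  cap <- profile$awc * root_depth / profile$max_root_depth
  list(water = wetness * cap, mineral_n = profile$initial_inorganic_n,
       root_depth = root_depth, drainage_cum = 0)
}

rooted_capacity <- function(state, profile) {
  profile$awc * state$root_depth / profile$max_root_depth
}

#' Fraction of transpirable soil water
#'
#' Plant-available water relative to the transpirable capacity of the rooted
#' zone, clipped to \[0, 1\]. With no roots yet (zero capacity) FTSW is
#' defined as 1: no transpiration has occurred pre-emergence.
#'
#' @param state A `soil_state`.
#' @param profile A [soil_profile()].
#' @return Fraction in \[0, 1\].
#' @export
ftsw <- function(state, profile) {
  cap <- rooted_capacity(state, profile)
  if (cap <= 0) return(1)
  min(1, max(0, state$water / cap))
}

#' Piecewise-linear drought response factor
#'
#' 1 at or above `upper`, 0 at or below `lower`, linear in between. Used for
#' the stomatal-conductance, leaf-expansion and biomass-production responses
#' to soil water deficit.
#'
#' @param ftsw_value FTSW, in \[0, 1\] (vectorized).
#' @param upper,lower FTSW thresholds, `upper >= lower`.
#' @return Factor in \[0, 1\].
#' @export
drought_response <- function(ftsw_value, upper, lower) {
  if (upper < lower) stop("drought_response: upper must be >= lower")
  if (upper == lower) return(ifelse(ftsw_value >= upper, 1, 0))
  pmin(1, pmax(0, (ftsw_value - lower) / (upper - lower)))
}

#' Drought acceleration of leaf senescence
#'
#' 1 above `UpperFTSWsen`, `MaxDSF` at or below `LowerFTSWsen`, linear in
#' between.
#'
#' @param ftsw_value FTSW.
#' @param p Named parameter set (uses `MaxDSF`, `UpperFTSWsen`,
#'   `LowerFTSWsen`).
#' @return Acceleration factor in \[1, MaxDSF\].
#' @export
senescence_acceleration <- function(ftsw_value, p) {
  up <- p[["UpperFTSWsen"]]; lo <- p[["LowerFTSWsen"]]
  if (up < lo) stop("senescence_acceleration: UpperFTSWsen < LowerFTSWsen")
  f <- if (up == lo) as.numeric(ftsw_value >= up)
       else pmin(1, pmax(0, (ftsw_value - lo) / (up - lo)))
  1 + (p[["MaxDSF"]] - 1) * (1 - f)
}

#' Daily soil water balance step
#'
#' Inflow enters the bucket; each day a fraction `percolation_coeff` of any
#' water above the rooted-zone capacity drains (the remainder is carried as
#' transient gravitational water). Actual transpiration is the demand scaled
#' by the stomatal drought response and capped by the root extraction limit,
#' soil evaporation is capped by remaining water. The daily balance
#' inflow - transpiration - evaporation - drainage = change in storage closes
#' exactly.
#'
#' @param state `soil_state`.
#' @param profile [soil_profile()].
#' @param inflow Rain plus irrigation, mm.
#' @param transp_demand Transpiration demand, mm.
#' @param evap_demand Soil evaporation demand, mm.
#' @param p Named parameter set (stomatal thresholds `UpperFTSWgs`,
#'   `LowerFTSWgs`; root extraction `MaxRWU`, `BetaRWU`).
#' @return List: updated `state`, `transpiration`, `evaporation`, `drainage`
#'   (all mm).
#' @export
step_water <- function(state, profile, inflow, transp_demand, evap_demand, p) {
  if (inflow < 0 || transp_demand < 0 || evap_demand < 0)
    stop("step_water: negative inputs")
  cap <- rooted_capacity(state, profile)
  w <- state$water + inflow
  surplus <- max(0, w - cap)
  drainage <- profile$percolation_coeff * surplus
  w <- w - drainage

  fgs <- drought_response(min(1, if (cap > 0) max(0, w / cap) else 1),
                          p[["UpperFTSWgs"]], p[["LowerFTSWgs"]])
  # root extraction limit: the root system removes at most the top-layer
  # relative rate MaxRWU per day at full rooting depth; the depth response
  # saturates with the profile-extraction efficiency BetaRWU
  df <- state$root_depth / profile$max_root_depth
  depth_shape <- -expm1(-10 * p[["BetaRWU"]] * df)
  extract_max <- w * p[["MaxRWU"]] * depth_shape
  transp <- min(transp_demand * fgs, extract_max, w)
  w <- w - transp
  evap <- min(evap_demand, w)
  w <- w - evap

  state$water <- w
  state$drainage_cum <- state$drainage_cum + drainage
  list(state = state, transpiration = transp, evaporation = evap,
       drainage = drainage)
}

#' Daily soil mineral-N step
#'
#' Mineralization is first-order in organic N with a linear temperature
#' factor (0 at <= 0 degC, 1 at >= 20 degC); leaching removes a fraction
#' `min(1, drainage / awc)` of the mineral pool; fertilizer is added and crop
#' uptake withdrawn the same day. N is conserved exactly.
#'
#' @param state `soil_state`.
#' @param profile [soil_profile()].
#' @param tmean Daily mean temperature, degC.
#' @param fertilizer Applied fertilizer N, g N m-2.
#' @param crop_uptake Withdrawn by the crop, g N m-2 (must not exceed the
#'   pool after additions).
#' @param drainage Today's drainage, mm.
#' @return List: updated `state`, `mineralization`, `leaching` (g N m-2).
#' @export
step_nitrogen <- function(state, profile, tmean, fertilizer, crop_uptake,
                          drainage) {
  ft <- min(1, max(0, tmean / 20))
  mineralization <- profile$mineralization_k * profile$organic_n * ft
  pool <- state$mineral_n + mineralization + fertilizer
  if (crop_uptake > pool + 1e-12)
    stop("step_nitrogen: uptake exceeds mineral N pool")
  pool <- pool - min(crop_uptake, pool)
  leaching <- pool * min(1, drainage / profile$awc)
  state$mineral_n <- pool - leaching
  list(state = state, mineralization = mineralization, leaching = leaching)
}

#' Daily root vertical extension
#'
#' Roots extend at `RVER` m per degCd, capped at the profile's maximum depth.
#' Newly rooted soil arrives at the rooted zone's current wetness fraction,
#' so FTSW is continuous under root growth; the water added this way is
#' returned so season ledgers can account for it.
#'
#' @param state `soil_state`.
#' @param profile [soil_profile()].
#' @param daily_tt Thermal time today, degCd.
#' @param p Named parameter set (uses `RVER`).
#' @return List: updated `state`, `water_added` (mm entrained with the newly
#'   rooted soil).
#' @export
root_extension <- function(state, profile, daily_tt, p) {
  if (daily_tt < 0) stop("root_extension: thermal time must be >= 0")
  cap0 <- rooted_capacity(state, profile)
  wet <- if (cap0 > 0) min(1, state$water / cap0) else 1
  state$root_depth <- min(profile$max_root_depth,
                          state$root_depth + p[["RVER"]] * daily_tt)
  cap1 <- rooted_capacity(state, profile)
  added <- wet * max(0, cap1 - cap0)
  state$water <- state$water + added
  list(state = state, water_added = added)
}

#' Hargreaves reference evapotranspiration
#'
#' @param tmin,tmax Daily temperature extremes, degC.
#' @param ra Extraterrestrial radiation, MJ m-2 d-1.
#' @return Reference ET, mm d-1 (non-negative).
#' @export
hargreaves_et <- function(tmin, tmax, ra) {
  tmean <- (tmin + tmax) / 2
  pmax(0, 0.0023 * (ra / 2.45) * (tmean + 17.8) * sqrt(pmax(0, tmax - tmin)))
}
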