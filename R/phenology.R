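#' Daily thermal time
#'
#' @param tmean Daily mean (canopy) temperature, degC.
#' @param base Base temperature, degC (0 by convention here).
#' @return degCd accrued today, `max(0, tmean - base)` (vectorized).
#' @export
thermal_time <- function(tmean, base = 0) {
  pmax(0, tmean - base)
}

#' Daily vernalization rate
#'
#' `VBEE + VAI * T` between 0 degC and the intermediate temperature
#' `IntTvern`, declining linearly to 0 at `MaxTvern`, zero outside
#' \[0, MaxTvern\].
#'
#' @param tmean Daily mean temperature, degC (vectorized).
#' @param p Named parameter set.
#' @return Progress fraction per day.
#' @export
vernalization_rate <- function(tmean, p) {
  vbee <- p[["VBEE"]]; vai <- p[["VAI"]]
  tint <- p[["IntTvern"]]; tmax <- p[["MaxTvern"]]
  peak <- vbee + vai * tint
  r <- ifelse(tmean <= tint, vbee + vai * tmean,
              peak * pmax(0, (tmax - tmean)) / max(tmax - tint, 1e-9))
  ifelse(tmean < 0 | tmean > tmax, 0, pmax(0, r))
}

#' Advance vernalization progress by one day
#'
#' @param phen Phenology state (see [phenology_init()]).
#' @param tmean Daily mean temperature, degC.
#' @param p Named parameter set.
#' @return Updated state; `vern` accumulates to 1 and `vern_done` flips once.
#' @export
vernalization_step <- function(phen, tmean, p) {
  if (!phen$vern_done) {
    phen$vern <- phen$vern + vernalization_rate(tmean, p)
    if (phen$vern >= 1) {
      phen$vern <- 1
      phen$vern_done <- TRUE
    }
  }
  phen
}

#' Effective phyllochron multiplier
#'
#' `Pdecr` for leaves below `Ldecr`, `Pincr` above `Lincr`, 1 in between.
#'
#' @param haun Current Haun index (leaves appeared).
#' @param p Named parameter set.
#' @export
phyllochron_factor <- function(haun, p) {
  if (haun < p[["Ldecr"]]) p[["Pdecr"]]
  else if (haun > p[["Lincr"]]) p[["Pincr"]]
  else 1
}

#' Final leaf number
#'
#' Interpolates from the absolute maximum towards the absolute minimum leaf
#' number with the vernalization effect, plus a short-day correction
#' referenced to a 16 h saturating daylength, clipped to
#' \[`MinL`, `MaxL`\]:
#' `FLN = clip(MinL + (MaxL - MinL) * (1 - v_eff) + SLDL * (16 - daylength))`.
#'
#' @param v_eff Vernalization effect in \[0, 1\] (1 = fully vernalized).
#' @param daylength_h Daylength (h) on the day the number is fixed.
#' @param p Named parameter set.
#' @return Final leaf number (real).
#' @export
final_leaf_number <- function(v_eff, daylength_h, p) {
  fln <- p[["MinL"]] + (p[["MaxL"]] - p[["MinL"]]) * (1 - v_eff) +
    p[["SLDL"]] * (16 - daylength_h)
  min(p[["MaxL"]], max(p[["MinL"]], fln))
}

#' Initialize a phenology state
#'
#' State fields: `tt_cum` (degCd since sowing), `clock` (phyllochron clock in
#' leaf units, uncapped), `haun` (= min(clock, FLN)), `vern` / `vern_done`,
#' `vern_at_ref` (progress when the Haun-4 floral reference is reached),
#' `fln` (NA until fixed), `emerged`, event thermal-time stamps and day
#' indices.
#'
#' @return A `phenology_state` list.
#' @export
phenology_init <- function() {
  list(tt_cum = 0, clock = 0, clock_prev = 0, haun = 0, daily_tt = 0,
       vern = 0, vern_done = FALSE, vern_at_ref = NA_real_,
       fln = NA_real_, emerged = FALSE,
       tt_emergence = NA_real_, tt_fll = NA_real_, tt_anthesis = NA_real_,
       day_emergence = NA_integer_, day_floral_init = NA_integer_,
       day_fll = NA_integer_, day_anthesis = NA_integer_,
       day_begin_gf = NA_integer_, day_end_cd = NA_integer_,
       day_end_er = NA_integer_, day_maturity = NA_integer_)
}

#' Advance the leaf-appearance clock
#'
#' The phyllochron clock advances by `daily_tt / (P * f)` where `f` is
#' [phyllochron_factor()]; the Haun index follows the clock but is capped at
#' the final leaf number once that is fixed.
#'
#' @param phen Phenology state (must have emerged).
#' @param daily_tt Thermal time today, degCd.
#' @param p Named parameter set.
#' @return Updated state.
#' @export
leaf_appearance_step <- function(phen, daily_tt, p) {
  f <- phyllochron_factor(phen$haun, p)
  phen$clock_prev <- phen$clock
  phen$clock <- phen$clock + daily_tt / (p[["P"]] * f)
  phen$haun <- if (is.na(phen$fln)) phen$clock else min(phen$clock, phen$fln)
  phen
}

#' One full phenology day
#'
#' Accumulates thermal time, advances vernalization and leaf appearance,
#' fixes the final leaf number once vernalization is complete and the Haun-4
#' floral reference has been passed, and records phase events: emergence at
#' `Dse` degCd after sowing, flag leaf ligule when the Haun index reaches the
#' final leaf number, anthesis `PFLLAnth` phyllochrons later, then the grain
#' phases at `Dcd`, `Dcd + Der` and `Dgf` degCd after anthesis.
#'
#' @param phen Phenology state.
#' @param tmean_canopy Canopy temperature for thermal time, degC.
#' @param tmean_air Air temperature for vernalization, degC.
#' @param daylength_h Today's daylength, h.
#' @param day Day index (1 = sowing day).
#' @param p Named parameter set.
#' @return Updated state with element `daily_tt` for the day.
#' @export
phenology_step <- function(phen, tmean_canopy, tmean_air, daylength_h, day, p) {
  tt <- thermal_time(tmean_canopy)
  phen$tt_cum <- phen$tt_cum + tt
  phen$daily_tt <- tt

  if (!phen$emerged) {
    if (phen$tt_cum >= p[["Dse"]]) {
      phen$emerged <- TRUE
      phen$tt_emergence <- phen$tt_cum
      phen$day_emergence <- day
    }
    return(phen)
  }

  phen <- vernalization_step(phen, tmean_air, p)
  phen <- leaf_appearance_step(phen, tt, p)

  if (is.na(phen$vern_at_ref) && phen$clock >= 4)
    phen$vern_at_ref <- phen$vern

  if (is.na(phen$fln) && phen$vern_done && phen$clock >= 4) {
    v_eff <- min(1, phen$vern_at_ref)
    phen$fln <- final_leaf_number(v_eff, daylength_h, p)
    phen$haun <- min(phen$clock, phen$fln)
  }

  if (!is.na(phen$fln)) {
    if (is.na(phen$day_floral_init) && phen$clock >= phen$fln - p[["NLL"]])
      phen$day_floral_init <- day
    if (is.na(phen$day_fll) && phen$haun >= phen$fln) {
      phen$day_fll <- day
      phen$tt_fll <- phen$tt_cum
    }
  }
  if (!is.na(phen$tt_fll) && is.na(phen$day_anthesis) &&
      phen$tt_cum >= phen$tt_fll + p[["PFLLAnth"]] * p[["P"]]) {
    phen$day_anthesis <- day
    phen$day_begin_gf <- day
    phen$tt_anthesis <- phen$tt_cum
  }
  if (!is.na(phen$tt_anthesis)) {
    since <- phen$tt_cum - phen$tt_anthesis
    if (is.na(phen$day_end_cd) && since >= p[["Dcd"]]) phen$day_end_cd <- day
    if (is.na(phen$day_end_er) && since >= min(p[["Dcd"]] + p[["Der"]], p[["Dgf"]]))
      phen$day_end_er <- day
    if (is.na(phen$day_maturity) && since >= p[["Dgf"]]) phen$day_maturity <- day
  }
  phen
}
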