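// Compiled daily season core. Mirrors the R reference implementation in
// R/phenology.R, R/soil.R, R/canopy.R and R/simulator.R operation for
// operation; the two engines are asserted equal in the test suite. The R
// functions remain the documented, unit-tested definition of each step.
#include <Rcpp.h>
using namespace Rcpp;

enum ParIdx {
  P_Dse = 0, P_MaxL, P_MinL, P_MaxLeafSoil, P_Lincr, P_Ldecr, P_P, P_Pdecr,
  P_Pincr, P_SLDL, P_PFLLAnth, P_IntTvern, P_MaxTvern, P_VAI, P_VBEE,
  P_AreaPL, P_AreaSL, P_AreaSS, P_PexpL, P_PlagLL, P_PlagSL, P_PsenLL,
  P_PsenSL, P_RatioFLPL, P_aSheath, P_NLL, P_Kl, P_FacCO2, P_TauSLN,
  P_SlopeFR, P_RUE, P_Tmax, P_Topt, P_Dcd, P_Der, P_Dgf, P_Kcd, P_AlphaNC,
  P_EarGR, P_Deg, P_SLWp, P_SSWp, P_FracLaminaBGR, P_FracSheathBGR,
  P_FracStemWSC, P_FracBEAR, P_LLOSS, P_CritSLN, P_MaxSLN, P_MinSLN,
  P_StrucLeafN, P_MaxStemN, P_StrucStemN, P_AlphaKn, P_AlphaSSN, P_AlphaNNI,
  P_BetaKn, P_BetaSSN, P_BetaNNI, P_MaxLeafRRND, P_MaxStemRRND,
  P_DMmaxNuptake, P_MaxRWU, P_MaxNuptake, P_RVER, P_BetaRWU, P_MaxDSF,
  P_LowerFTSWexp, P_LowerFTSWgs, P_LowerFTSWrue, P_LowerFTSWsen,
  P_UpperFTSWexp, P_UpperFTSWgs, P_UpperFTSWrue, P_UpperFTSWsen
};

static const int MAXL = 32;  // layer array capacity

static inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

static inline double drought(double f, double up, double lo) {
  if (up == lo) return f >= up ? 1.0 : 0.0;
  return clamp01((f - lo) / (up - lo));
}

// [[Rcpp::export(name = ".season_core")]]
List season_core(NumericVector par, NumericVector tmean, NumericVector srad,
                 NumericVector rain, NumericVector pet, NumericVector dl,
                 NumericVector fdif, double awc, double max_root_depth,
                 double perc, double miner_k, double organic_n,
                 double init_inorganic, NumericVector fert_amt,
                 NumericVector irr_amt, double sow_irr, double co2,
                 double shoots) {
  const int n_days = tmean.size();
  double p[75];
  for (int i = 0; i < 75; i++) p[i] = par[i];
  if (p[P_CritSLN] > p[P_MaxSLN]) p[P_CritSLN] = p[P_MaxSLN];
  const double scale = shoots * 1e-4;

  // phenology state
  double tt_cum = 0, clock = 0, clock_prev = 0, haun = 0, vern = 0;
  bool vern_done = false, emerged = false;
  double vern_at_ref = -1, fln = -1;
  double tt_fll = -1, tt_anthesis = -1;
  int day_emergence = -1, day_floral_init = -1, day_fll = -1,
      day_anthesis = -1, day_end_cd = -1, day_end_er = -1, day_maturity = -1;

  // soil state
  double root_depth = 0.05;
  double cap0 = awc * root_depth / max_root_depth;
  double water = cap0, mineral_n = init_inorganic;

  // canopy (provisional pre-floral geometry for the first 8 ranks)
  int ncan = 8;
  bool built = false;
  double fi_rank = -1;
  double lam_pot[MAXL], sh_pot[MAXL], lag[MAXL], sen[MAXL];
  double a_exp_lam[MAXL], a_sen_lam[MAXL], a_exp_sh[MAXL], a_sen_sh[MAXL];
  for (int i = 0; i < MAXL; i++) {
    lam_pot[i] = p[P_AreaSL] * scale; sh_pot[i] = p[P_AreaSS] * scale;
    lag[i] = p[P_PlagSL]; sen[i] = p[P_PsenSL];
    a_exp_lam[i] = a_sen_lam[i] = a_exp_sh[i] = a_sen_sh[i] = 0;
  }

  // pools
  double dm_lam = 0, dm_sheath = 0, dm_stem = 0, dm_ear = 0, dm_grain = 0,
         dm_dead = 0, wsc = 0, seed_dm = 10;
  double n_lam = 0.15, n_sheath = 0, n_stem = 0, n_grain = 0, n_dead = 0;
  double post_anth_n = 0, grain_number = 0, grain_struct = 0;
  double reserve_pool = -1, reserve_released = 0;
  double anth_dm_lam = 0, anth_dm_sheath = 0;
  const double seed_n0 = n_lam, seed_dm_tot = seed_dm;

  bool fired[5] = {false, false, false, false, false};

  double water_in = 0, water_out = 0, n_in = 0, n_out_leach = 0,
         uptake_cum = 0, dm_prod_cum = 0, seed_dm_used = 0;
  const double soil_water0 = water, soil_n0 = mineral_n;

  double gai = 0, gai_lam = 0, gai_sh = 0, gai_anthesis = NA_REAL;
  bool anth_done = false;

  for (int d = 0; d < n_days; d++) {
    double t_air = tmean[d];
    double t_can = t_air;
    if (haun < p[P_MaxLeafSoil]) {
      int j0 = d - 4 < 0 ? 0 : d - 4;
      double s = 0; int c = 0;
      for (int j = j0; j <= d; j++) { s += tmean[j]; c++; }
      t_can = s / c;
    }

    // ---- phenology step ----
    double tt = t_can > 0 ? t_can : 0;
    tt_cum += tt;
    if (!emerged) {
      if (tt_cum >= p[P_Dse]) { emerged = true; day_emergence = d + 1; }
    } else {
      if (!vern_done) {
        double r;
        double peak = p[P_VBEE] + p[P_VAI] * p[P_IntTvern];
        if (t_air < 0 || t_air > p[P_MaxTvern]) r = 0;
        else if (t_air <= p[P_IntTvern]) r = p[P_VBEE] + p[P_VAI] * t_air;
        else {
          double den = p[P_MaxTvern] - p[P_IntTvern];
          if (den < 1e-9) den = 1e-9;
          r = peak * (p[P_MaxTvern] - t_air) / den;
          if (r < 0) r = 0;
        }
        vern += r;
        if (vern >= 1) { vern = 1; vern_done = true; }
      }
      double f = (haun < p[P_Ldecr]) ? p[P_Pdecr]
                 : (haun > p[P_Lincr] ? p[P_Pincr] : 1.0);
      clock_prev = clock;
      clock += tt / (p[P_P] * f);
      haun = (fln < 0) ? clock : (clock < fln ? clock : fln);

      if (vern_at_ref < 0 && clock >= 4) vern_at_ref = vern;
      if (fln < 0 && vern_done && clock >= 4) {
        double v_eff = vern_at_ref < 1 ? vern_at_ref : 1;
        double fl = p[P_MinL] + (p[P_MaxL] - p[P_MinL]) * (1 - v_eff) +
          p[P_SLDL] * (16 - dl[d]);
        if (fl < p[P_MinL]) fl = p[P_MinL];
        if (fl > p[P_MaxL]) fl = p[P_MaxL];
        fln = fl;
        haun = clock < fln ? clock : fln;
      }
      if (fln > 0) {
        if (day_floral_init < 0 && clock >= fln - p[P_NLL])
          day_floral_init = d + 1;
        if (day_fll < 0 && haun >= fln) { day_fll = d + 1; tt_fll = tt_cum; }
      }
      if (tt_fll >= 0 && day_anthesis < 0 &&
          tt_cum >= tt_fll + p[P_PFLLAnth] * p[P_P]) {
        day_anthesis = d + 1;
        tt_anthesis = tt_cum;
      }
      if (tt_anthesis >= 0) {
        double since = tt_cum - tt_anthesis;
        double er = p[P_Dcd] + p[P_Der];
        if (er > p[P_Dgf]) er = p[P_Dgf];
        if (day_end_cd < 0 && since >= p[P_Dcd]) day_end_cd = d + 1;
        if (day_end_er < 0 && since >= er) day_end_er = d + 1;
        if (day_maturity < 0 && since >= p[P_Dgf]) day_maturity = d + 1;
      }
    }
    if (day_maturity > 0) break;  // filling stops at maturity

    // ---- install final canopy geometry when FLN is fixed ----
    if (!built && fln > 0) {
      double fr = fln - p[P_NLL];
      if (fr < 1) return List::create(Named("error") = "degenerate canopy");
      int n = (int)std::ceil(fln);
      if (n > MAXL) n = MAXL;
      double denom = (n - 1) - fr;
      if (denom < 1e-9) denom = 1e-9;
      for (int i = 0; i < n; i++) {
        double rank = i + 1;
        bool started = a_exp_lam[i] > 0;
        if (started || rank <= fr) continue;  // keep provisional geometry
        double j = rank - fr;
        double w = j < 1 ? j : 1;
        double rmp;
        if (i == n - 1) rmp = p[P_RatioFLPL] * p[P_AreaPL];
        else {
          double t = j / denom; if (t > 1) t = 1;
          rmp = p[P_AreaSL] + (p[P_AreaPL] - p[P_AreaSL]) * t;
        }
        double shc = p[P_AreaSS] *
          (1 + p[P_aSheath] * (j / p[P_NLL]) * (j / p[P_NLL]));
        lam_pot[i] = ((1 - w) * p[P_AreaSL] + w * rmp) * scale;
        sh_pot[i] = ((1 - w) * p[P_AreaSS] + w * shc) * scale;
        lag[i] = (1 - w) * p[P_PlagSL] + w * p[P_PlagLL];
        sen[i] = (1 - w) * p[P_PsenSL] + w * p[P_PsenLL];
      }
      ncan = n;
      fi_rank = fr;
      built = true;
    }

    // ---- management triggers ----
    double irrigation = (d == 0) ? sow_irr : 0;
    double fertilizer = 0;
    bool reached[5];
    reached[0] = clock >= 3;                                      // GS21
    reached[1] = day_floral_init > 0;                             // GS30
    reached[2] = fln > 0 &&
      clock >= std::floor(fln - p[P_NLL]) + 1 - p[P_PexpL];       // GS31
    reached[3] = fln > 0 && haun >= fln - 1;                      // GS37
    reached[4] = day_anthesis > 0;                                // GS65
    for (int s = 0; s < 5; s++) {
      if (reached[s] && !fired[s]) {
        fired[s] = true;
        fertilizer += fert_amt[s];
        irrigation += irr_amt[s];
      }
    }

    // ---- root extension ----
    if (emerged) {
      double c0 = awc * root_depth / max_root_depth;
      double wet = c0 > 0 ? (water / c0 < 1 ? water / c0 : 1) : 1;
      root_depth += p[P_RVER] * tt;
      if (root_depth > max_root_depth) root_depth = max_root_depth;
      double c1 = awc * root_depth / max_root_depth;
      double added = wet * (c1 > c0 ? c1 - c0 : 0);
      water += added;
      water_in += added;
    }

    // ---- water balance ----
    double cap = awc * root_depth / max_root_depth;
    double cover = 1 - std::exp(-p[P_Kl] * gai);
    double transp_demand = pet[d] * cover;
    double ftsw_pre = cap > 0 ? clamp01(water / cap) : 1;
    double evap_demand = 0.6 * pet[d] * (1 - cover) *
      (3 * ftsw_pre < 1 ? 3 * ftsw_pre : 1);
    double inflow = rain[d] + irrigation;
    double w = water + inflow;
    double surplus = w - cap > 0 ? w - cap : 0;
    double drainage = perc * surplus;
    w -= drainage;
    double fgs = drought(cap > 0 ? clamp01(w / cap) : 1,
                         p[P_UpperFTSWgs], p[P_LowerFTSWgs]);
    double dfrac = root_depth / max_root_depth;
    double depth_shape = -std::expm1(-10 * p[P_BetaRWU] * dfrac);
    double extract_max = w * p[P_MaxRWU] * depth_shape;
    double transp = transp_demand * fgs;
    if (transp > extract_max) transp = extract_max;
    if (transp > w) transp = w;
    w -= transp;
    double evap = evap_demand < w ? evap_demand : w;
    w -= evap;
    water = w;
    water_in += inflow;
    water_out += transp + evap + drainage;
    double ftsw_d = cap > 0 ? clamp01(water / cap) : 1;

    double uptake = 0;
    if (emerged) {
      double f_exp = drought(ftsw_d, p[P_UpperFTSWexp], p[P_LowerFTSWexp]);
      double fsen = (p[P_UpperFTSWsen] == p[P_LowerFTSWsen])
        ? (ftsw_d >= p[P_UpperFTSWsen] ? 1.0 : 0.0)
        : clamp01((ftsw_d - p[P_LowerFTSWsen]) /
                  (p[P_UpperFTSWsen] - p[P_LowerFTSWsen]));
      double accel = 1 + (p[P_MaxDSF] - 1) * (1 - fsen);

      // production from yesterday's canopy
      double ipar = 0.5 * srad[d] * cover;
      double sln_mean = gai_lam > 1e-9 ? n_lam / gai_lam : p[P_MaxSLN];
      double topt = p[P_Topt], tmx = p[P_Tmax];
      if (topt >= tmx) topt = tmx - 1e-6;
      double ft = (t_air <= 0 || t_air >= tmx) ? 0
        : (t_air <= topt ? t_air / topt : (tmx - t_air) / (tmx - topt));
      double fco2 = 1 + p[P_FacCO2] * std::log(co2 / 350);
      double span = p[P_MaxSLN] - p[P_MinSLN];
      if (span < 1e-9) span = 1e-9;
      double fn = (1 - std::exp(-p[P_TauSLN] * (sln_mean - p[P_MinSLN]))) /
                  (1 - std::exp(-p[P_TauSLN] * span));
      fn = clamp01(fn);
      double fr = (1 + p[P_SlopeFR] * fdif[d]) / (1 + p[P_SlopeFR]);
      double fw = drought(ftsw_d, p[P_UpperFTSWrue], p[P_LowerFTSWrue]);
      double daily_dm = p[P_RUE] * ft * fco2 * fn * fr * fw * ipar;
      dm_prod_cum += daily_dm;

      double since_anth = anth_done ? tt_cum - tt_anthesis : -1;

      double decline = since_anth <= 0 ? 1
        : (1 - since_anth / p[P_Dgf] > 0 ? 1 - since_anth / p[P_Dgf] : 0);
      double crop_dm_tot = dm_lam + dm_sheath + dm_stem + dm_ear + dm_grain;
      double sup = p[P_MaxNuptake] *
        (crop_dm_tot / p[P_DMmaxNuptake] < 1 ?
           crop_dm_tot / p[P_DMmaxNuptake] : 1) * decline;
      double lab_ex = n_lam - p[P_CritSLN] * gai_lam;
      if (lab_ex < 0) lab_ex = 0;
      double n_for_exp = (mineral_n < sup ? mineral_n : sup) + lab_ex;
      double max_area_n = n_for_exp / p[P_CritSLN];

      // ---- canopy step (development-driven; DM booked afterwards) ----
      double texp = p[P_PexpL];
      double d_lam_s = 0, d_sh_s = 0;
      double dl_i[MAXL], ds_i[MAXL];
      for (int i = 0; i < ncan; i++) {
        double rank = i + 1;
        double hi = clock < rank ? clock : rank;
        double lo = clock_prev > rank - texp ? clock_prev : rank - texp;
        double win = hi - lo > 0 ? hi - lo : 0;
        dl_i[i] = lam_pot[i] * win / texp * f_exp;
        ds_i[i] = sh_pot[i] * win / texp * f_exp;
        d_lam_s += dl_i[i];
        d_sh_s += ds_i[i];
      }
      if (d_lam_s > max_area_n && d_lam_s > 0) {
        double f = (max_area_n > 0 ? max_area_n : 0) / d_lam_s;
        for (int i = 0; i < ncan; i++) { dl_i[i] *= f; ds_i[i] *= f; }
        d_lam_s *= f; d_sh_s *= f;
      }
      double demand = d_lam_s * p[P_SLWp] + d_sh_s * p[P_SSWp];
      double sen_lam_s = 0, sen_sh_s = 0;
      for (int i = 0; i < ncan; i++) {
        a_exp_lam[i] += dl_i[i];
        a_exp_sh[i] += ds_i[i];
        double rank = i + 1;
        double st = rank + lag[i];
        double lo = clock_prev > st ? clock_prev : st;
        double dsc = clock - lo > 0 ? clock - lo : 0;
        double rate = dsc * accel / sen[i];
        double sl = a_exp_lam[i] * rate;
        double cap_l = a_exp_lam[i] - a_sen_lam[i];
        if (sl > cap_l) sl = cap_l;
        double ss = a_exp_sh[i] * rate;
        double cap_s = a_exp_sh[i] - a_sen_sh[i];
        if (ss > cap_s) ss = cap_s;
        a_sen_lam[i] += sl; a_sen_sh[i] += ss;
        sen_lam_s += sl; sen_sh_s += ss;
      }
      double wsc_avail = wsc < dm_stem ? wsc : dm_stem;
      double supply = anth_done ? 0 : daily_dm + seed_dm + wsc_avail;
      double paid = demand < supply ? demand : supply;
      double from_prod = paid < (anth_done ? 0 : daily_dm)
        ? paid : (anth_done ? 0 : daily_dm);
      double seed_draw = paid - from_prod < seed_dm
        ? paid - from_prod : seed_dm;
      if (seed_draw < 0) seed_draw = 0;
      double wsc_draw = paid - from_prod - seed_draw;
      if (wsc_draw < 0) wsc_draw = 0;
      seed_dm -= seed_draw;
      seed_dm_used += seed_draw;
      wsc -= wsc_draw;
      dm_stem -= wsc_draw;
      double lam_cost = d_lam_s * p[P_SLWp];
      double sh_cost = d_sh_s * p[P_SSWp];
      double lam_share = lam_cost + sh_cost > 0
        ? lam_cost / (lam_cost + sh_cost) : 0;

      // senesced tissue to dead pools
      double dead_lam = sen_lam_s * p[P_SLWp];
      if (dead_lam > dm_lam) dead_lam = dm_lam;
      double dead_sh = sen_sh_s * p[P_SSWp];
      if (dead_sh > dm_sheath) dead_sh = dm_sheath;
      double dn_l = p[P_StrucLeafN] * dead_lam;
      if (dn_l > n_lam) dn_l = n_lam;
      double dn_s = p[P_StrucStemN] * dead_sh;
      if (dn_s > n_sheath) dn_s = n_sheath;
      dm_lam -= dead_lam; dm_sheath -= dead_sh;
      dm_dead += dead_lam + dead_sh;
      n_lam -= dn_l; n_sheath -= dn_s; n_dead += dn_l + dn_s;

      bool at_anth = !anth_done && day_anthesis > 0;
      if (!anth_done) {
        // allocate the day's biomass
        double total = daily_dm + seed_draw + wsc_draw;
        double dm_leaf = paid * lam_share;
        double dm_sh = paid * (1 - lam_share);
        double rest = total - dm_leaf - dm_sh;
        if (rest < 0) rest = 0;
        dm_lam += dm_leaf;
        dm_sheath += dm_sh;
        bool in_ear = tt_fll >= 0 &&
          tt_cum >= tt_fll + p[P_Deg] * p[P_PFLLAnth] * p[P_P];
        double ear = in_ear ? p[P_FracBEAR] * rest : 0;
        double stem = rest - ear;
        dm_ear += ear;
        dm_stem += stem;
        wsc += p[P_FracStemWSC] * stem;
      }
      if (at_anth) {
        anth_done = true;
        gai_anthesis = 0;
        for (int i = 0; i < ncan; i++)
          gai_anthesis += (a_exp_lam[i] - a_sen_lam[i]) +
                          (a_exp_sh[i] - a_sen_sh[i]);
      }
      if (anth_done && day_maturity < 0) {
        since_anth = tt_cum - tt_anthesis;
        bool cell_div = since_anth <= p[P_Dcd];
        double new_dm = at_anth ? 0 : daily_dm;
        double lam_n_withdrawn = 0;

        if (at_anth) {
          grain_number = p[P_EarGR] * dm_ear;
          double seed = 1e-4 * grain_number;
          if (seed > dm_ear) seed = dm_ear;
          dm_ear -= seed; dm_grain += seed; grain_struct = seed;
          anth_dm_lam = dm_lam; anth_dm_sheath = dm_sheath;
        }
        if (cell_div) {
          double growth = grain_struct * std::expm1(p[P_Kcd] * tt);
          double pay_dm = growth < new_dm ? growth : new_dm;
          double pay_wsc = growth - pay_dm;
          if (pay_wsc > wsc) pay_wsc = wsc;
          if (pay_wsc > dm_stem) pay_wsc = dm_stem;
          growth = pay_dm + pay_wsc;
          wsc -= pay_wsc; dm_stem -= pay_wsc;
          dm_grain += growth; grain_struct += growth;
          double unused = new_dm - pay_dm;
          double n_need = p[P_AlphaNC] * growth;
          double lab_lam = n_lam - p[P_StrucLeafN] * dm_lam;
          if (lab_lam < 0) lab_lam = 0;
          double lab_stem = n_stem - p[P_StrucStemN] * dm_stem;
          if (lab_stem < 0) lab_stem = 0;
          double a = n_need < lab_lam ? n_need : lab_lam;
          n_lam -= a; lam_n_withdrawn = a;
          double b = n_need - a < lab_stem ? n_need - a : lab_stem;
          n_stem -= b;
          n_grain += a + b;
          if (unused > 0) {  // banks as labile stem carbohydrate
            dm_stem += unused;
            wsc += unused;
          }
        } else {
          if (reserve_pool < 0) {
            reserve_pool = p[P_FracLaminaBGR] * anth_dm_lam +
              p[P_FracSheathBGR] * anth_dm_sheath +
              (wsc < dm_stem ? wsc : dm_stem);
            reserve_released = 0;
          }
          double span2 = p[P_Dgf] - p[P_Dcd];
          if (span2 < 1e-9) span2 = 1e-9;
          double frac = (since_anth - p[P_Dcd]) / span2;
          if (frac > 1) frac = 1;
          double target = reserve_pool * frac;
          double rel = target - reserve_released;
          if (rel < 0) rel = 0;
          double av_l = dm_lam, av_s = dm_sheath,
                 av_w = wsc < dm_stem ? wsc : dm_stem;
          double av = av_l + av_s + av_w;
          if (rel > av) rel = av;
          if (rel > 0 && av > 0) {
            double tl = rel * av_l / av, ts = rel * av_s / av,
                   tw = rel * av_w / av;
            dm_lam -= tl; dm_sheath -= ts; wsc -= tw; dm_stem -= tw;
            reserve_released += rel;
          }
          dm_grain += new_dm + rel;

          double tt_er = p[P_Dcd] + p[P_Der];
          if (tt_er > p[P_Dgf]) tt_er = p[P_Dgf];
          double taper = 1;
          if (since_anth > tt_er) {
            double den = p[P_Dgf] - tt_er;
            if (den < 1e-9) den = 1e-9;
            taper = (p[P_Dgf] - since_anth) / den;
            if (taper < 0) taper = 0;
          }
          double lab_lam = n_lam - p[P_StrucLeafN] * dm_lam;
          if (lab_lam < 0) lab_lam = 0;
          double lab_st = n_stem - p[P_StrucStemN] * dm_stem;
          if (lab_st < 0) lab_st = 0;
          double lab_sh = n_sheath - p[P_StrucStemN] * dm_sheath;
          if (lab_sh < 0) lab_sh = 0;
          double lab_stem_tot = lab_st + lab_sh;
          double dn_lam2 = p[P_MaxLeafRRND] * lab_lam * tt * taper;
          if (dn_lam2 > lab_lam) dn_lam2 = lab_lam;
          double dn_stem_tot = p[P_MaxStemRRND] * lab_stem_tot * tt * taper;
          if (dn_stem_tot > lab_stem_tot) dn_stem_tot = lab_stem_tot;
          double dn_st = lab_stem_tot > 0
            ? dn_stem_tot * lab_st / lab_stem_tot : 0;
          double dn_sh2 = dn_stem_tot - dn_st;
          n_lam -= dn_lam2; n_stem -= dn_st; n_sheath -= dn_sh2;
          n_grain += dn_lam2 + dn_stem_tot;
          lam_n_withdrawn = dn_lam2;
        }

        // LLOSS coupling
        double glam = 0;
        for (int i = 0; i < ncan; i++) glam += a_exp_lam[i] - a_sen_lam[i];
        if (lam_n_withdrawn > 0 && glam > 1e-9) {
          double sln = n_lam / glam;
          if (sln < 0.2) sln = 0.2;
          double extra = p[P_LLOSS] * lam_n_withdrawn / sln;
          if (extra > glam) extra = glam;
          if (extra > 0) {
            for (int i = 0; i < ncan; i++) {
              double green = a_exp_lam[i] - a_sen_lam[i];
              a_sen_lam[i] += extra * green / glam;
            }
            double dead = extra * p[P_SLWp];
            if (dead > dm_lam) dead = dm_lam;
            double dn = p[P_StrucLeafN] * dead;
            if (dn > n_lam) dn = n_lam;
            dm_lam -= dead; dm_dead += dead;
            n_lam -= dn; n_dead += dn;
          }
        }
      }

      // ---- N uptake ----
      gai_lam = 0; gai_sh = 0;
      for (int i = 0; i < ncan; i++) {
        gai_lam += a_exp_lam[i] - a_sen_lam[i];
        gai_sh += a_exp_sh[i] - a_sen_sh[i];
      }
      gai = gai_lam + gai_sh;
      {
        double shoot_dm = dm_lam + dm_sheath + dm_stem + dm_ear + dm_grain;
        double shoot_n = n_lam + n_sheath + n_stem + n_grain;
        double sdm = shoot_dm > 1e-9 ? shoot_dm : 1e-9;
        double dm_t = sdm / 100;
        double ncrit = dm_t <= 1 ? p[P_AlphaNNI]
          : p[P_AlphaNNI] * std::pow(dm_t, -p[P_BetaNNI]);
        double nact = 100 * shoot_n / sdm;
        double nni = ncrit > 0 ? nact / ncrit : 1;
        double nni_c = nni > 0.05 ? nni : 0.05;
        double kappa = p[P_AlphaKn] * std::pow(nni_c, p[P_BetaKn]) * p[P_Kl];
        double kap_c = kappa > 1e-9 ? kappa : 1e-9;
        double cap_lam = p[P_MaxSLN] * gai_lam *
          (1 - std::exp(-kappa)) / kap_c;
        double slm = gai_lam > 1e-9 ? n_lam / gai_lam : 0;
        if (slm < 0) slm = 0;
        double cap_sh2 = gai_sh * p[P_AlphaSSN] *
          std::pow(slm, p[P_BetaSSN]);
        double cap_stem = p[P_MaxStemN] * (dm_stem + dm_ear);
        double def_lam = cap_lam - n_lam; if (def_lam < 0) def_lam = 0;
        double def_sh = cap_sh2 - n_sheath; if (def_sh < 0) def_sh = 0;
        double def_stem = cap_stem - n_stem; if (def_stem < 0) def_stem = 0;
        double dem = def_lam + def_sh + def_stem;
        double since2 = anth_done ? tt_cum - tt_anthesis : -1;
        double decline2 = since2 <= 0 ? 1
          : (1 - since2 / p[P_Dgf] > 0 ? 1 - since2 / p[P_Dgf] : 0);
        double sup2 = p[P_MaxNuptake] *
          (shoot_dm / p[P_DMmaxNuptake] < 1 ?
             (shoot_dm > 0 ? shoot_dm : 0) / p[P_DMmaxNuptake] : 1) *
          decline2;
        uptake = dem;
        if (uptake > mineral_n) uptake = mineral_n;
        if (uptake > sup2) uptake = sup2;
        if (uptake > 0) {
          double u = uptake;
          double a = u < def_lam ? u : def_lam; n_lam += a; u -= a;
          double b = u < def_sh ? u : def_sh; n_sheath += b; u -= b;
          n_stem += (u < def_stem ? u : def_stem);
        }
        if (since2 > 0) post_anth_n += uptake;
        uptake_cum += uptake;
      }
    }

    // ---- soil N balance ----
    {
      double ftm = t_air / 20;
      ftm = clamp01(ftm);
      double mineralization = miner_k * organic_n * ftm;
      double pool = mineral_n + mineralization + fertilizer;
      double upt = uptake < pool ? uptake : pool;
      pool -= upt;
      double lfrac = drainage / awc;
      if (lfrac > 1) lfrac = 1;
      double leaching = pool * lfrac;
      mineral_n = pool - leaching;
      n_in += mineralization + fertilizer;
      n_out_leach += leaching;
    }
  }

  double crop_dm = dm_lam + dm_sheath + dm_stem + dm_ear + dm_grain + dm_dead;
  double crop_n = n_lam + n_sheath + n_stem + n_grain + n_dead;
  bool completed = day_maturity > 0;
  return List::create(
    Named("anthesis_day") = day_anthesis > 0 ? day_anthesis : NA_INTEGER,
    Named("gai_anthesis") = gai_anthesis,
    Named("crop_dm_maturity") = crop_dm,
    Named("crop_n_maturity") = crop_n,
    Named("grain_dm_maturity") = dm_grain,
    Named("grain_n_maturity") = n_grain,
    Named("post_anthesis_n_uptake") = post_anth_n,
    Named("gpc") = dm_grain > 0 ? 100 * 5.7 * n_grain / dm_grain : NA_REAL,
    Named("grain_number") = grain_number,
    Named("completed") = completed,
    Named("day_emergence") = day_emergence,
    Named("day_floral_init") = day_floral_init,
    Named("day_fll") = day_fll,
    Named("day_end_cd") = day_end_cd,
    Named("day_end_er") = day_end_er,
    Named("day_maturity") = day_maturity,
    Named("fln") = fln > 0 ? fln : NA_REAL,
    Named("ledger") = List::create(
      Named("water_residual") = (water - soil_water0) - (water_in - water_out),
      Named("water_throughput") = water_in + water_out,
      Named("c_residual") = crop_dm - dm_prod_cum - seed_dm_used,
      Named("dm_produced") = dm_prod_cum,
      Named("soil_n_residual") = (mineral_n - soil_n0) -
        (n_in - n_out_leach - uptake_cum),
      Named("n_throughput") = n_in + n_out_leach + uptake_cum,
      Named("crop_n_residual") = crop_n - uptake_cum - seed_n0,
      Named("uptake_cum") = uptake_cum));
}
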