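#' Evaluate a design of unit-cube parameter vectors in one scenario-year
#'
#' Maps each row through the multiplicative perturbation rule and runs one
#' crop season, returning the eight per-run outputs (grain protein deviation
#' is added later, per scenario-year, by regression across runs).
#'
#' @param points Matrix of unit-cube rows, columns named by parameter.
#' @param weather Site weather series.
#' @param site,n_treatment,season Scenario coordinates.
#' @param start_year First calendar year of the weather series.
#' @param spec Perturbation specification.
#' @param base Base parameter set.
#' @return Matrix `nrow(points) x 8` with columns `anthesis`, `gai`,
#'   `crop_dm`, `crop_n`, `grain_dm`, `grain_n`, `post_n`, `gpc`; rows of
#'   incomplete seasons are NA.
#' @export
evaluate_design <- function(points, weather, site, n_treatment, season,
                            start_year = 1970L, spec = perturbation_spec(),
                            base = nominal_parameters()) {
  out <- matrix(NA_real_, nrow(points), 8,
                dimnames = list(NULL, c("anthesis", "gai", "crop_dm",
                                        "crop_n", "grain_dm", "grain_n",
                                        "post_n", "gpc")))
  sow <- as.Date(sprintf("%d-%s", start_year + season - 1L,
                         site_sowing_date(site)))
  soil <- site_soil(site)
  mgmt <- management_plan(n_treatment)
  for (r in seq_len(nrow(points))) {
    p <- rescale_unit_vector(base, points[r, ], spec)
    res <- tryCatch(run_season(p, weather, soil, mgmt, sow),
                    error = function(e) NULL)
    if (!is.null(res) && res$completed)
      out[r, ] <- c(res$anthesis_day, res$gai_anthesis, res$crop_dm_maturity,
                    res$crop_n_maturity, res$grain_dm_maturity,
                    res$grain_n_maturity, res$post_anthesis_n_uptake,
                    res$gpc)
  }
  out
}

#' Grain protein deviation
#'
#' The residual of grain protein concentration from its ordinary
#' least-squares regression on grain yield across the parameter vectors
#' ("genotypes") of one scenario-year. With no yield variance the residuals
#' degrade to centred GPC and the slope is flagged undefined.
#'
#' @param gpc Grain protein concentrations, percent of grain DM.
#' @param gy Grain yields, kg DM m-2.
#' @return List: `residuals`, `slope` (percent per kg m-2), `intercept`,
#'   `r2`, `p_value`, `significant` (F-test p < 0.05), `slope_defined`.
#' @export
grain_protein_deviation <- function(gpc, gy) {
  ok <- is.finite(gpc) & is.finite(gy)
  if (sum(ok) < 3) stop("grain_protein_deviation: need >= 3 finite pairs")
  res <- rep(NA_real_, length(gpc))
  if (stats::var(gy[ok]) <= 0) {
    res[ok] <- gpc[ok] - mean(gpc[ok])
    return(list(residuals = res, slope = NA_real_, intercept = NA_real_,
                r2 = NA_real_, p_value = NA_real_, significant = FALSE,
                slope_defined = FALSE))
  }
  fit <- stats::lm(gpc[ok] ~ gy[ok])
  res[ok] <- stats::residuals(fit)
  sm <- summary(fit)
  pval <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
  list(residuals = res, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = sm$r.squared,
       p_value = unname(pval), significant = is.finite(pval) && pval < 0.05,
       slope_defined = TRUE)
}

output_names <- function() {
  c("anthesis", "gai", "crop_dm", "crop_n", "grain_dm", "grain_n",
    "post_n", "gpc", "gpd")
}

add_gpd <- function(y) {
  gpd <- rep(NA_real_, nrow(y))
  ok <- is.finite(y[, "gpc"]) & is.finite(y[, "grain_dm"])
  if (sum(ok) >= 3)
    gpd <- grain_protein_deviation(y[, "gpc"], y[, "grain_dm"] / 1000)$residuals
  cbind(y, gpd = gpd)
}

#' Morris screening over the site x N x year experiment matrix
#'
#' Generates one trajectory design over the named factors, evaluates it in
#' every scenario-year (with grain protein deviation appended per
#' scenario-year) and returns tidy per-factor statistics. With `store_dir`
#' set, each scenario-year shard is written to CSV and skipped when already
#' present (resumability).
#'
#' @param factors Factor names (default all 75).
#' @param sites,n_treatments,years Experiment matrix (years is a count).
#' @param r,p_levels Morris design size.
#' @param seed Seed for the design and the site weather.
#' @param store_dir Optional shard directory.
#' @param start_year First weather year.
#' @return List: `stats` (tidy data.frame factor x site x N x year x output
#'   with mu_star, sigma, mu), `design`, `gpd` (per scenario-year regression
#'   summaries), `incomplete` (count of failed runs per scenario-year).
#' @export
morris_experiment <- function(factors = parameter_table()$name,
                              sites = c("AV", "CF", "RR"),
                              n_treatments = c("HN", "LN"),
                              years = 10, r = 10, p_levels = 8, seed = 1L,
                              store_dir = NULL, start_year = 1970L) {
  design <- sample_trajectories(factors, p = p_levels, r = r,
                                seed = derive_seed(seed, 101))
  stats_rows <- list()
  gpd_rows <- list()
  inc_rows <- list()
  for (site in sites) {
    weather <- generate_weather(site_preset(site, seed = derive_seed(seed, site_salt(site))),
                                years + 1, start_year)
    for (ntr in n_treatments) {
      for (season in seq_len(years)) {
        shard <- shard_path(store_dir, "morris", site, ntr, season)
        if (!is.null(shard) && file.exists(shard)) {
          y <- as.matrix(utils::read.csv(shard))
        } else {
          y <- evaluate_design(design$points, weather, site, ntr, season,
                               start_year)
          y <- add_gpd(y)
          if (!is.null(shard))
            utils::write.csv(as.data.frame(y), shard, row.names = FALSE)
        }
        inc_rows[[length(inc_rows) + 1L]] <-
          data.frame(site = site, n_treatment = ntr, year = season,
                     n_incomplete = sum(!is.finite(y[, "grain_dm"])))
        g <- tryCatch(
          grain_protein_deviation(y[, "gpc"], y[, "grain_dm"] / 1000),
          error = function(e) NULL)
        if (!is.null(g))
          gpd_rows[[length(gpd_rows) + 1L]] <-
            data.frame(site = site, n_treatment = ntr, year = season,
                       slope = g$slope, r2 = g$r2, p_value = g$p_value,
                       significant = g$significant)
        for (out in colnames(y)) {
          ee <- withCallingHandlers(
            elementary_effects(design, y[, out]),
            warning = function(w) invokeRestart("muffleWarning"))
          if (any(vapply(ee, length, integer(1)) < 2L)) next
          st <- morris_stats(ee)
          st$site <- site; st$n_treatment <- ntr; st$year <- season
          st$output <- out
          stats_rows[[length(stats_rows) + 1L]] <- st
        }
      }
    }
  }
  list(stats = do.call(rbind, stats_rows), design = design,
       gpd = do.call(rbind, gpd_rows), incomplete = do.call(rbind, inc_rows))
}

#' Extended-FAST analysis over the experiment matrix
#'
#' For each scenario-year and factor search curve, evaluates the simulator
#' along the curve and estimates first-order and total indices for every
#' output (grain protein deviation computed within the curve). Sharding as
#' in [morris_experiment()].
#'
#' @param factors Factor names (default the 41 screening-selected ones).
#' @param sites,n_treatments,years Experiment matrix.
#' @param ns,M Design size (points per curve, harmonics).
#' @param resamples Independent search curves averaged per factor.
#' @param seed Seed for phases and weather.
#' @param store_dir Optional shard directory.
#' @param start_year First weather year.
#' @return List: `indices` (tidy factor x site x N x year x output with
#'   s_i, s_ti), `design`.
#' @export
efast_experiment <- function(factors = efast_parameter_table()$name,
                             sites = c("AV", "CF", "RR"),
                             n_treatments = c("HN", "LN"),
                             years = 3, ns = 65, M = 4, resamples = 1L,
                             seed = 1L, store_dir = NULL,
                             start_year = 1970L) {
  design <- fast_design(factors, ns = ns, M = M, resamples = resamples,
                        seed = derive_seed(seed, 211))
  rows <- list()
  for (site in sites) {
    weather <- generate_weather(site_preset(site, seed = derive_seed(seed, site_salt(site))),
                                years + 1, start_year)
    for (ntr in n_treatments) {
      for (season in seq_len(years)) {
        shard <- shard_path(store_dir, "efast", site, ntr, season)
        if (!is.null(shard) && file.exists(shard)) {
          tidy <- utils::read.csv(shard)
        } else {
          tidy <- efast_scenario(design, weather, site, ntr, season,
                                 start_year)
          if (!is.null(shard))
            utils::write.csv(tidy, shard, row.names = FALSE)
        }
        rows[[length(rows) + 1L]] <- tidy
      }
    }
  }
  list(indices = do.call(rbind, rows), design = design)
}

efast_scenario <- function(design, weather, site, ntr, season, start_year) {
  out <- list()
  for (fc in design$factors) {
    acc <- list()
    for (cv in design$curves[[fc]]) {
      y <- evaluate_design(cv$points, weather, site, ntr, season, start_year)
      y <- add_gpd(y)
      for (vn in colnames(y)) {
        yy <- y[, vn]
        bad <- !is.finite(yy)
        if (any(bad)) {
          if (mean(bad) < 0.01) yy <- repair_curve(yy) else next
        }
        fi <- tryCatch(fast_indices(yy, design, fc),
                       error = function(e) NULL)
        if (is.null(fi)) next
        acc[[length(acc) + 1L]] <- data.frame(output = vn, s_i = fi$s_i,
                                              s_ti = fi$s_ti)
      }
    }
    if (!length(acc)) next
    accd <- do.call(rbind, acc)
    for (vn in unique(accd$output))
      out[[length(out) + 1L]] <-
        data.frame(factor = fc, site = site, n_treatment = ntr,
                   year = season, output = vn,
                   s_i = mean(accd$s_i[accd$output == vn]),
                   s_ti = mean(accd$s_ti[accd$output == vn]))
  }
  do.call(rbind, out)
}

shard_path <- function(dir, method, site, ntr, season) {
  if (is.null(dir)) return(NULL)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, sprintf("%s_%s_%s_y%02d.csv", method, site, ntr, season))
}

derive_seed <- function(seed, salt) {
  ((as.numeric(seed) %% 1e6) * 48271 + as.numeric(salt) * 97561) %% 2147483629
}

site_salt <- function(site) {
  sum(utf8ToInt(site)) + 7
}

#' One-at-a-time effect signs over the experiment matrix
#'
#' For each factor and site x N treatment, runs the simulator at multipliers
#' 0.5, 0.6, ..., 1.5 of the factor's nominal value over `years` seasons
#' (pooled), and takes the sign of the ordinary least-squares slope of each
#' output against the parameter value. These signs decorate the rescaled
#' screening heat maps.
#'
#' @param factors Factor names.
#' @param sites,n_treatments,years Experiment matrix.
#' @param outputs Output columns to sign (default grain yield and protein).
#' @param seed Weather seed (matched to [morris_experiment()]).
#' @param start_year First weather year.
#' @return data.frame `factor`, `site`, `n_treatment`, `output`, `sign`,
#'   `slope`.
#' @export
oat_sign_table <- function(factors, sites = c("AV", "CF", "RR"),
                           n_treatments = c("HN", "LN"), years = 2,
                           outputs = c("grain_dm", "gpc"), seed = 1L,
                           start_year = 1970L) {
  multipliers <- seq(0.5, 1.5, by = 0.1)
  base <- nominal_parameters()
  rows <- list()
  for (site in sites) {
    weather <- generate_weather(
      site_preset(site, seed = derive_seed(seed, site_salt(site))),
      years + 1, start_year)
    soil <- site_soil(site)
    sow <- lapply(seq_len(years), function(s)
      as.Date(sprintf("%d-%s", start_year + s - 1L, site_sowing_date(site))))
    for (ntr in n_treatments) {
      mgmt <- management_plan(ntr)
      for (fc in factors) {
        xs <- c()
        ys <- matrix(numeric(0), 0, length(outputs),
                     dimnames = list(NULL, outputs))
        for (m in multipliers) {
          p <- base
          p[[fc]] <- base[[fc]] * m
          for (s in seq_len(years)) {
            res <- tryCatch(run_season(p, weather, soil, mgmt, sow[[s]]),
                            error = function(e) NULL)
            if (is.null(res) || !res$completed) next
            vals <- c(grain_dm = res$grain_dm_maturity, gpc = res$gpc,
                      anthesis = res$anthesis_day, gai = res$gai_anthesis,
                      crop_dm = res$crop_dm_maturity,
                      crop_n = res$crop_n_maturity,
                      grain_n = res$grain_n_maturity,
                      post_n = res$post_anthesis_n_uptake)
            xs <- c(xs, p[[fc]])
            ys <- rbind(ys, vals[outputs])
          }
        }
        for (out in outputs) {
          ok <- is.finite(ys[, out])
          sl <- if (sum(ok) >= 6 && stats::var(xs[ok]) > 0)
            stats::cov(xs[ok], ys[ok, out]) / stats::var(xs[ok]) else NA_real_
          sg <- if (is.na(sl)) 0
                else if (abs(sl * max(abs(base[[fc]]), 1)) <
                           1e-12 * max(abs(ys[ok, out]), 1)) 0
                else sign(sl)
          rows[[length(rows) + 1L]] <-
            data.frame(factor = fc, site = site, n_treatment = ntr,
                       output = out, sign = sg, slope = sl)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Median-over-years heat-map tables
#'
#' Aggregates tidy per-year sensitivity statistics to medians over years,
#' then (for Morris statistics) min-max rescales each output across factors
#' pooled over sites and N treatments, optionally signing the rescaled
#' values with one-at-a-time regression slopes. Factors are ordered by the
#' submodel blocks of the parameter table.
#'
#' @param stats Tidy data.frame with `factor`, `site`, `n_treatment`,
#'   `year`, `output`, and a value column.
#' @param value Name of the value column (`"mu_star"` or `"s_ti"`).
#' @param rescale Min-max rescale per output (the Morris convention)?
#' @param signs Optional data.frame `factor`, `site`, `n_treatment`,
#'   `output`, `sign` to attach.
#' @return data.frame `factor`, `submodel`, `site`, `n_treatment`,
#'   `output`, `median`, and `value_scaled` when rescaled (in \[-1, 1\] when
#'   signed).
#' @export
build_heatmaps <- function(stats, value = "mu_star", rescale = TRUE,
                           signs = NULL) {
  med <- stats::aggregate(stats[[value]],
                          by = stats[c("factor", "site", "n_treatment",
                                       "output")],
                          FUN = stats::median)
  names(med)[5] <- "median"
  if (rescale) {
    med$value_scaled <- NA_real_
    for (out in unique(med$output)) {
      i <- med$output == out
      rng <- range(med$median[i])
      med$value_scaled[i] <- if (diff(rng) > 0)
        (med$median[i] - rng[1]) / diff(rng) else 0
    }
    if (!is.null(signs)) {
      key <- function(d) paste(d$factor, d$site, d$n_treatment, d$output)
      m <- match(key(med), key(signs))
      med$value_scaled <- med$value_scaled * ifelse(is.na(m), 1,
                                                    signs$sign[m])
    }
  }
  tab <- parameter_table()
  ord <- match(med$factor, tab$name)
  med$submodel <- tab$submodel[ord]
  med[order(ord, med$output, med$site, med$n_treatment), ]
}

#' Distribution summaries of scenario outputs
#'
#' Empirical CDF and quantile summaries (10/25/50/75/90 percent) per group.
#'
#' @param values Numeric vector.
#' @param group Optional grouping vector (same length).
#' @return data.frame per group with the five quantiles, `n`, `mean`; the
#'   attribute `"ecdf"` carries one empirical CDF function per group.
#' @export
summarize_distributions <- function(values, group = rep("all", length(values))) {
  stopifnot(length(values) >= 1)
  qs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  sp <- split(values[is.finite(values)], group[is.finite(values)])
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    q <- stats::quantile(v, qs, names = FALSE)
    data.frame(group = g, q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
               q90 = q[5], n = length(v), mean = mean(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "ecdf") <- lapply(sp, stats::ecdf)
  out
}
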