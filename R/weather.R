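#' Astronomical daylength
#'
#' Standard solar-declination daylength (hours of sun above the horizon).
#'
#' @param latitude Degrees north (must satisfy |latitude| < 66.5).
#' @param day_of_year Integer day of year, 1..366 (vectorized).
#' @return Daylength in hours, in (0, 24).
#' @export
daylength <- function(latitude, day_of_year) {
  if (abs(latitude) >= 66.5)
    stop("daylength: polar latitudes not supported")
  phi <- latitude * pi / 180
  decl <- -0.4093 * cos(2 * pi * (day_of_year + 10) / 365.25)
  cosH <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 * acos(cosH) / pi
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation (FAO-56 formulation), the envelope used
#' both for the clear-sky radiation model and for Hargreaves reference
#' evapotranspiration.
#'
#' @inheritParams daylength
#' @return MJ m-2 d-1 (vectorized over `day_of_year`).
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365.25)
  decl <- 0.409 * sin(2 * pi * day_of_year / 365.25 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Weather generator configuration
#'
#' Parameters of the stochastic daily weather generator: a seasonal
#' temperature sinusoid with AR(1) anomalies, a two-state (wet/dry) Markov
#' precipitation occurrence chain with gamma wet-day amounts, and a clear-sky
#' radiation envelope damped by cloudiness tied to rain occurrence. Seasonal
#' vectors are ordered DJF, MAM, JJA, SON.
#'
#' @param site Site label.
#' @param latitude Degrees north.
#' @param tmean_annual Annual mean temperature (degC).
#' @param tamp Amplitude of the seasonal temperature sinusoid (degC); the
#'   warmest day is 20 July (day 201).
#' @param trange Mean diurnal range tmax - tmin (degC).
#' @param tnoise_sd Innovation s.d. of the AR(1) daily anomaly (degC).
#' @param ar1 AR(1) coefficient of the daily temperature anomaly.
#' @param p_wet_dry,p_wet_wet Seasonal Markov transition probabilities
#'   P(wet | previous dry) and P(wet | previous wet), length-4 vectors.
#' @param rain_shape Gamma shape of wet-day amounts (shared across seasons).
#' @param rain_mean Seasonal mean wet-day amount (mm), length-4 vector.
#' @param transmissivity Clear-sky fraction of extraterrestrial radiation.
#' @param cloud_dry,cloud_wet Fraction of clear-sky radiation reaching the
#'   ground on dry and wet days.
#' @param seed Integer RNG seed governing the whole series.
#' @return An object of class `weather_config`.
#' @export
weather_config <- function(site = "XX", latitude = 45,
                           tmean_annual = 11, tamp = 8, trange = 9,
                           tnoise_sd = 2.2, ar1 = 0.6,
                           p_wet_dry = rep(0.25, 4), p_wet_wet = rep(0.5, 4),
                           rain_shape = 0.75, rain_mean = rep(6, 4),
                           transmissivity = 0.75,
                           cloud_dry = 0.75, cloud_wet = 0.35,
                           seed = 1L) {
  cfg <- list(site = site, latitude = latitude, tmean_annual = tmean_annual,
              tamp = tamp, trange = trange, tnoise_sd = tnoise_sd, ar1 = ar1,
              p_wet_dry = p_wet_dry, p_wet_wet = p_wet_wet,
              rain_shape = rain_shape, rain_mean = rain_mean,
              transmissivity = transmissivity,
              cloud_dry = cloud_dry, cloud_wet = cloud_wet,
              seed = as.integer(seed))
  if (any(!is.finite(unlist(cfg[-1]))) ||
      any(c(cfg$p_wet_dry, cfg$p_wet_wet) < 0) ||
      any(c(cfg$p_wet_dry, cfg$p_wet_wet) > 1) ||
      cfg$rain_shape <= 0 || any(cfg$rain_mean <= 0) ||
      length(cfg$p_wet_dry) != 4L || length(cfg$p_wet_wet) != 4L ||
      length(cfg$rain_mean) != 4L ||
      cfg$trange <= 0 || cfg$tnoise_sd < 0 || abs(cfg$ar1) >= 1)
    stop("weather_config: invalid configuration")
  class(cfg) <- "weather_config"
  cfg
}

#' Site climate presets
#'
#' Generator configurations emulating three contrasted European climates:
#' `AV` (Mediterranean: warm dry summers, mild wet winters), `CF`
#' (Continental: hot summers, cold relatively dry winters) and `RR` (Oceanic:
#' cool summers, evenly distributed precipitation). The presets were
#' calibrated so that, with the nominal crop parameters, long-run means over
#' the emergence-to-anthesis and anthesis-to-maturity windows approach the
#' published site medians (e.g. 9.0 degC pre-anthesis at AV, ~446 mm
#' pre-anthesis precipitation at RR, ~73 mm post-anthesis at AV).
#'
#' @param site One of `"AV"`, `"CF"`, `"RR"`.
#' @param seed RNG seed passed through to the configuration.
#' @return A [weather_config()].
#' @export
site_preset <- function(site, seed = 1L) {
  switch(site,
    AV = weather_config(site = "AV", latitude = 43.91,
                        tmean_annual = 14.0, tamp = 8.1, trange = 9.5,
                        p_wet_dry = c(0.17, 0.18, 0.13, 0.18),
                        p_wet_wet = c(0.45, 0.45, 0.35, 0.45),
                        rain_shape = 0.75,
                        rain_mean = c(7.0, 7.5, 9.0, 9.0),
                        seed = seed),
    CF = weather_config(site = "CF", latitude = 45.80,
                        tmean_annual = 11.7, tamp = 8.9, trange = 10.0,
                        p_wet_dry = c(0.20, 0.22, 0.18, 0.20),
                        p_wet_wet = c(0.45, 0.48, 0.42, 0.45),
                        rain_shape = 0.75,
                        rain_mean = c(4.5, 5.5, 8.0, 6.0),
                        seed = seed),
    RR = weather_config(site = "RR", latitude = 51.80,
                        tmean_annual = 9.6, tamp = 6.6, trange = 8.0,
                        p_wet_dry = c(0.34, 0.30, 0.28, 0.32),
                        p_wet_wet = c(0.62, 0.55, 0.52, 0.60),
                        rain_shape = 0.75,
                        rain_mean = c(4.5, 4.5, 5.5, 5.5),
                        cloud_dry = 0.70,
                        seed = seed),
    stop("site_preset: unknown site '", site, "'")
  )
}

season_of_month <- function(m) {
  # 1 = DJF, 2 = MAM, 3 = JJA, 4 = SON
  c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[m]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-year substream seed (kept below 2^31)
year_seed <- function(seed, year) {
  (as.numeric(seed) * 48271 + as.numeric(year) * 65537) %% 2147483629
}

#' Generate a multi-year daily weather series
#'
#' Deterministic given the configuration seed. Each calendar year draws from
#' its own derived RNG substream, so year k of a series is invariant to the
#' total number of years generated.
#'
#' @param config A [weather_config()].
#' @param years Number of whole calendar years to generate (>= 1).
#' @param start_year First calendar year (default 1970).
#' @return A `weather_series`: data.frame with columns `date`, `tmin`,
#'   `tmax`, `srad` (MJ m-2 d-1), `rain` (mm d-1) and attributes `site`,
#'   `latitude`.
#' @export
generate_weather <- function(config, years, start_year = 1970L) {
  stopifnot(inherits(config, "weather_config"))
  if (!is.numeric(years) || years < 1) stop("generate_weather: years must be >= 1")
  years <- as.integer(years)
  out <- vector("list", years)
  for (k in seq_len(years)) {
    yr <- start_year + k - 1L
    out[[k]] <- with_seed(year_seed(config$seed, yr),
                          generate_weather_year(config, yr))
  }
  ser <- do.call(rbind, out)
  rownames(ser) <- NULL
  attr(ser, "site") <- config$site
  attr(ser, "latitude") <- config$latitude
  class(ser) <- c("weather_series", "data.frame")
  ser
}

generate_weather_year <- function(config, yr) {
  dates <- seq(as.Date(sprintf("%d-01-01", yr)),
               as.Date(sprintf("%d-12-31", yr)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  sea <- season_of_month(mon)

  # temperature: sinusoid + AR(1) anomaly
  base <- config$tmean_annual + config$tamp * cos(2 * pi * (doy - 201) / 365.25)
  innov <- stats::rnorm(n, 0, config$tnoise_sd)
  anom <- numeric(n)
  anom[1] <- innov[1]
  for (i in 2:n) anom[i] <- config$ar1 * anom[i - 1] + innov[i]
  tmean <- base + anom
  half_range <- pmax(0.25, config$trange / 2 + stats::rnorm(n, 0, 0.75))
  tmin <- tmean - half_range
  tmax <- tmean + half_range

  # precipitation: two-state Markov occurrence, gamma amounts
  u <- stats::runif(n)
  wet <- logical(n)
  wet[1] <- u[1] < config$p_wet_dry[sea[1]]
  for (i in 2:n) {
    pw <- if (wet[i - 1]) config$p_wet_wet[sea[i]] else config$p_wet_dry[sea[i]]
    wet[i] <- u[i] < pw
  }
  rain <- numeric(n)
  nw <- sum(wet)
  if (nw > 0) {
    mu <- config$rain_mean[sea[wet]]
    rain[wet] <- stats::rgamma(nw, shape = config$rain_shape,
                               scale = mu / config$rain_shape)
  }

  # radiation: clear-sky envelope x cloudiness tied to rain occurrence
  ra <- extraterrestrial_radiation(config$latitude, doy)
  cloud <- ifelse(wet, config$cloud_wet, config$cloud_dry)
  srad <- ra * config$transmissivity * cloud *
    pmax(0.5, 1 + stats::rnorm(n, 0, 0.08))
  srad <- pmax(srad, 0.1)

  data.frame(date = dates, tmin = tmin, tmax = tmax, srad = srad, rain = rain)
}

#' Read / write daily weather CSV
#'
#' The on-disk format is a CSV with header `date,tmin,tmax,srad,rain`,
#' ISO-8601 dates, degC, MJ m-2 d-1 and mm d-1. `read_weather` rejects
#' malformed files and reports the offending line numbers (header = line 1).
#'
#' @param path File path.
#' @param site,latitude Metadata attached to the returned series.
#' @return `read_weather`: a `weather_series`.
#' @export
read_weather <- function(path, site = "file", latitude = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "srad", "rain")
  if (!all(need %in% names(df)))
    stop("read_weather: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) stop("read_weather: no records")
  line <- seq_len(nrow(df)) + 1L  # header occupies line 1
  d <- as.Date(df$date)
  bad <- line[is.na(d)]
  if (length(bad)) stop("read_weather: unparseable date on line(s) ",
                        paste(bad, collapse = ", "))
  num <- vapply(df[c("tmin", "tmax", "srad", "rain")],
                function(x) all(is.finite(as.numeric(x))), logical(1))
  if (!all(num)) stop("read_weather: non-numeric values in column(s) ",
                      paste(names(num)[!num], collapse = ", "))
  bad <- line[df$tmax < df$tmin]
  if (length(bad)) stop("read_weather: tmax < tmin on line(s) ",
                        paste(bad, collapse = ", "))
  bad <- line[df$srad < 0 | df$rain < 0]
  if (length(bad)) stop("read_weather: negative srad/rain on line(s) ",
                        paste(bad, collapse = ", "))
  if (any(diff(d) <= 0)) {
    bad <- line[-1][diff(d) <= 0]
    stop("read_weather: dates not strictly increasing at line(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(diff(d) != 1)) {
    bad <- line[-1][diff(d) != 1]
    stop("read_weather: date gap before line(s) ", paste(bad, collapse = ", "))
  }
  out <- data.frame(date = d, tmin = as.numeric(df$tmin),
                    tmax = as.numeric(df$tmax), srad = as.numeric(df$srad),
                    rain = as.numeric(df$rain))
  attr(out, "site") <- site
  attr(out, "latitude") <- latitude
  class(out) <- c("weather_series", "data.frame")
  out
}

#' @rdname read_weather
#' @param series A `weather_series`.
#' @export
write_weather <- function(series, path) {
  df <- as.data.frame(series)[c("date", "tmin", "tmax", "srad", "rain")]
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
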