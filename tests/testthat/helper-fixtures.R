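# Shared fixtures, built in code at test time.

nominal <- nominal_parameters()

# constant synthetic weather: handy for closed-form phenology checks
constant_weather <- function(tmean = 15, days = 420, srad = 15, rain = 1,
                             start = "1970-10-01", latitude = 45) {
  dates <- seq(as.Date(start), by = "day", length.out = days)
  w <- data.frame(date = dates, tmin = tmean - 5, tmax = tmean + 5,
                  srad = srad, rain = rain)
  attr(w, "site") <- "CONST"
  attr(w, "latitude") <- latitude
  class(w) <- c("weather_series", "data.frame")
  w
}

# cache site weather across test files (generation is cheap but repeated)
site_weather <- local({
  cache <- list()
  function(site, years = 3, seed = 1) {
    key <- paste(site, years, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_weather(site_preset(site, seed = seed),
                                        years, 1970)
    cache[[key]]
  }
})

random_unit_vector <- function(names) {
  stats::setNames(stats::runif(length(names)), names)
}

# brute-force oracle: enumerate every admissible +delta elementary effect of
# factor i on the p-level grid (base level of i over the lower half-grid,
# all other coordinates over the full grid)
brute_force_ee <- function(f, k, i, p = 8) {
  delta <- p / (2 * (p - 1))
  levels <- (0:(p - 1)) / (p - 1)
  lower <- levels[levels <= 1 - delta + 1e-12]
  others <- setdiff(seq_len(k), i)
  grids <- c(list(lower), rep(list(levels), length(others)))
  combos <- do.call(expand.grid, grids)
  apply(combos, 1, function(row) {
    x <- numeric(k)
    x[i] <- row[1]
    x[others] <- as.numeric(row[-1])
    x2 <- x
    x2[i] <- x[i] + delta
    (f(x2) - f(x)) / delta
  })
}
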