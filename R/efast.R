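#' Extended-FAST design
#'
#' Search-curve sampling for the extended Fourier amplitude sensitivity
#' test. For each factor of interest a curve of `ns` points is generated
#' with that factor driven at the maximum frequency
#' `omega_max = floor((ns - 1) / (2 * M))` and every other factor at a low
#' complementary frequency (drawn at random from
#' `1..max(1, floor(omega_max / (2 * M)))`), through the arcsine map
#' `x_j = 1/2 + asin(sin(w_j s + phi_j)) / pi` with random phase shifts per
#' curve. `resamples` independent curves (fresh complementary frequencies
#' and phases) can be averaged per factor to reduce the single-curve
#' estimation noise; the default of 1 gives the classic `k * ns` model-run
#' count.
#'
#' @param factors Character vector of factor names (k of them).
#' @param ns Points per search curve (odd; default 729).
#' @param M Number of harmonics used in the spectral estimates (default 4).
#' @param seed RNG seed for frequencies and phases.
#' @param resamples Curves per factor (default 1).
#' @return An `efast_design`: list with `factors`, `ns`, `M`, `omega_max`,
#'   `n_comp`, `resamples`, and `curves[[factor]][[r]]` each holding
#'   `points` (ns x k), `omega`, `phi`, `s`.
#' @export
fast_design <- function(factors, ns = 729, M = 4, seed = 1L, resamples = 1L) {
  k <- length(factors)
  if (ns %% 2 != 1) stop("fast_design: ns must be odd")
  omega_max <- floor((ns - 1) / (2 * M))
  if (omega_max < 1)
    stop("fast_design: ns too small for ", M, " harmonics")
  n_comp <- max(1, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(ns) - ns - 1) / ns   # ns points spanning (-pi, pi)
  curves <- vector("list", k)
  names(curves) <- factors
  with_seed(seed, {
    for (i in seq_len(k)) {
      curves[[i]] <- lapply(seq_len(resamples), function(r) {
        w <- numeric(k)
        w[i] <- omega_max
        if (k > 1)
          w[-i] <- sample.int(n_comp, k - 1, replace = k - 1 > n_comp)
        phi <- stats::runif(k, 0, 2 * pi)
        pts <- matrix(NA_real_, ns, k, dimnames = list(NULL, factors))
        for (j in seq_len(k))
          pts[, j] <- 0.5 + asin(sin(w[j] * s + phi[j])) / pi
        list(points = pts, omega = w, phi = phi, s = s)
      })
    }
  })
  structure(list(factors = factors, ns = ns, M = M, omega_max = omega_max,
                 n_comp = n_comp, resamples = resamples, curves = curves,
                 seed = seed),
            class = "efast_design")
}

#' First-order and total sensitivity indices from one search curve
#'
#' Fourier-decomposes the model output along a curve on which `factor` runs
#' at `omega_max`. The first-order index is the spectral power at
#' `omega_max` and its first `M` harmonics over the total variance; the
#' total index is one minus the power at the complementary low frequencies
#' (everything at or below `omega_max / 2`) over the total variance.
#'
#' @param y Model outputs along the curve (length ns, finite).
#' @param design An `efast_design`.
#' @param factor Factor name (selects the curve geometry; any resample of
#'   the factor shares `s`, `omega_max` and `M`).
#' @return List: `s_i`, `s_ti`, `variance`.
#' @export
fast_indices <- function(y, design, factor) {
  ns <- design$ns
  if (length(y) != ns) stop("fast_indices: y must have length ns")
  if (any(!is.finite(y))) stop("fast_indices: non-finite outputs")
  s <- design$curves[[factor]][[1]]$s
  wmax <- design$omega_max
  M <- design$M
  nfreq <- (ns - 1) / 2
  freq <- seq_len(nfreq)
  A <- vapply(freq, function(w) mean(y * cos(w * s)), numeric(1))
  B <- vapply(freq, function(w) mean(y * sin(w * s)), numeric(1))
  lambda <- 2 * (A^2 + B^2)
  V <- sum(lambda)
  if (V <= 1e-24) stop("fast_indices: constant output, indices undefined")
  s_i <- sum(lambda[seq_len(M) * wmax]) / V
  s_ti <- 1 - sum(lambda[seq_len(floor(wmax / 2))]) / V
  list(s_i = s_i, s_ti = s_ti, variance = V)
}

#' Run a full extended-FAST analysis of a model function
#'
#' Evaluates the model over every curve of the design and returns tidy
#' per-factor indices (averaged over the design's resample curves). Curves
#' with a small number of failed points (< 1 percent) are repaired by
#' linear interpolation along the curve; curves with more failures are
#' dropped with a warning.
#'
#' @param f Function mapping a named unit-cube vector (one row of the design
#'   points) to a numeric output.
#' @param design An `efast_design`.
#' @return data.frame with columns `factor`, `s_i`, `s_ti`.
#' @export
fast_analyze <- function(f, design) {
  res <- lapply(design$factors, function(fc) {
    est <- vapply(design$curves[[fc]], function(cv) {
      pts <- cv$points
      y <- vapply(seq_len(nrow(pts)), function(r) as.numeric(f(pts[r, ])),
                  numeric(1))
      bad <- !is.finite(y)
      if (any(bad)) {
        if (mean(bad) < 0.01) y <- repair_curve(y)
        else return(c(NA_real_, NA_real_))
      }
      fi <- fast_indices(y, design, fc)
      c(fi$s_i, fi$s_ti)
    }, numeric(2))
    ok <- is.finite(est[1, ])
    if (!any(ok)) {
      warning("fast_analyze: dropped all curves for ", fc)
      return(NULL)
    }
    if (any(!ok))
      warning("fast_analyze: dropped ", sum(!ok), " curve(s) for ", fc)
    data.frame(factor = fc, s_i = mean(est[1, ok]), s_ti = mean(est[2, ok]))
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

repair_curve <- function(y) {
  bad <- which(!is.finite(y))
  ok <- which(is.finite(y))
  y[bad] <- stats::approx(ok, y[ok], xout = bad, rule = 2)$y
  y
}

#' Model-run counts of the extended-FAST method
#'
#' `fast_run_count` is the number of parameter vectors of a k-factor design
#' with ns points per search curve; `fast_min_runs` is the method's minimum,
#' `k * (4 * M^2 + 1)` (65 points per curve for M = 4 harmonics).
#'
#' @param k Number of factors.
#' @param ns Points per curve.
#' @param M Harmonics.
#' @return Integer count.
#' @export
fast_run_count <- function(k, ns) k * ns

#' @rdname fast_run_count
#' @export
fast_min_runs <- function(k, M = 4) k * (4 * M^2 + 1)

#' Influential-parameter selection from total sensitivity indices
#'
#' For each year (within a site x N treatment), factors are ranked by
#' total index and the minimal prefix reaching `coverage` of the summed
#' indices is marked; a factor is selected when marked in at least
#' `year_fraction` of the years of at least one site x N treatment. Ties
#' break deterministically by factor name.
#'
#' @param s_ti Data.frame with columns `factor`, `site`, `n_treatment`,
#'   `year`, `s_ti` (possibly several output variables pooled by the
#'   caller).
#' @param coverage Fraction of the summed total index to cover (0.90).
#' @param year_fraction Minimum fraction of years (0.50).
#' @return Character vector of selected factor names (sorted).
#' @export
select_influential <- function(s_ti, coverage = 0.90, year_fraction = 0.50) {
  stopifnot(nrow(s_ti) > 0)
  selected <- character(0)
  for (cell in split(s_ti, list(s_ti$site, s_ti$n_treatment), drop = TRUE)) {
    years <- unique(cell$year)
    marks <- table(unlist(lapply(years, function(yr) {
      d <- cell[cell$year == yr, ]
      d <- d[order(-d$s_ti, d$factor), ]
      tot <- sum(d$s_ti)
      if (tot <= 0) return(character(0))
      need <- coverage * tot
      cum <- cumsum(d$s_ti)
      d$factor[seq_len(which(cum >= need - 1e-12)[1])]
    })))
    sel <- names(marks)[marks >= year_fraction * length(years)]
    selected <- union(selected, sel)
  }
  sort(selected)
}
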