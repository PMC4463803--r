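#' Morris trajectory design
#'
#' One-at-a-time screening design on a p-level grid of the unit hypercube.
#' Each of the r trajectories is a sequence of k+1 points in which every
#' consecutive pair differs in exactly one coordinate by +/- delta, with
#' `delta = p / (2 * (p - 1))`; every factor moves exactly once per
#' trajectory, in random order and from a random admissible starting level.
#'
#' @param k Number of factors (or character vector of factor names).
#' @param p Number of grid levels (even; default 8).
#' @param r Number of trajectories (default 10).
#' @param seed RNG seed.
#' @return A `morris_design`: list with `points` (an `r*(k+1) x k` matrix of
#'   unit-cube rows), `factor` / `sign` (which factor moved into each point
#'   and with which step sign), `k`, `p`, `r`, `delta`, `names`.
#' @export
sample_trajectories <- function(k, p = 8, r = 10, seed = 1L) {
  nms <- if (is.character(k)) k else paste0("x", seq_len(k))
  k <- length(nms)
  if (p %% 2 != 0) stop("sample_trajectories: p must be even")
  if (r < 1) stop("sample_trajectories: r must be >= 1")
  delta <- p / (2 * (p - 1))
  levels0 <- (seq_len(p / 2) - 1) / (p - 1)   # admissible starting levels
  pts <- matrix(NA_real_, nrow = r * (k + 1), ncol = k,
                dimnames = list(NULL, nms))
  fac <- integer(r * (k + 1))
  sgn <- integer(r * (k + 1))
  with_seed(seed, {
    for (t in seq_len(r)) {
      x <- levels0[sample.int(p / 2, k, replace = TRUE)]
      dirs <- sample(c(-1, 1), k, replace = TRUE)
      # a +delta step from the low half-grid always stays inside [0,1];
      # -delta steps are mirrored up front
      x[dirs < 0] <- x[dirs < 0] + delta
      ord <- sample.int(k)
      row0 <- (t - 1) * (k + 1) + 1
      pts[row0, ] <- x
      for (j in seq_len(k)) {
        i <- ord[j]
        x[i] <- x[i] + dirs[i] * delta
        pts[row0 + j, ] <- x
        fac[row0 + j] <- i
        sgn[row0 + j] <- dirs[i]
      }
    }
  })
  structure(list(points = pts, factor = fac, sign = sgn,
                 k = k, p = p, r = r, delta = delta, names = nms),
            class = "morris_design")
}

#' Elementary effects from model outputs along a design
#'
#' For each within-trajectory step that moved factor i from x to
#' x +/- delta*e_i, the elementary effect is
#' `(y(after) - y(before)) / (sign * delta)`. Trajectories containing
#' non-finite outputs (e.g. incomplete seasons) are dropped with a warning.
#'
#' @param design A `morris_design`.
#' @param y Numeric vector of model outputs aligned to `design$points` rows.
#' @return A list of length k (named by factor) of elementary-effect
#'   vectors, one element per retained trajectory.
#' @export
elementary_effects <- function(design, y) {
  npts <- design$r * (design$k + 1)
  if (length(y) != npts)
    stop("elementary_effects: y must have length r*(k+1)")
  ee <- rep(list(numeric(0)), design$k)
  names(ee) <- design$names
  dropped <- 0L
  for (t in seq_len(design$r)) {
    rows <- ((t - 1) * (design$k + 1) + 1):(t * (design$k + 1))
    yt <- y[rows]
    if (any(!is.finite(yt))) {
      dropped <- dropped + 1L
      next
    }
    for (j in 2:length(rows)) {
      i <- design$factor[rows[j]]
      e <- (yt[j] - yt[j - 1]) / (design$sign[rows[j]] * design$delta)
      ee[[i]] <- c(ee[[i]], e)
    }
  }
  if (dropped > 0L)
    warning("elementary_effects: dropped ", dropped,
            " trajectory(ies) with non-finite outputs")
  ee
}

#' Morris screening statistics
#'
#' `mu_star` is the mean absolute elementary effect (overall importance),
#' `sigma` the sample standard deviation of the effects (non-linearity
#' and/or interaction), `mu` the signed mean.
#'
#' @param effects List of per-factor elementary-effect vectors
#'   (from [elementary_effects()]).
#' @return data.frame with columns `factor`, `mu_star`, `sigma`, `mu`,
#'   `n_effects`.
#' @export
morris_stats <- function(effects) {
  n <- vapply(effects, length, integer(1))
  if (any(n < 2L))
    stop("morris_stats: need >= 2 elementary effects per factor")
  data.frame(
    factor = names(effects),
    mu_star = vapply(effects, function(e) mean(abs(e)), numeric(1)),
    sigma = vapply(effects, stats::sd, numeric(1)),
    mu = vapply(effects, mean, numeric(1)),
    n_effects = n,
    row.names = NULL)
}

#' Min-max rescaling of sensitivity medians for heat maps
#'
#' Rescales each output column to \[0, 1\] across all rows (factors, pooled
#' over sites and N treatments): `(z - min) / (max - min)`. A constant
#' column is returned as all zeros with a warning.
#'
#' @param values Matrix or data.frame of medians, rows = factors (x site x
#'   N), columns = outputs.
#' @return Object of the same shape, each column rescaled to \[0, 1\].
#' @export
rescale_heatmap <- function(values) {
  m <- as.matrix(values)
  out <- apply(m, 2, function(z) {
    rng <- range(z)
    if (diff(rng) <= 0) {
      warning("rescale_heatmap: constant column rescaled to zeros")
      return(rep(0, length(z)))
    }
    (z - rng[1]) / diff(rng)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Sign of a factor's overall effect by one-at-a-time regression
#'
#' Varies one parameter at a time over multipliers 0.5, 0.6, ..., 1.5 of its
#' nominal value, evaluates the model at each, and returns the sign of the
#' ordinary least-squares slope of output against parameter value (0 when
#' the relative slope magnitude is below 1e-12, or when more than half the
#' runs are unusable).
#'
#' @param f Function taking a full named parameter set and returning a
#'   numeric output (may return NA for failed runs).
#' @param base Named parameter set to perturb.
#' @param factor Parameter name.
#' @param multipliers Multipliers of the nominal value.
#' @return -1, 0 or +1.
#' @export
sign_by_oat <- function(f, base, factor, multipliers = seq(0.5, 1.5, by = 0.1)) {
  x0 <- base[[factor]]
  xs <- x0 * multipliers
  ys <- vapply(multipliers, function(m) {
    p <- base
    p[[factor]] <- x0 * m
    as.numeric(f(p))
  }, numeric(1))
  ok <- is.finite(ys)
  if (sum(ok) < length(ys) / 2) {
    warning("sign_by_oat: sign undetermined for ", factor,
            " (too many failed runs)")
    return(0)
  }
  if (stats::var(xs[ok]) == 0) return(0)
  slope <- stats::cov(xs[ok], ys[ok]) / stats::var(xs[ok])
  scale <- max(abs(ys[ok]), abs(slope * x0), 1e-300)
  if (abs(slope * max(abs(x0), 1)) < 1e-12 * scale) 0 else sign(slope)
}

#' Number of model runs of a Morris design
#'
#' @param k Number of factors.
#' @param r Number of trajectories.
#' @return `r * (k + 1)`.
#' @export
morris_run_count <- function(k, r) r * (k + 1)
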