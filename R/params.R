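#' The 75-parameter trait space
#'
#' The simulator is parameterized by 75 named morpho-physiological trait
#' parameters grouped into eight submodels (phenology, leaf layer expansion,
#' light interception and use efficiency, grain, DM allocation, N allocation,
#' root growth and N uptake, soil drought factors). The table ships with the
#' package as a CSV; [parameter_table()] loads it once and caches it.
#'
#' @return A data.frame with columns `name`, `symbol`, `submodel`,
#'   `definition`, `nominal`, `unit`; one row per parameter, 75 rows total.
#' @export
parameter_table <- function() {
  if (is.null(.wheatsens_env$param_table)) {
    path <- system.file("extdata", "trait_parameters.csv", package = "wheatsens",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(!anyDuplicated(tab$name), nrow(tab) == 75L,
              all(is.finite(tab$nominal)))
    .wheatsens_env$param_table <- tab
  }
  .wheatsens_env$param_table
}

.wheatsens_env <- new.env(parent = emptyenv())

#' Nominal parameter set
#'
#' @return Named numeric vector of length 75 holding the nominal value of
#'   every trait parameter.
#' @export
nominal_parameters <- function() {
  tab <- parameter_table()
  stats::setNames(tab$nominal, tab$name)
}

#' Parameters selected for the variance-based analysis
#'
#' The 41 parameters retained after elementary-effects screening, the default
#' factor set of the extended-FAST analysis.
#'
#' @return data.frame with columns `name` and `submodel` (41 rows).
#' @export
efast_parameter_table <- function() {
  path <- system.file("extdata", "efast_selected_parameters.csv",
                      package = "wheatsens", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$name %in% parameter_table()$name))
  tab
}

#' Perturbation specification for the unit-hypercube rescaling
#'
#' Each parameter x is perturbed multiplicatively around its nominal value:
#' x = x_nominal * (frac_min + (frac_max - frac_min) * u) with u in [0, 1].
#' The default +/-20 percent band encompasses the observed range of genetic
#' variation for most of the traits.
#'
#' @param frac_min,frac_max Lower/upper fractional bounds (defaults 0.8, 1.2).
#' @param overrides Optional named list of `c(frac_min, frac_max)` pairs for
#'   individual parameters.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(frac_min = 0.8, frac_max = 1.2, overrides = list()) {
  if (!(is.numeric(frac_min) && is.numeric(frac_max) &&
        frac_min > 0 && frac_min <= frac_max))
    stop("perturbation_spec: need 0 < frac_min <= frac_max")
  for (ov in overrides) {
    if (length(ov) != 2L || ov[1] <= 0 || ov[1] > ov[2])
      stop("perturbation_spec: invalid override")
  }
  structure(list(frac_min = frac_min, frac_max = frac_max, overrides = overrides),
            class = "perturbation_spec")
}

#' Map unit-cube coordinates to a parameter set
#'
#' Applies the multiplicative perturbation rule to a named subset of
#' parameters: each named parameter is replaced by
#' `nominal * (frac_min + (frac_max - frac_min) * u)`; parameters not named
#' in `u` are left unchanged.
#'
#' @param base Named numeric parameter set (usually [nominal_parameters()]).
#' @param u Named numeric vector with values in \[0, 1\]; names must be a
#'   subset of the parameter names.
#' @param spec A [perturbation_spec()].
#' @return The perturbed named parameter set.
#' @export
rescale_unit_vector <- function(base, u, spec = perturbation_spec()) {
  if (is.null(names(u)) || any(!nzchar(names(u))))
    stop("rescale_unit_vector: u must be fully named")
  unknown <- setdiff(names(u), names(base))
  if (length(unknown))
    stop("rescale_unit_vector: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("rescale_unit_vector: coordinates must lie in [0, 1]")
  lo <- rep(spec$frac_min, length(u))
  hi <- rep(spec$frac_max, length(u))
  if (length(spec$overrides)) {
    idx <- match(names(spec$overrides), names(u))
    ok <- !is.na(idx)
    lo[idx[ok]] <- vapply(spec$overrides[ok], `[`, numeric(1), 1L)
    hi[idx[ok]] <- vapply(spec$overrides[ok], `[`, numeric(1), 2L)
  }
  base[names(u)] <- base[names(u)] * (lo + (hi - lo) * u)
  base
}

#' Consistency checks on a parameter set
#'
#' Advisory validation of cross-parameter orderings implied by the parameter
#' definitions (threshold orderings, phase-duration nesting, non-negativity).
#' The sensitivity analyses perturb parameters independently, so validation is
#' advisory there; the simulator clips the orderings it physically requires
#' and warns when it does.
#'
#' @param p Named numeric parameter set with the full 75 entries.
#' @return Character vector of violation messages (empty when consistent).
#' @export
validate_parameters <- function(p) {
  expected <- parameter_table()$name
  missing <- setdiff(expected, names(p))
  if (length(missing))
    return(paste0("missing parameter: ", missing))
  v <- character(0)
  chk <- function(cond, msg) if (!cond) v <<- c(v, msg)
  chk(all(is.finite(p[expected])), "non-finite parameter value")
  chk(p[["MinL"]] <= p[["MaxL"]], "MinL must be <= MaxL")
  chk(p[["Ldecr"]] < p[["Lincr"]], "Ldecr must be < Lincr")
  chk(p[["Topt"]] < p[["Tmax"]], "Topt must be < Tmax (RUE temperature response)")
  chk(p[["IntTvern"]] < p[["MaxTvern"]], "IntTvern must be < MaxTvern")
  for (s in c("exp", "gs", "rue", "sen")) {
    chk(p[[paste0("UpperFTSW", s)]] >= p[[paste0("LowerFTSW", s)]],
        paste0("UpperFTSW", s, " must be >= LowerFTSW", s))
  }
  chk(p[["MinSLN"]] <= p[["CritSLN"]] && p[["CritSLN"]] <= p[["MaxSLN"]],
      "need MinSLN <= CritSLN <= MaxSLN")
  chk(p[["Dcd"]] <= p[["Dgf"]], "Dcd must be <= Dgf")
  chk(p[["Dcd"]] + p[["Der"]] <= p[["Dgf"]], "Dcd + Der must be <= Dgf")
  nonneg <- c("Dse", "P", "PexpL", "PlagLL", "PlagSL", "PsenLL", "PsenSL",
              "AreaPL", "AreaSL", "AreaSS", "NLL", "Kl", "RUE", "Dcd", "Der",
              "Dgf", "Kcd", "EarGR", "SLWp", "SSWp", "MaxNuptake", "RVER",
              "MaxRWU", "PFLLAnth")
  chk(all(p[nonneg] >= 0), "durations, areas, and rates must be >= 0")
  v
}
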