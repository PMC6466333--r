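# Plow-layer soil accumulation model: annual input flux from fertilizer,
# cumulative soil concentration, and time until the soil limit is reached,
# deterministically and by Monte Carlo over the fertilizer concentration
# distribution.

#' Annual trace-metal input flux from fertilizer application
#'
#' The metal mass added per kg of plow-layer soil in one application
#' year:
#' \deqn{Q_p = \frac{IR_f \, \alpha}{\rho_b \, V}}
#' with `IR_f` the application rate (t/hm^2/yr), `alpha` the fertilizer
#' concentration (mg/kg DW), `rho_b` the soil bulk density (g/cm^3, i.e.
#' t/m^3) and `V` the plow-layer volume (m^3/hm^2; 2000 for a 20 cm
#' layer).  The t-to-kg factors in numerator and denominator cancel, so
#' `Qp` is in mg metal per kg soil per year.
#'
#' @param alpha Fertilizer concentration(s), mg/kg DW; a named vector
#'   gives per-metal fluxes.
#' @param params An `fr_region` object (see [load_region_parameters()]).
#' @return Numeric vector of `Qp` (mg/kg per application-year), named
#'   like `alpha`.
#' @export
#' @examples
#' p <- load_region_parameters("north")
#' annual_input(478.11, p)  # Zn: ~6.01 mg/kg/yr
annual_input <- function(alpha, params) {
  stopifnot(inherits(params, "fr_region"))
  if (any(alpha < 0)) stop("'alpha' must be >= 0", call. = FALSE)
  if (params$rho_b <= 0 || params$IR_f <= 0 || params$V_plow <= 0) {
    stop("region parameters must be positive", call. = FALSE)
  }
  params$IR_f * alpha / (params$rho_b * params$V_plow)
}

#' Soil concentration after repeated application
#'
#' Linear no-loss accumulation: `Qi = Q0 + years * Qp`.  Losses through
#' leaching, runoff, crop uptake, or gains from atmospheric deposition
#' are not modelled, so long-horizon projections are conservative
#' (slightly overestimated).
#'
#' @param Q0 Background soil concentration(s), mg/kg.
#' @param Qp Annual input flux(es) from [annual_input()], mg/kg/yr.
#' @param years Number of application years (>= 0).
#' @return Soil concentration(s) after `years` years, mg/kg.
#' @export
cumulative_concentration <- function(Q0, Qp, years) {
  if (any(years < 0)) stop("'years' must be >= 0", call. = FALSE)
  Q0 + years * Qp
}

#' Years until the soil limit is reached
#'
#' Closed form `T = (Cs - Q0) / Qp`.  `Qp = 0` gives `Inf`; a background
#' already at or above the limit gives `T = 0` with the
#' `already_exceeding` flag set.  The identity `Q0 + T * Qp = Cs` holds
#' exactly for every finite positive `T`.
#'
#' @param Q0 Background soil concentration(s), mg/kg.
#' @param Qp Annual input flux(es), mg/kg/yr.
#' @param Cs Soil limit(s), mg/kg (> 0), e.g. from [load_soil_limits()].
#' @return List with numeric `years` (unrounded, possibly `Inf`) and
#'   logical `already_exceeding`, both named like the inputs.
#' @export
#' @examples
#' lim <- load_soil_limits()
#' p <- load_region_parameters("north")
#' Qp <- annual_input(survey_medians("north"), p)
#' time_to_limit(p$Q0, Qp, lim)$years  # Zn ~38.7 -> rounds to 39
time_to_limit <- function(Q0, Qp, Cs) {
  if (any(Cs <= 0)) stop("'Cs' must be > 0", call. = FALSE)
  if (any(Qp < 0)) stop("'Qp' must be >= 0", call. = FALSE)
  exceeding <- Q0 >= Cs
  years <- ifelse(exceeding, 0, ifelse(Qp == 0, Inf, (Cs - Q0) / Qp))
  if (!is.null(names(Q0))) names(years) <- names(Q0)
  list(years = years, already_exceeding = exceeding)
}

#' Deterministic accumulation table for a region
#'
#' Couples the annual input flux (at the supplied fertilizer medians)
#' with the time-to-limit computation, one row per metal.  Times are
#' reported unrounded and rounded half-up to the nearest year; the
#' rounded value is always derived from the *unrounded* flux (chaining
#' a rounded flux distorts slow metals, e.g. 944 instead of 928 years).
#'
#' @param params An `fr_region` object.
#' @param alpha Named per-metal fertilizer concentrations (mg/kg DW);
#'   defaults to the packaged survey medians of the region.
#' @param soil_limits Named soil limits, mg/kg.
#' @return Data frame: `region`, `metal`, `alpha`, `Qp`, `T_years`
#'   (unrounded), `T_rounded`, `already_exceeding`.
#' @export
accumulation_table <- function(params,
                               alpha = survey_medians(params$region_name),
                               soil_limits = load_soil_limits()) {
  stopifnot(inherits(params, "fr_region"),
            all(trace_metals() %in% names(alpha)),
            all(trace_metals() %in% names(soil_limits)))
  alpha <- alpha[trace_metals()]
  Qp <- annual_input(alpha, params)
  tt <- time_to_limit(params$Q0, Qp, soil_limits[trace_metals()])
  data.frame(region = params$region_name, metal = trace_metals(),
             alpha = as.numeric(alpha), Qp = as.numeric(Qp),
             T_years = as.numeric(tt$years),
             T_rounded = round_half_up(as.numeric(tt$years)),
             already_exceeding = as.logical(tt$already_exceeding),
             stringsAsFactors = FALSE, row.names = trace_metals())
}

#' Monte Carlo time-to-limit simulation
#'
#' Propagates the uncertainty in the fertilizer concentration through
#' the accumulation model: per iteration, one concentration per metal is
#' drawn from its distribution spec, converted to an annual flux, and
#' the years-to-limit computed.  Because the time is a monotone
#' (decreasing) function of the concentration, the simulated median time
#' converges on the deterministic time evaluated at the distribution
#' median, which serves as the simulation's analytic oracle.
#'
#' Quantiles are taken with `type = 1` (inverse empirical CDF) so that
#' infinite draws (metals whose flux cannot reach the limit) never
#' produce NaN by interpolation.
#'
#' @param specs Named list of `fr_distspec` covering all seven metals.
#' @param params An `fr_region` object.
#' @param soil_limits Named soil limits, mg/kg.
#' @param n_iterations Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed (required).
#' @param report_quantiles Probabilities to report (default 5%, 50%,
#'   95%).
#' @param horizons Optional year horizons; for each, the probability
#'   that the limit is reached within it is reported.
#' @return Data frame of class `fr_mc_time`: per metal the requested
#'   quantiles of T (columns `T_q<pct>`) and any horizon probabilities
#'   (columns `p_within_<h>`).
#' @export
#' @examples
#' mc <- mc_time_to_limit(region_distribution_specs("north"),
#'                        load_region_parameters("north"),
#'                        n_iterations = 1000, seed = 7)
#' mc["Zn", "T_q50"]  # ~39 years
mc_time_to_limit <- function(specs, params,
                             soil_limits = load_soil_limits(),
                             n_iterations = 1e5, seed,
                             report_quantiles = c(0.05, 0.5, 0.95),
                             horizons = NULL) {
  stopifnot(inherits(params, "fr_region"),
            all(trace_metals() %in% names(specs)),
            n_iterations >= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(all(report_quantiles >= 0 & report_quantiles <= 1))
  set.seed(as.integer(seed))

  rows <- lapply(trace_metals(), function(m) {
    alpha <- draw_spec(specs[[m]], n_iterations)
    Qp <- annual_input(alpha, params)
    tt <- time_to_limit(rep(params$Q0[[m]], n_iterations), Qp,
                        soil_limits[[m]])$years
    q <- if (all(is.infinite(tt))) {
      rep(Inf, length(report_quantiles))
    } else {
      as.numeric(stats::quantile(tt, report_quantiles, type = 1,
                                 names = FALSE))
    }
    row <- data.frame(metal = m, stringsAsFactors = FALSE)
    for (k in seq_along(report_quantiles)) {
      row[[sprintf("T_q%02d", round(100 * report_quantiles[k]))]] <- q[k]
    }
    for (h in horizons) {
      row[[sprintf("p_within_%g", h)]] <- mean(tt <= h)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metal
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("fr_mc_time", "data.frame")
  out
}
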