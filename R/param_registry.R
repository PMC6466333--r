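#' Load regional soil and application parameters
#'
#' Returns the soil background concentrations `Q0` (mg/kg), soil bulk
#' density `rho_b` (g/cm^3), annual organic fertilizer application rate
#' `IR_f` (t/hm^2/yr) and plow-layer volume `V_plow` (m^3/hm^2, 20 cm
#' depth) for one of the three surveyed regions, or a pooled
#' `"northern"` aggregate.
#'
#' The pooled aggregate is built from the three regional rows:
#' backgrounds and bulk density are sample-size-weighted means (default
#' weights 48/55/14, the regional survey sizes), while the application
#' rate is the unweighted arithmetic mean of the three regional rates.
#'
#' @param region_name One of `"north"`, `"northwest"`, `"northeast"`, or
#'   `"northern"` for the pooled aggregate.
#' @param weights Optional numeric vector of length 3 (north, northwest,
#'   northeast) overriding the sample-size weights used for the pooled
#'   aggregate.
#' @return An object of class `fr_region`: a list with elements
#'   `region_name`, `Q0` (named numeric, all seven metals), `rho_b`,
#'   `IR_f`, `V_plow` (2000), and `n_samples`.
#' @export
#' @examples
#' p <- load_region_parameters("north")
#' p$IR_f          # 33.92 t/hm^2/yr
#' p$Q0[["Zn"]]    # 67.30 mg/kg
load_region_parameters <- function(region_name, weights = NULL) {
  tab <- read_param_csv("region_params.csv")
  regions <- tab$region
  if (!is.character(region_name) || length(region_name) != 1L) {
    stop("'region_name' must be a single region name", call. = FALSE)
  }
  q0_cols <- paste0("Q0_", trace_metals())

  if (region_name %in% regions) {
    row <- tab[tab$region == region_name, , drop = FALSE]
    Q0 <- as.numeric(row[1, q0_cols])
    names(Q0) <- trace_metals()
    out <- list(region_name = region_name, Q0 = Q0,
                rho_b = row$rho_b, IR_f = row$IR_f,
                V_plow = 2000, n_samples = row$n_samples)
  } else if (identical(region_name, "northern")) {
    if (is.null(weights)) weights <- tab$n_samples
    if (length(weights) != nrow(tab) || any(weights < 0) || sum(weights) <= 0) {
      stop("'weights' must be non-negative, one per region, with positive sum",
           call. = FALSE)
    }
    w <- weights / sum(weights)
    Q0 <- colSums(as.matrix(tab[, q0_cols]) * w)
    names(Q0) <- trace_metals()
    out <- list(region_name = "northern", Q0 = Q0,
                rho_b = sum(tab$rho_b * w),
                IR_f = mean(tab$IR_f),
                V_plow = 2000, n_samples = sum(tab$n_samples))
  } else {
    stop(sprintf("unknown region '%s'; valid regions: %s",
                 region_name,
                 paste(c(regions, "northern"), collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(all(out$Q0 > 0), out$rho_b > 0, out$IR_f > 0)
  structure(out, class = "fr_region")
}

#' @export
print.fr_region <- function(x, ...) {
  cat(sprintf("Region parameters: %s (n = %d samples)\n",
              x$region_name, x$n_samples))
  cat(sprintf("  rho_b = %.4g g/cm3, IR_f = %.4g t/hm2/yr, V_plow = %g m3/hm2\n",
              x$rho_b, x$IR_f, x$V_plow))
  cat("  Soil background Q0 (mg/kg):\n")
  print(round(x$Q0, 4))
  invisible(x)
}

#' Load human exposure constants
#'
#' All constants of the three-pathway exposure model: soil ingestion rate,
#' exposure frequency and duration, body weight, lifetime averaging time,
#' dermal contact parameters, particulate inhalation parameters, and the
#' per-metal absorption coefficients `beta` (gastrointestinal), `gamma`
#' (skin), and `theta` (lung).
#'
#' @return An object of class `fr_exposure`: a list of scalar constants
#'   (`IR_p`, `EF_a`, `ED_a`, `BW`, `LT`, `EV`, `SA`, `mu`, `eta`,
#'   `omega`, `IR_b`, `f_spod`, `EFOD_a`, `f_spid`, `EFID_a`) plus named
#'   numeric vectors `beta`, `gamma`, `theta` over the seven metals.
#' @export
#' @examples
#' ep <- load_exposure_parameters()
#' ep$beta[["Cd"]]   # 0.05
#' ep$theta[["Cr"]]  # 1 (assumed, no literature value)
load_exposure_parameters <- function() {
  tab <- read_param_csv("exposure_params.csv")
  scalars <- tab[is.na(tab$metal) | tab$metal == "", ]
  out <- as.list(stats::setNames(scalars$value, scalars$parameter))
  for (coef in c("beta", "gamma", "theta")) {
    rows <- tab[tab$parameter == coef & !is.na(tab$metal) & tab$metal != "", ]
    v <- stats::setNames(rows$value, rows$metal)[trace_metals()]
    if (anyNA(v)) stop(sprintf("packaged '%s' incomplete", coef))
    out[[coef]] <- v
  }
  stopifnot(all(out$beta >= 0 & out$beta <= 1),
            all(out$gamma >= 0 & out$gamma <= 1),
            all(out$theta >= 0 & out$theta <= 1))
  structure(out, class = "fr_exposure")
}

#' Load toxicity reference values
#'
#' Route-specific reference doses (`RfD_f` oral, `RfD_s` dermal, `RfD_b`
#' inhalation; mg/kg/day) for all seven metals, and cancer slope factors
#' (`SF`; kg day/mg) for the four carcinogens Cr, Ni, As, Cd.  `SF` is
#' `NA` for Cu, Zn, Pb.
#'
#' @return A data frame of class `fr_toxicity` with row names the metal
#'   symbols and columns `SF`, `RfD_f`, `RfD_s`, `RfD_b`.
#' @export
#' @examples
#' tox <- load_toxicity_parameters()
#' tox["Cr", "RfD_s"]  # 2.9e-5
#' tox["As", "SF"]     # 15.1
load_toxicity_parameters <- function() {
  tab <- read_param_csv("toxicity.csv")
  rownames(tab) <- tab$metal
  tab <- tab[trace_metals(), c("SF", "RfD_f", "RfD_s", "RfD_b")]
  stopifnot(all(tab$RfD_f > 0), all(tab$RfD_s > 0), all(tab$RfD_b > 0),
            identical(rownames(tab)[!is.na(tab$SF)], carcinogens()))
  class(tab) <- c("fr_toxicity", "data.frame")
  tab
}

#' Fertilizer limit standards for one jurisdiction
#'
#' Maximum acceptable trace-metal concentrations (mg/kg dry weight) in
#' compost / organic fertilizer for a national or regional standard.
#' Metals a standard does not regulate are omitted from the result (never
#' returned as zero).
#'
#' @param jurisdiction_id Identifier of a packaged standard, e.g.
#'   `"china_ny525"`, `"germany_I"`, `"us_uscc"`.  See
#'   [list_jurisdictions()].
#' @return Named numeric vector of limits for the regulated metals only.
#' @export
#' @examples
#' load_standards("china_ny525")  # Cr 300, As 30, Cd 3, Pb 100
load_standards <- function(jurisdiction_id) {
  tab <- read_param_csv("fertilizer_standards.csv")
  if (!is.character(jurisdiction_id) || length(jurisdiction_id) != 1L ||
      !jurisdiction_id %in% tab$jurisdiction) {
    stop(sprintf("unknown jurisdiction '%s'; available: %s",
                 as.character(jurisdiction_id)[1],
                 paste(tab$jurisdiction, collapse = ", ")),
         call. = FALSE)
  }
  row <- tab[tab$jurisdiction == jurisdiction_id, trace_metals()]
  lim <- stats::setNames(as.numeric(row), trace_metals())
  lim <- lim[!is.na(lim)]
  stopifnot(all(lim > 0))
  lim
}

#' List packaged fertilizer-standard jurisdictions
#'
#' @return Data frame with columns `jurisdiction`, `label`,
#'   `standard_file`.
#' @export
list_jurisdictions <- function() {
  tab <- read_param_csv("fertilizer_standards.csv")
  tab[, c("jurisdiction", "label", "standard_file")]
}

#' Soil quality limits (GB15618-2018, dry land, pH > 7.5)
#'
#' The maximum permissible soil concentrations `Cs` used as the
#' accumulation endpoint: Cr 250, Ni 190, Cu 100, Zn 300, As 25, Cd 0.6,
#' Pb 170 mg/kg.
#'
#' @return Named numeric vector over the seven metals.
#' @export
load_soil_limits <- function() {
  tab <- read_param_csv("soil_limits.csv")
  lim <- stats::setNames(tab$limit, tab$metal)[trace_metals()]
  stopifnot(!anyNA(lim), all(lim > 0))
  lim
}

#' Published survey summary statistics
#'
#' Per-region, per-metal summary of the fertilizer survey (range, mean,
#' median, SD, CV%, Shapiro-Wilk p-value) used to parameterize the
#' synthetic survey generator and the accumulation model medians.
#'
#' @param region Optional region filter (`"north"`, `"northwest"`,
#'   `"northeast"`, `"northern"`); `NULL` returns all rows.
#' @return Data frame with columns `region`, `metal`, `range_low`,
#'   `range_high`, `mean`, `median`, `sd`, `cv`, `shapiro_p`.
#' @export
load_survey_summary <- function(region = NULL) {
  tab <- read_param_csv("survey_summary.csv")
  if (!is.null(region)) {
    if (!region %in% tab$region) {
      stop(sprintf("unknown region '%s'; valid regions: %s", region,
                   paste(unique(tab$region), collapse = ", ")),
           call. = FALSE)
    }
    tab <- tab[tab$region == region, ]
    rownames(tab) <- tab$metal
  }
  tab
}

#' Survey median concentrations for a region
#'
#' Convenience accessor: the per-metal median fertilizer concentrations
#' (mg/kg DW) driving the deterministic accumulation model.
#'
#' @inheritParams load_survey_summary
#' @return Named numeric vector over the seven metals.
#' @export
survey_medians <- function(region) {
  tab <- load_survey_summary(region)
  stats::setNames(tab$median, tab$metal)[trace_metals()]
}
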