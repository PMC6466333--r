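#' Build a concentration distribution from summary statistics
#'
#' Constructs the sampling distribution for one metal's fertilizer
#' concentration from its reported median, coefficient of variation, and
#' observed range.  For the default lognormal family the log-scale
#' location is `log(median)` and the log-scale spread is solved from the
#' CV through the closed form `sdlog^2 = log(1 + (cv/100)^2)` (the
#' mean/sd ratio of a lognormal depends only on `sdlog`).  `cv = 0`
#' degenerates to a point mass at the median.
#'
#' The observed range is stored as metadata.  By default it is *not*
#' used to truncate the distribution: the extrema of a modest survey are
#' order statistics, not support bounds, and hard truncation at them
#' systematically shrinks the upper tail (the sample CV of heavy-tailed
#' metals drops ~20% below its target).  Set `truncate = TRUE` to draw
#' from the range-truncated distribution instead (rejection sampling, so
#' no boundary atoms).
#'
#' @param median Target median, mg/kg (> 0).
#' @param cv Target coefficient of variation, percent (>= 0).
#' @param range_low,range_high Observed concentration range, mg/kg.
#' @param family `"lognormal"` (parametric, default) or `"empirical"`
#'   (resample `values` with replacement).
#' @param values Numeric vector of observed concentrations, required for
#'   the empirical family.
#' @param truncate Logical; restrict draws to `[range_low, range_high]`.
#' @return An object of class `fr_distspec`.
#' @export
#' @examples
#' sp <- spec_from_summary(478.11, 73.83, 0.50, 1595.42)
#' sp$sdlog  # sqrt(log(1 + 0.7383^2))
spec_from_summary <- function(median, cv, range_low = 0, range_high = Inf,
                              family = c("lognormal", "empirical"),
                              values = NULL, truncate = FALSE) {
  family <- match.arg(family)
  stop_not_numeric_scalar(median, "median")
  stop_not_numeric_scalar(cv, "cv")
  if (median <= 0) stop("'median' must be > 0", call. = FALSE)
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  if (range_low < 0 || range_high < range_low) {
    stop("range must satisfy 0 <= range_low <= range_high", call. = FALSE)
  }
  if (truncate && (median < range_low || median > range_high)) {
    stop("'median' must lie inside the truncation range", call. = FALSE)
  }
  if (family == "empirical" && (is.null(values) || !length(values))) {
    stop("family 'empirical' requires 'values'", call. = FALSE)
  }
  structure(list(median = median, cv = cv,
                 range_low = range_low, range_high = range_high,
                 family = family, values = values, truncate = truncate,
                 meanlog = log(median),
                 sdlog = sqrt(log1p((cv / 100)^2))),
            class = "fr_distspec")
}

#' @export
print.fr_distspec <- function(x, ...) {
  cat(sprintf("%s concentration spec: median %.4g, CV %.4g%%%s\n",
              x$family, x$median, x$cv,
              if (x$truncate)
                sprintf(", truncated to [%.4g, %.4g]",
                        x$range_low, x$range_high)
              else ""))
  invisible(x)
}

#' Distribution specs for every metal of a surveyed region
#'
#' Builds the seven per-metal [spec_from_summary()] objects from the
#' packaged survey summary of a region.
#'
#' @inheritParams load_survey_summary
#' @param truncate Logical, passed to [spec_from_summary()].
#' @return Named list of `fr_distspec`, one per metal, canonical order.
#' @export
region_distribution_specs <- function(region, truncate = FALSE) {
  tab <- load_survey_summary(region)
  specs <- lapply(trace_metals(), function(m) {
    r <- tab[m, ]
    spec_from_summary(r$median, r$cv, r$range_low, r$range_high,
                      truncate = truncate)
  })
  stats::setNames(specs, trace_metals())
}

# Rejection sampler for a (possibly truncated) spec.  Truncation by
# resampling, never clipping; capped at ~1e6 attempts per requested draw.
draw_spec <- function(spec, n) {
  stopifnot(inherits(spec, "fr_distspec"), n >= 0)
  if (n == 0) return(numeric(0))
  lo <- if (spec$truncate) spec$range_low else 0
  hi <- if (spec$truncate) spec$range_high else Inf

  if (spec$family == "empirical") {
    pool <- spec$values[spec$values >= lo & spec$values <= hi]
    if (!length(pool)) {
      stop("truncation range excludes every empirical value", call. = FALSE)
    }
    return(sample(pool, n, replace = TRUE))
  }
  if (spec$sdlog == 0) {              # point mass at the median
    if (spec$median < lo || spec$median > hi) {
      stop("truncation range excludes the point mass", call. = FALSE)
    }
    return(rep(spec$median, n))
  }
  if (spec$truncate) {
    mass <- stats::plnorm(hi, spec$meanlog, spec$sdlog) -
      stats::plnorm(lo, spec$meanlog, spec$sdlog)
    if (mass <= 1e-12) {
      stop("truncation range excludes essentially all distribution mass",
           call. = FALSE)
    }
  }
  out <- numeric(0)
  attempts <- 0
  while (length(out) < n) {
    x <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    out <- c(out, x[x >= lo & x <= hi])
    attempts <- attempts + n
    if (attempts > 1e6 * n) {
      stop("rejection sampling failed: range retains too little mass",
           call. = FALSE)
    }
  }
  out[seq_len(n)]
}

# Quantile function of a (truncated) spec, for copula draws (u in [0,1]).
quantile_spec <- function(spec, u) {
  if (spec$family == "empirical") {
    pool <- sort(spec$values)
    return(pool[pmax(1L, ceiling(u * length(pool)))])
  }
  if (spec$sdlog == 0) return(rep(spec$median, length(u)))
  lo <- if (spec$truncate) spec$range_low else 0
  hi <- if (spec$truncate) spec$range_high else Inf
  Fa <- stats::plnorm(lo, spec$meanlog, spec$sdlog)
  Fb <- stats::plnorm(hi, spec$meanlog, spec$sdlog)
  stats::qlnorm(Fa + u * (Fb - Fa), spec$meanlog, spec$sdlog)
}

#' Generate a synthetic fertilizer survey
#'
#' Draws `n` fertilizer samples with one concentration per metal from the
#' supplied distribution specs, reproducibly under a fixed seed.  Metals
#' are independent by default; supplying a Spearman rank-correlation
#' matrix induces dependence through a Gaussian copula (rank correlations
#' converted to the copula's Pearson parameter by `2 sin(pi rho / 6)`).
#'
#' @param specs Named list of [spec_from_summary()] objects covering all
#'   seven metals (e.g. from [region_distribution_specs()]).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; required, so every table is reproducible.
#' @param region Region label written into the table.
#' @param rank_corr Optional 7x7 Spearman rank-correlation matrix
#'   (canonical metal order) for correlated generation.
#' @return A concentration table: data frame with columns `sample_id`,
#'   `region`, and the seven metals (mg/kg DW).
#' @export
#' @examples
#' specs <- region_distribution_specs("north")
#' tab <- generate_samples(specs, n = 48, seed = 1, region = "north")
generate_samples <- function(specs, n, seed, region = "synthetic",
                             rank_corr = NULL) {
  if (!is.list(specs) || !all(trace_metals() %in% names(specs))) {
    stop("'specs' must be a named list covering all seven metals",
         call. = FALSE)
  }
  stop_not_numeric_scalar(n, "n")
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  stop_not_numeric_scalar(seed, "seed")
  set.seed(as.integer(seed))

  if (is.null(rank_corr)) {
    conc <- lapply(trace_metals(), function(m) draw_spec(specs[[m]], n))
  } else {
    stopifnot(is.matrix(rank_corr), all(dim(rank_corr) == 7L),
              isTRUE(all.equal(rank_corr, t(rank_corr))),
              all(diag(rank_corr) == 1))
    pearson <- 2 * sin(pi * rank_corr / 6)
    diag(pearson) <- 1
    L <- chol(pearson)
    z <- matrix(stats::rnorm(n * 7L), nrow = n) %*% L
    u <- stats::pnorm(z)
    conc <- lapply(seq_along(trace_metals()), function(i) {
      quantile_spec(specs[[trace_metals()[i]]], u[, i])
    })
  }
  out <- data.frame(sample_id = sprintf("%s_%04d", region, seq_len(n)),
                    region = region, stringsAsFactors = FALSE)
  for (i in seq_along(trace_metals())) out[[trace_metals()[i]]] <- conc[[i]]
  validate_concentration_table(out)
}
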