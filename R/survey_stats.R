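# Descriptive statistics, normality testing, rank correlation, and
# standards-exceedance screening of a concentration table.

#' Summarize a fertilizer concentration table
#'
#' Per-metal minimum, maximum, mean, median, sample standard deviation
#' (n - 1 denominator), coefficient of variation (100 * sd / mean), and
#' Shapiro-Wilk normality p-value on the raw concentrations.  The
#' Shapiro p-value is `NA` when fewer than 3 samples are available or
#' the column is constant.
#'
#' @param table A concentration table (see [read_concentration_table()]
#'   or [generate_samples()]).
#' @return Data frame with one row per metal: `metal`, `n`, `min`,
#'   `max`, `mean`, `median`, `sd`, `cv`, `shapiro_p`.
#' @export
#' @examples
#' tab <- generate_samples(region_distribution_specs("north"), 48, seed = 1)
#' summarize_survey(tab)
summarize_survey <- function(table) {
  table <- validate_concentration_table(table)
  rows <- lapply(trace_metals(), function(m) {
    x <- table[[m]]
    n <- length(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    sw <- NA_real_
    if (n >= 3 && n <= 5000 && isTRUE(s > 0)) {
      sw <- stats::shapiro.test(x)$p.value
    }
    data.frame(metal = m, n = n, min = min(x), max = max(x),
               mean = mean(x), median = stats::median(x), sd = s,
               cv = if (isTRUE(mean(x) > 0)) 100 * s / mean(x) else NA_real_,
               shapiro_p = sw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metal
  out
}

#' Spearman rank correlation matrix of the seven metals
#'
#' Midrank-tie Spearman correlations with two-sided p-values: the
#' t-approximation for n > 10, the exact null distribution (ties
#' permitting) for n <= 10.  Pairs involving a constant column are `NA`;
#' the diagonal is exactly 1.
#'
#' @param table A concentration table with at least 4 samples.
#' @return List of class `fr_corr` with 7x7 matrices `rho` and `p`,
#'   logical matrices `sig05` and `sig01`, and the sample size `n`.
#' @export
spearman_matrix <- function(table) {
  table <- validate_concentration_table(table)
  X <- as.matrix(table[, trace_metals()])
  n <- nrow(X)
  if (n < 4) stop("at least 4 samples are required", call. = FALSE)

  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  constant <- apply(X, 2, function(x) length(unique(x)) == 1L)
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho)[!constant] <- 1

  p <- matrix(NA_real_, 7, 7, dimnames = dimnames(rho))
  for (i in 1:6) {
    for (j in (i + 1):7) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(
        stats::cor.test(X[, i], X[, j], method = "spearman",
                        exact = n <= 10, alternative = "two.sided"))
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p,
                 sig05 = !is.na(p) & p < 0.05,
                 sig01 = !is.na(p) & p < 0.01,
                 n = n),
            class = "fr_corr")
}

#' @export
print.fr_corr <- function(x, ...) {
  cat(sprintf("Spearman correlation of %d samples (* p<0.05, ** p<0.01)\n",
              x$n))
  m <- format(round(x$rho, 2))
  m[x$sig05] <- paste0(m[x$sig05], "*")
  m[x$sig01] <- paste0(m[x$sig01], "*")
  print(m, quote = FALSE)
  invisible(x)
}

#' Exceedance screening against fertilizer limit standards
#'
#' Counts, per metal, the samples whose concentration strictly exceeds
#' the supplied limit (a sample exactly at the limit complies: limits
#' are maximum acceptable concentrations).  Metals without a limit are
#' flagged unregulated and excluded from the rates.
#'
#' @param table A concentration table.
#' @param limits Named numeric vector of limits (mg/kg DW), e.g. from
#'   [load_standards()]; metals absent from `limits` are unregulated.
#' @param jurisdiction_id Optional label recorded in the report.
#' @return Data frame with one row per metal: `metal`, `limit`,
#'   `n_tested`, `n_exceeding`, `rate` (percent), `regulated`.  The
#'   jurisdiction label is kept as attribute `"jurisdiction"`.
#' @export
#' @examples
#' tab <- generate_samples(region_distribution_specs("north"), 117, seed = 1)
#' exceedance_rates(tab, load_standards("china_ny525"), "china_ny525")
exceedance_rates <- function(table, limits, jurisdiction_id = NULL) {
  table <- validate_concentration_table(table)
  if (nrow(table) == 0) stop("'table' must be nonempty", call. = FALSE)
  stopifnot(is.numeric(limits), !is.null(names(limits)))
  rows <- lapply(trace_metals(), function(m) {
    x <- table[[m]]
    if (m %in% names(limits) && is.finite(limits[[m]])) {
      ne <- sum(x > limits[[m]])
      data.frame(metal = m, limit = limits[[m]], n_tested = length(x),
                 n_exceeding = ne, rate = 100 * ne / length(x),
                 regulated = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(metal = m, limit = NA_real_, n_tested = length(x),
                 n_exceeding = NA_integer_, rate = NA_real_,
                 regulated = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metal
  attr(out, "jurisdiction") <- jurisdiction_id
  out
}
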