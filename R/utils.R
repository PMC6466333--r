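# Internal helpers shared across modules.

# round() in R is round-half-even; the published tables round half away
# from zero, so time-to-limit comparisons need an explicit half-up rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Path to a packaged parameter file.
param_file <- function(name) {
  system.file("extdata", "params", name, package = "fertrisk", mustWork = TRUE)
}

read_param_csv <- function(name, ...) {
  utils::read.csv(param_file(name), stringsAsFactors = FALSE,
                  check.names = FALSE, ...)
}

stop_not_numeric_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", what), call. = FALSE)
  }
}
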