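# Frozen reference values for the regional assessment tables, and small
# fixture builders.  All numbers were transcribed from the published
# regional tables and independently re-derived from the model equations
# before being frozen here.

# Annual input flux (mg/kg/yr, as printed) and integer years-to-limit
# per region.  Metal order: Cr, Ni, Cu, Zn, As, Cd, Pb.
ref_accumulation <- list(
  north = list(
    Qp = c(0.21, 0.21, 0.56, 6.01, 0.087, 0.0048, 0.19),
    T  = c(928, 774, 141, 39, 187, 107, 784)),
  northwest = list(
    Qp = c(0.37, 0.37, 0.68, 2.95, 0.17, 0.011, 0.39),
    T  = c(504, 421, 115, 78, 76, 46, 387)),
  northeast = list(
    Qp = c(0.72, 0.46, 0.95, 2.50, 0.37, 0.0070, 0.40),
    T  = c(275, 364, 86, 90, 46, 73, 359))
)

# Reproduce the mixed print format of the flux row: two decimals for
# values >= 0.1, two significant figures below.
format_like_flux_row <- function(x) {
  ifelse(x >= 0.1, fertrisk:::round_half_up(x, 2), signif(x, 2))
}

# Hazard quotients per pathway (oral f / dermal s / respiratory b) and
# comprehensive HI, per region.
ref_hq <- list(
  north = list(
    f = c(Cr = 1.81e-4, Ni = 8.70e-6, Cu = 2.21e-4, Zn = 1.04e-4,
          As = 1.22e-2, Cd = 2.01e-6, Pb = 2.14e-3),
    s = c(Cr = 1.09e-1, Ni = 5.05e-5, Cu = 1.28e-3, Zn = 5.95e-4,
          As = 7.09e-2, Cd = 1.17e-5, Pb = 1.24e-2),
    b = c(Cr = 1.58e-4, Ni = 5.64e-7, Cu = 1.29e-5, Zn = 8.96e-6,
          As = 5.34e-5, Cd = 3.51e-6, Pb = 2.52e-4),
    HI = 0.21),
  northwest = list(
    f = c(Cr = 2.31e-4, Ni = 1.10e-5, Cu = 2.42e-4, Zn = 1.01e-4,
          As = 1.74e-2, Cd = 2.63e-6, Pb = 2.50e-3),
    s = c(Cr = 1.39e-1, Ni = 6.41e-5, Cu = 1.41e-3, Zn = 5.86e-4,
          As = 1.01e-1, Cd = 1.53e-5, Pb = 1.45e-2),
    b = c(Cr = 2.02e-4, Ni = 7.15e-7, Cu = 1.41e-5, Zn = 8.82e-6,
          As = 7.63e-5, Cd = 4.60e-6, Pb = 2.93e-4),
    HI = 0.28),
  northeast = list(
    f = c(Cr = 1.86e-4, Ni = 7.56e-6, Cu = 2.04e-4, Zn = 1.09e-4,
          As = 1.12e-2, Cd = 2.09e-6, Pb = 3.22e-3),
    s = c(Cr = 1.12e-1, Ni = 4.39e-5, Cu = 1.19e-3, Zn = 6.33e-4,
          As = 6.51e-2, Cd = 1.22e-5, Pb = 1.87e-2),
    b = c(Cr = 1.63e-4, Ni = 4.90e-7, Cu = 1.19e-5, Zn = 9.54e-6,
          As = 4.90e-5, Cd = 3.67e-6, Pb = 3.79e-4),
    HI = 0.21)
)

# Cancer risks per pathway and total, per region.  The published
# northwest oral As entry (7.90e-4) contradicts that table's own
# all-pathway row (5.40e-4) and is a transcription slip for 7.90e-5,
# which is what is frozen here.
ref_cr <- list(
  north = list(
    f = c(Cr = 2.28e-5, Ni = 1.46e-7, As = 5.52e-5, Cd = 1.26e-8),
    s = c(Cr = 1.33e-4, Ni = 8.49e-7, As = 3.21e-4, Cd = 7.34e-8),
    b = c(Cr = 3.99e-7, Ni = 2.56e-9, As = 9.67e-7, Cd = 2.21e-10),
    TCR = 5.34e-4),
  northwest = list(
    f = c(Cr = 2.90e-5, Ni = 1.85e-7, As = 7.90e-5, Cd = 1.66e-8),
    s = c(Cr = 1.69e-4, Ni = 1.08e-6, As = 4.59e-4, Cd = 9.62e-8),
    b = c(Cr = 5.09e-7, Ni = 3.24e-9, As = 1.38e-6, Cd = 2.90e-10),
    TCR = 7.39e-4),
  northeast = list(
    f = c(Cr = 2.35e-5, Ni = 1.27e-7, As = 5.07e-5, Cd = 1.32e-8),
    s = c(Cr = 1.36e-4, Ni = 7.38e-7, As = 2.95e-4, Cd = 7.66e-8),
    b = c(Cr = 4.11e-7, Ni = 2.22e-9, As = 8.88e-7, Cd = 2.31e-10),
    TCR = 5.08e-4)
)

ref_hi_northern <- 0.24
ref_tcr_northern <- 6.29e-4

# A tiny hand-checkable concentration table: every metal takes the
# values 1, 2, 3 across three samples.
toy_table <- function(values = 1:3, region = "toy") {
  out <- data.frame(sample_id = paste0("s", seq_along(values)),
                    region = region, stringsAsFactors = FALSE)
  for (m in trace_metals()) out[[m]] <- as.numeric(values)
  out
}

# Concentration table with exact per-metal values supplied as a named
# list of equal-length vectors.
table_from_values <- function(values, region = "fixture") {
  n <- length(values[[1]])
  out <- data.frame(sample_id = paste0("s", seq_len(n)),
                    region = region, stringsAsFactors = FALSE)
  for (m in trace_metals()) out[[m]] <- values[[m]]
  out
}
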