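test_that("annual input flux matches independent hand arithmetic", {
  nc <- load_region_parameters("north")
  # Zn: 33.92 t/hm2/yr * 478.11 mg/kg / (1.35 t/m3 * 2000 m3/hm2)
  expect_equal(annual_input(478.11, nc), 33.92 * 478.11 / (1.35 * 2000))
  expect_equal(round(annual_input(478.11, nc), 2), 6.01)
  nw <- load_region_parameters("northwest")
  expect_equal(round(annual_input(19.84, nw), 2), 0.68)
  expect_equal(annual_input(0, nc), 0)
  expect_error(annual_input(-1, nc), ">= 0")
  bad <- nc; bad$rho_b <- 0
  expect_error(annual_input(1, bad), "positive")
})

test_that("cumulative concentration is affine in years", {
  expect_equal(cumulative_concentration(51.6, 0.2138, 0), 51.6)
  expect_equal(cumulative_concentration(51.6, 0.2138, 1), 51.8138)
  q2 <- cumulative_concentration(10, 0.5, 2)
  q1 <- cumulative_concentration(10, 0.5, 1)
  expect_equal(q2 - q1, 0.5)
  expect_error(cumulative_concentration(10, 0.5, -1), ">= 0")
})

test_that("time to limit satisfies its closed-form identity exactly", {
  tt <- time_to_limit(67.3, 6.0065, 300)
  expect_equal(67.3 + tt$years * 6.0065, 300)   # machine-precision identity
  cases <- expand.grid(Q0 = c(0.1, 20, 60), Qp = c(0.01, 0.5, 4),
                       Cs = c(25, 100, 300))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      r <- time_to_limit(Q0, Qp, Cs)
      if (is.finite(r$years) && !r$already_exceeding) {
        expect_equal(Q0 + r$years * Qp, Cs)
      }
    })
  }
  # degenerate cases are encoded in the result, not errors
  expect_equal(time_to_limit(10, 0, 25)$years, Inf)
  z <- time_to_limit(30, 1, 25)
  expect_equal(z$years, 0)
  expect_true(z$already_exceeding)
  expect_error(time_to_limit(10, 1, 0), "> 0")
})

test_that("time to limit is monotone in each driver", {
  p <- load_region_parameters("north")
  t_base <- time_to_limit(50, annual_input(100, p), 250)$years
  # more concentrated fertilizer or heavier application: sooner
  expect_lt(time_to_limit(50, annual_input(150, p), 250)$years, t_base)
  p_heavy <- p; p_heavy$IR_f <- p$IR_f * 2
  expect_lt(time_to_limit(50, annual_input(100, p_heavy), 250)$years, t_base)
  # denser soil or a looser limit: later
  p_dense <- p; p_dense$rho_b <- p$rho_b * 1.5
  expect_gt(time_to_limit(50, annual_input(100, p_dense), 250)$years, t_base)
  expect_gt(time_to_limit(50, annual_input(100, p), 400)$years, t_base)
})

test_that("the regional accumulation tables reproduce the reference rows", {
  for (r in names(ref_accumulation)) {
    acc <- accumulation_table(load_region_parameters(r))
    expect_equal(format_like_flux_row(acc$Qp), ref_accumulation[[r]]$Qp,
                 label = paste(r, "flux row"))
    expect_equal(acc$T_rounded, ref_accumulation[[r]]$T,
                 label = paste(r, "time row"))
  }
  # rounding chains from the unrounded flux: a pre-rounded flux would
  # give 944 years for Cr in the north instead of 928
  nc <- accumulation_table(load_region_parameters("north"))
  expect_equal(nc["Cr", "T_rounded"], 928)
  expect_equal(fertrisk:::round_half_up((250 - 51.6) / 0.21), 945)
})

test_that("the pooled northern row reproduces its anchor metals", {
  acc <- accumulation_table(load_region_parameters("northern"))
  expect_equal(acc[c("Zn", "Cd", "As"), "T_rounded"], c(53, 53, 82),
               ignore_attr = TRUE)
  expect_equal(min(acc$T_rounded), 53)
})

test_that("a point-mass spec makes the simulation collapse to the deterministic time", {
  med <- survey_medians("north")
  specs <- lapply(trace_metals(), function(m) spec_from_summary(med[[m]], 0))
  names(specs) <- trace_metals()
  p <- load_region_parameters("north")
  mc <- mc_time_to_limit(specs, p, n_iterations = 50, seed = 1)
  det <- accumulation_table(p)
  expect_equal(mc$T_q05, det$T_years)
  expect_equal(mc$T_q50, det$T_years)
  expect_equal(mc$T_q95, det$T_years)
})

test_that("simulated median times track the deterministic median-input times", {
  # T is monotone in the concentration, so the simulation median must
  # converge on the deterministic time at the distribution median
  p <- load_region_parameters("north")
  mc <- mc_time_to_limit(region_distribution_specs("north"), p,
                         n_iterations = 2e4, seed = 7)
  det <- accumulation_table(p)
  expect_true(all(abs(mc$T_q50 / det$T_years - 1) < 0.03))
  expect_true(all(diff(unlist(mc["Zn", c("T_q05", "T_q50", "T_q95")])) > 0))
})

test_that("simulation respects the seed and the application-rate scaling law", {
  p <- load_region_parameters("northwest")
  specs <- region_distribution_specs("northwest")
  m1 <- mc_time_to_limit(specs, p, n_iterations = 500, seed = 3)
  m2 <- mc_time_to_limit(specs, p, n_iterations = 500, seed = 3)
  expect_identical(m1, m2)
  # doubling the application rate halves every time, draw for draw
  p2 <- p; p2$IR_f <- 2 * p$IR_f
  m3 <- mc_time_to_limit(specs, p2, n_iterations = 500, seed = 3)
  expect_equal(m3$T_q50, m1$T_q50 / 2)
  expect_equal(m3$T_q05, m1$T_q05 / 2)
})

test_that("metals that cannot reach the limit report infinite quantiles", {
  p <- load_region_parameters("north")
  sp0 <- spec_from_summary(1e-9, 0)
  specs <- stats::setNames(rep(list(sp0), 7), trace_metals())
  p$Q0[] <- 1e-6
  mc <- mc_time_to_limit(specs, p, n_iterations = 20, seed = 1,
                         horizons = c(50, 1e9))
  expect_true(all(is.finite(mc$T_q50)))   # tiny but positive flux
  sp_zero <- spec_from_summary(1e-300, 0)
  specs$Zn <- sp_zero
  mc2 <- mc_time_to_limit(specs, p, n_iterations = 20, seed = 1)
  expect_lt(mc2["Cd", "T_q50"], Inf)
  expect_equal(mc2["Zn", "T_q50"] > 1e100, TRUE)
})
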