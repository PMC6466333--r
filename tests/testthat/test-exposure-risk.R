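ep <- load_exposure_parameters()
tox <- load_toxicity_parameters()

test_that("pathway doses match independent hand arithmetic", {
  # oral, As at the north-China exposed concentration
  q_f <- 8.737 * 100 * 250 * 25 * 1.0 / (56.8 * 26280) * 1e-6
  expect_equal(oral_dose(8.737, ep, "As"), q_f, ignore_attr = TRUE)
  expect_equal(q_f / 3e-4, 1.22e-2, tolerance = 0.005)
  # dermal, full factor chain with SA in cm2
  q_s <- 8.737 * 1 * (1.614 * 1e4) * 0.18 * 0.2 * 250 * 25 * 1.0 /
    (56.8 * 26280) * 1e-6
  expect_equal(dermal_dose(8.737, ep, "As"), q_s, ignore_attr = TRUE)
  # respiratory, outdoor + indoor suspended-particle terms
  q_b <- 0.0958 * 0.15 * 14.5 * 25 * 0.05 * (0.8 * 87.5 + 0.5 * 262.5) /
    (56.8 * 26280) * 1e-6
  expect_equal(respiratory_dose(0.0958, ep, "Cd"), q_b, ignore_attr = TRUE)
  expect_equal(q_b / 1e-5, 3.51e-6, tolerance = 0.005)
  # zero concentration, zero dose
  expect_equal(oral_dose(0, ep, "Cr"), 0, ignore_attr = TRUE)
  expect_error(dermal_dose(-1, ep, "Cr"), ">= 0")
})

test_that("every dose is exactly linear in the soil concentration", {
  Qi <- stats::setNames(c(51.8, 26, 21, 73, 8.7, 0.096, 17.8),
                        trace_metals())
  for (k in c(0.5, 2, 10)) {
    d1 <- dose_profile(Qi, ep)
    dk <- dose_profile(k * Qi, ep)
    expect_equal(dk$Q_f, k * d1$Q_f)
    expect_equal(dk$Q_s, k * d1$Q_s)
    expect_equal(dk$Q_b, k * d1$Q_b)
  }
})

test_that("the two coefficient conventions differ by the documented ratios", {
  Qi <- stats::setNames(rep(10, 7), trace_metals())
  pub <- dose_profile(Qi, ep, mode = "as_published")
  wri <- dose_profile(Qi, ep, mode = "as_written")
  # oral identical; dermal scales by gamma/beta; inhalation by theta/beta
  expect_equal(wri$Q_f, pub$Q_f)
  expect_equal(wri$Q_s / pub$Q_s, unname(ep$gamma / ep$beta))
  expect_equal(wri$Q_b / pub$Q_b, unname(ep$theta / ep$beta))
  # Cr and As agree across modes on the inhalation route (theta = beta... = 1
  # only for the published convention with beta = 1; check As explicitly)
  expect_equal(wri["As", "Q_b"], pub["As", "Q_b"])
})

test_that("hazard quotients, HI, cancer risks and TCR decompose additively", {
  Qi <- stats::setNames(c(51.8, 26, 21, 73, 8.7, 0.096, 17.8),
                        trace_metals())
  doses <- dose_profile(Qi, ep)
  hi <- hazard_index(doses, tox)
  expect_equal(hi$HQ$HQ, hi$HQ$HQ_f + hi$HQ$HQ_s + hi$HQ$HQ_b)
  expect_equal(hi$HI, sum(hi$HQ$HQ))
  cr <- cancer_risk(doses, tox)
  expect_equal(cr$CR$CR, cr$CR$CR_f + cr$CR$CR_s + cr$CR$CR_b)
  expect_equal(cr$TCR, sum(cr$CR$CR))
  expect_identical(cr$CR$metal, carcinogens())
  # zero exposure, zero risk
  zero <- dose_profile(stats::setNames(rep(0, 7), trace_metals()), ep)
  expect_equal(hazard_index(zero, tox)$HI, 0)
  expect_equal(cancer_risk(zero, tox)$TCR, 0)
})

test_that("regional risk reports reproduce the reference hazard tables", {
  for (r in names(ref_hq)) {
    rr <- risk_report(load_region_parameters(r))
    hq <- rr$HQ
    for (m in trace_metals()) {
      expect_equal(hq[m, "HQ_f"], ref_hq[[r]]$f[[m]], tolerance = 0.02,
                   label = sprintf("%s oral HQ %s", r, m))
      expect_equal(hq[m, "HQ_s"], ref_hq[[r]]$s[[m]], tolerance = 0.02,
                   label = sprintf("%s dermal HQ %s", r, m))
      expect_equal(hq[m, "HQ_b"], ref_hq[[r]]$b[[m]], tolerance = 0.02,
                   label = sprintf("%s respiratory HQ %s", r, m))
    }
    expect_equal(round(rr$HI, 2), ref_hq[[r]]$HI)
  }
})

test_that("regional risk reports reproduce the reference cancer tables", {
  for (r in names(ref_cr)) {
    rr <- risk_report(load_region_parameters(r))
    cr <- rr$CR
    for (m in carcinogens()) {
      expect_equal(cr[m, "CR_f"], ref_cr[[r]]$f[[m]], tolerance = 0.02,
                   label = sprintf("%s oral CR %s", r, m))
      expect_equal(cr[m, "CR_s"], ref_cr[[r]]$s[[m]], tolerance = 0.02,
                   label = sprintf("%s dermal CR %s", r, m))
      expect_equal(cr[m, "CR_b"], ref_cr[[r]]$b[[m]], tolerance = 0.02,
                   label = sprintf("%s respiratory CR %s", r, m))
    }
    expect_equal(rr$TCR, ref_cr[[r]]$TCR, tolerance = 0.005)
  }
  # the pooled northern region
  rn <- risk_report(load_region_parameters("northern"))
  expect_equal(round(rn$HI, 2), ref_hi_northern)
  expect_equal(rn$TCR, ref_tcr_northern, tolerance = 0.005)
})

test_that("risk grading follows the two-way matrix", {
  expect_equal(unclass(risk_grade(0, 0)), "Low risk", ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.24, 6.29e-4)), "High risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.6, 5e-5)), "High risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.3, 5e-6)), "Moderate risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.8, 2e-4)), "Extreme risk",
               ignore_attr = TRUE)
  # bins are right-closed; exactly 1e-4 belongs to the explicit top band
  expect_equal(unclass(risk_grade(0.25, 1e-6)), "Low risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.2500001, 1e-6)), "Low risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.26, 1e-6)), "Low risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.26, 1.0000001e-6)), "Moderate risk",
               ignore_attr = TRUE)
  expect_equal(unclass(risk_grade(0.1, 1e-4)), "High risk",
               ignore_attr = TRUE)
  # HI beyond the table clamps to the extreme column with a flag
  g <- risk_grade(1.4, 1e-7)
  expect_equal(unclass(g), "High risk", ignore_attr = TRUE)
  expect_true(attr(g, "hi_exceeds_one"))
  expect_false(attr(risk_grade(0.9, 1e-7), "hi_exceeds_one"))
  expect_error(risk_grade(-0.1, 1e-6), ">= 0")
})

test_that("years to the HI threshold agree with a year-stepping oracle", {
  p <- load_region_parameters("north")
  n_star <- years_to_hi_threshold(p)
  # independent oracle: walk the hazard index year by year
  hi_at <- function(n) {
    Qp <- annual_input(survey_medians("north"), p)
    Qi <- p$Q0 + n * Qp
    hazard_index(dose_profile(Qi, ep), tox)$HI
  }
  lo <- floor(n_star); hi <- ceiling(n_star)
  expect_lt(hi_at(lo), 1)
  expect_gte(hi_at(hi), 1 - 1e-9)
  expect_equal(hi_at(n_star), 1)       # the crossing itself, exactly
  # affinity: doubling the flux halves the remaining margin
  p2 <- p; p2$IR_f <- 2 * p$IR_f
  expect_equal(years_to_hi_threshold(p2), n_star / 2)
  # threshold already met at year zero
  expect_equal(years_to_hi_threshold(p, threshold = 1e-6), 0)
})
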