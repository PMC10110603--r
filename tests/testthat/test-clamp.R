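test_that("series-resistance correction does exact unit arithmetic", {
  expect_equal(correct_series_resistance(-60, 0, 10), -60)
  expect_equal(correct_series_resistance(-60, 100, 10), -61)
  expect_equal(correct_series_resistance(-40, -200, 15), -37)
  expect_error(correct_series_resistance(-60, 100, -1), ">= 0")
  # exactness across 12 orders of magnitude of current: the correction is
  # bitwise the textbook expression, and the pure drop term is exact
  for (expo in -4:7) {
    i <- 10^expo
    expect_identical(correct_series_resistance(-60, i, 10),
                     -60 - i * 10 * 1e-3)
    expect_identical(correct_series_resistance(0, i, 10), -i * 10 * 1e-3)
  }
})

test_that("Nernst conversion matches a constant-by-constant evaluation", {
  p <- nernst_params(Cl_out = 132.5, temperature = 303.15)
  # independent evaluation, written out from the constants
  rt_f <- 8.314 * 303.15 / 96485 * 1000
  expect_equal(chloride_from_nernst(-70.7, p),
               132.5 * exp(-70.7 / rt_f), tolerance = 1e-12)
  expect_equal(chloride_from_nernst(-70.7, p), 8.8, tolerance = 0.01)
  expect_equal(nernst_potential(10.9, p), rt_f * log(10.9 / 132.5),
               tolerance = 1e-12)
  expect_equal(nernst_potential(10.9, p), -65.3, tolerance = 0.001)
  expect_equal(chloride_from_nernst(0, p), 132.5)
  expect_equal(nernst_potential(132.5, p), 0)
})

test_that("Nernst forward and inverse are exact inverses, and monotone", {
  p <- nernst_params(132.5)
  for (cl in c(0.5, 2, 8.8, 10.9, 50, 132.5, 400)) {
    back <- chloride_from_nernst(nernst_potential(cl, p), p)
    expect_lt(abs(back / cl - 1), 1e-9)
  }
  rt_f <- 1000 * p$R * p$temperature / p$F
  expect_equal(nernst_potential(20, p) - nernst_potential(10, p),
               rt_f * log(2), tolerance = 1e-12)
  expect_error(nernst_potential(0, p), "> 0")
  expect_error(nernst_params(Cl_out = 0), "> 0")
})

test_that("solution chloride accounting follows stoichiometry and refuses unknowns", {
  acsf <- c(NaCl = 126, KCl = 2.5, NaH2PO4 = 1.25, MgSO4 = 2,
            CaCl2 = 2, NaHCO3 = 26, glucose = 20)
  expect_equal(chloride_from_solution(acsf), 132.5)
  expect_equal(chloride_from_solution(c(KCl = 150, HEPES = 10)), 150)
  expect_equal(chloride_from_solution(c(K_gluconate = 140, HEPES = 10)), 0)
  expect_error(chloride_from_solution(c(mystery_salt = 10)), "mystery_salt")
  expect_equal(chloride_from_solution(c(XCl3 = 2),
                                      stoichiometry = c(XCl3 = 3)), 6)
})

test_that("junction-potential correction is signed and guarded against re-application", {
  expect_equal(as.numeric(apply_ljp(-51.1, 10.5)), -61.6)
  expect_equal(as.numeric(apply_ljp(-50, 0)), -50)
  v <- apply_ljp(-51.1, 10.5)
  expect_error(apply_ljp(v, 10.5), "twice")
})

test_that("peak current is the baseline-subtracted signed extremum", {
  fs <- 10000
  flat <- ephys_trace(rep(-20, fs), fs, "pA")
  expect_equal(as.numeric(peak_gaba_current(flat, 0.5, response_window = 0.3)), 0)
  x <- rep(-20, fs)
  x[6000:6050] <- x[6000:6050] - 150
  tr <- ephys_trace(x, fs, "pA")
  pk <- peak_gaba_current(tr, 0.5, response_window = 0.3)
  expect_equal(as.numeric(pk), -150)
  expect_equal(attr(pk, "I_total"), -170)
  expect_error(peak_gaba_current(tr, 0.95, response_window = 0.3), "beyond")
})

test_that("reversal fit interpolates, reports diagnostics, and rejects degenerate input", {
  fit <- fit_reversal(data.frame(V_corr = c(-80, -60), I_peak = c(-30, 10)))
  expect_equal(fit$E_rev, -65)
  expect_equal(unname(coef(fit)["E_rev"]), -65)
  expect_equal(length(residuals(fit)), 2L)
  expect_equal(predict(fit, data.frame(V_corr = -65)), 0, tolerance = 1e-12)
  expect_error(fit_reversal(data.frame(V_corr = c(-60, -60),
                                       I_peak = c(-5, 5))), "distinct")
  expect_error(fit_reversal(data.frame(V_corr = c(-80, -60),
                                       I_peak = c(10, -30))), "slope")
  # extrapolation beyond 10 mV without a sign change is refused
  expect_error(fit_reversal(data.frame(V_corr = c(-100, -90, -80),
                                       I_peak = c(-45, -35, -25))),
               "extrapolate")
  # mild extrapolation within 10 mV is allowed but flagged
  fit2 <- fit_reversal(data.frame(V_corr = c(-90, -80, -76),
                                  I_peak = c(-15, -5, -1)))
  expect_true(fit2$extrapolated)
})

test_that("noisy reversal estimation is unbiased over replicates", {
  errs <- vapply(1:200, function(r) {
    pts <- withr::with_seed(4000 + r, {
      v <- seq(-100, -40, by = 10)
      i <- 2 * (v - (-72)) + stats::rnorm(7, 0, 5)
      data.frame(V_corr = v, I_peak = i)
    })
    fit_reversal(pts)$E_rev - (-72)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("chloride estimate composes the fit with the Nernst conversion", {
  est <- estimate_chloride(-70.7, nernst_params(132.5))
  expect_s3_class(est, "chloride_estimate")
  expect_equal(est$Cl_in, chloride_from_nernst(-70.7, nernst_params(132.5)))
  fit <- fit_reversal(data.frame(V_corr = c(-80, -60), I_peak = c(-30, 10)))
  est2 <- estimate_chloride(fit, nernst_params(132.5))
  expect_equal(est2$E_GABA, -65)
  expect_identical(est2$diagnostics$n_points, 2L)
})
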