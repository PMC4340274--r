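test_that("wild-type rate law has the harmonic-sum structure", {
  # equal half-resistances: 1/(1/2 + 1/2) = 1
  expect_equal(v_wt(k1 = 1, k2 = 2, grx_tot = 1, pssg = 2, gsh = 1), 1)
  # saturating substrate leaves GSH oxidation rate-limiting
  expect_equal(v_wt(1, 1, 1, pssg = 1e12, gsh = 3), 1 * 1 * 9,
               tolerance = 1e-10)
  # continuous limit at zero substrate or zero glutathione
  expect_equal(v_wt(1, 1, 1, 0, 10), 0)
  expect_equal(v_wt(1, 1, 1, 10, 0), 0)
  expect_error(v_wt(1, 1, 1, -1, 1), "non-negative")
  expect_error(v_wt(-1, 1, 1, 1, 1), "positive")
})

test_that("oxidized fraction interpolates between 0 and 1", {
  expect_equal(grxss_fraction(1, 2, pssg = 2, gsh = 1), 0.5)
  expect_equal(grxss_fraction(1, 1, pssg = 5, gsh = 0), 1)
  expect_error(grxss_fraction(1, 1, 0, 0), "zero")
  # monotone in both axes
  f <- grxss_fraction(1, 1, pssg = c(1, 2, 4, 8), gsh = 3)
  expect_true(all(diff(f) > 0))
  g <- grxss_fraction(1, 1, pssg = 3, gsh = c(1, 2, 4, 8))
  expect_true(all(diff(g) < 0))
})

test_that("mutant rate law is the first-order analogue", {
  expect_equal(v_mut(k1 = 1, k2p = 2, grx_tot = 1, pssg = 2, gsh = 1), 1)
  expect_equal(v_mut(1, 1, 1, 10, 0), 0)
})

test_that("rate ratio tends to its glutathione-limited value", {
  expect_equal(rate_ratio_limit(k2 = 1, k2p = 50, gsh = 100), 2)
  expect_equal(rate_ratio_limit(k2 = 0.5, k2p = 50, gsh = 100), 1)
  # high-substrate consistency of the full ratio with the limit
  withr::with_seed(5, {
    for (i in 1:20) {
      k2 <- draw_log_uniform(1, 1e-5)
      k2p <- draw_log_uniform(1, 0.01)
      gsh <- draw_log_uniform(1, 300, decades = 2)
      expect_equal(rate_ratio(0.1, k2, k2p, pssg = 1e9, gsh = gsh),
                   rate_ratio_limit(k2, k2p, gsh), tolerance = 1e-4)
    }
  })
  # the wild-type gains on the mutant as glutathione rises
  rr <- rate_ratio(0.1, 1e-5, 0.01, pssg = 1e7,
                   gsh = c(50, 150, 500, 1500))
  expect_true(all(diff(rr) > 0))
  expect_error(rate_ratio(1, 1, 1, pssg = 1, gsh = 0), "positive")
})

test_that("reciprocal coefficients encode the parallel-line prediction", {
  rc <- reciprocal_coefficients(k1 = 1, k2 = 1, grx_tot = 1, gsh = 7)
  expect_equal(rc$slope, 1)
  # the slope is glutathione-free ...
  expect_equal(reciprocal_coefficients(1, 1, 1, gsh = 700)$slope, 1)
  # ... while the intercept falls with the square of glutathione
  expect_equal(reciprocal_coefficients(1, 1, 1, gsh = 14)$intercept,
               rc$intercept / 4)
  # OLS on the reciprocal transform of the analytic curve recovers both
  pssg <- log_grid(0.1, 20, 12L)
  d <- assay_dataset(pssg, v_wt(0.073, 4.23e-6, 0.24, pssg, 998),
                     varied_species = "PSSG", fixed = c(GSH = 998))
  r <- to_reciprocal(d)
  fit <- lm(inv_rate ~ inv_x, data = r)
  rc <- reciprocal_coefficients(0.073, 4.23e-6, 0.24, 998)
  expect_equal(unname(coef(fit)[2L]), rc$slope, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[1L]), rc$intercept, tolerance = 1e-8)
})

test_that("Hill forms are exact algebraic identities, not fits", {
  hf <- hill_form_wt(k1 = 1, k2 = 1, grx_tot = 1, pssg = 4)
  expect_equal(hf$K_half, 2)
  expect_equal(hf$n, 2)
  expect_equal(predict(hf, gsh = hf$K_half), hf$V / 2)
  hm <- hill_form_mut(k1 = 1, k2p = 1, grx_tot = 1, pssg = 3)
  expect_equal(hm$K_half, 3)
  expect_equal(hm$n, 1)
  # pointwise identity with the underlying rate laws over a wide log grid
  gsh <- log_grid(0.01, 1e5, 40L)
  hf <- hill_form_wt(0.073, 4.23e-6, 0.24, 70)
  expect_equal(predict(hf, gsh), v_wt(0.073, 4.23e-6, 0.24, 70, gsh),
               tolerance = 1e-12)
  hm <- hill_form_mut(0.073, 0.01, 0.24, 70)
  expect_equal(predict(hm, gsh), v_mut(0.073, 0.01, 0.24, 70, gsh),
               tolerance = 1e-12)
})

test_that("wild-type rate is monotone and degree-1 in total glutaredoxin", {
  withr::with_seed(7, {
    k1 <- draw_log_uniform(6, 0.1)
    k2 <- draw_log_uniform(6, 1e-5)
    pssg <- draw_log_uniform(6, 10)
    gsh <- draw_log_uniform(6, 300)
    for (i in 1:6) {
      base <- v_wt(k1[i], k2[i], 1, pssg[i], gsh[i])
      expect_equal(v_wt(k1[i], k2[i], 3.7, pssg[i], gsh[i]), 3.7 * base)
      expect_gt(v_wt(k1[i] * 2, k2[i], 1, pssg[i], gsh[i]), base)
      expect_gt(v_wt(k1[i], k2[i] * 2, 1, pssg[i], gsh[i]), base)
      expect_gt(v_wt(k1[i], k2[i], 1, pssg[i] * 2, gsh[i]), base)
      expect_gt(v_wt(k1[i], k2[i], 1, pssg[i], gsh[i] * 2), base)
    }
  })
})
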