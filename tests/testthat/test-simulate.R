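test_that("trajectories honour clamps, conservation and determinism", {
  m <- wt_core_grx1()
  tc <- time_course(m, t_end = 100, n_points = 51)
  # moiety drift stays at solver noise level
  expect_lt(unname(conservation_drift(tc)["Grx"]), 1e-8)
  # clamped species equal their inputs bit-for-bit
  expect_identical(unique(tc$PSSG), 70)
  expect_identical(unique(tc$GSH), 998)
  # identical call -> bit-identical trajectory
  expect_identical(tc, time_course(m, t_end = 100, n_points = 51))
})

test_that("a system without driving force stays put", {
  # zero clamped substrate and zero glutathione: both rates vanish
  m <- build_wildtype_core(grx_params(k1 = 1, k2_wt = 1, grx_tot = 1),
                           pssg = 0, gsh = 0)
  tc <- time_course(m, t_end = 10, n_points = 11)
  expect_true(all(tc$GrxSH2 == 1))
  expect_true(all(tc$GrxSS == 0))
  expect_true(all(tc$flux.v1 == 0))
})

test_that("symmetric core relaxes monotonically to the half-oxidized state", {
  m <- build_wildtype_core(grx_params(k1 = 1, k2_wt = 1, grx_tot = 1),
                           pssg = 2, gsh = sqrt(2))
  tc <- time_course(m, t_end = 8, n_points = 41)
  expect_true(all(diff(tc$GrxSS) > -1e-12))
  expect_equal(tc$GrxSS[nrow(tc)], 0.5, tolerance = 1e-6)
})

test_that("steady_state agrees with the closed forms across random draws", {
  withr::with_seed(23, {
    for (i in 1:10) {
      k1 <- draw_log_uniform(1, 0.1)
      k2 <- draw_log_uniform(1, 1e-5)
      gt <- draw_log_uniform(1, 0.5)
      pssg <- draw_log_uniform(1, 10)
      gsh <- draw_log_uniform(1, 300)
      m <- build_wildtype_core(grx_params(k1 = k1, k2_wt = k2,
                                          grx_tot = gt), pssg, gsh)
      ss <- steady_state(m)
      expect_equal(ss$fluxes[["v2"]], v_wt(k1, k2, gt, pssg, gsh),
                   tolerance = 1e-6)
      expect_equal(unname(ss$state[["GrxSS"]]) / gt,
                   grxss_fraction(k1, k2, pssg, gsh), tolerance = 1e-6)
    }
  })
})

test_that("the stiff assay model balances its fluxes at steady state", {
  m <- hed_model_grx1()
  ss <- steady_state(m)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-10)
  expect_equal(ss$fluxes[["GR"]], ss$fluxes[["GrxRed"]], tolerance = 1e-9)
  # glutathione moiety holds at steady state too
  expect_equal(unname(ss$state[["GSH"]] + 2 * ss$state[["GSSG"]]), 1000,
               tolerance = 1e-8)
  # long integration and the root solve agree on the flux
  tc <- time_course(m, t_end = 5000, n_points = 6, rtol = 1e-11,
                    atol = 1e-13)
  expect_equal(tc[nrow(tc), "flux.GR"], ss$fluxes[["GR"]],
               tolerance = 1e-5)
  # results are bit-reproducible
  expect_identical(steady_state(m)$state, ss$state)
})

test_that("steady_state_flux projects the full solution", {
  m <- wt_core_grx1()
  ss <- steady_state(m)
  expect_identical(steady_state_flux(m, "v1"), unname(ss$fluxes[["v1"]]))
  expect_identical(steady_state_flux(m), unname(ss$fluxes[["v2"]]))
  expect_error(steady_state_flux(m, "nope"), "unknown reaction")
})

test_that("non-relaxing systems are reported honestly", {
  # GSH dynamic in the coupled system: the glutathione pool grows by one
  # GSH per catalytic cycle, so the only steady state has zero
  # deglutathionylation flux; the solver must not silently return a bad
  # root
  m <- build_ecoli_system(ecoli_default_params(),
                          clamped = c(NADPH = 250, NADP = 1, PSSG = 5,
                                      PSH = 1))
  res <- steady_state(m, on_fail = "flag")
  if (res$converged) expect_lt(res$fluxes[["deglut"]], 1e-6)
  else expect_false(res$converged)
})
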