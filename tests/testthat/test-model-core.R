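test_that("parameter constructor validates positivity and names units", {
  expect_error(grx_params(k1 = -1), "strictly positive")
  expect_error(grx_params(k1 = 0), "strictly positive")
  expect_error(set_params(grx_params(), nope = 1), "unknown parameter")
  p <- set_params(grx_params(k1 = 1), k1 = 2)
  expect_equal(p$k1, 2)
  # the wild-type and mutant GSH-oxidation constants live in distinct,
  # unit-tagged fields
  units <- attr(grx_params(), "units")
  expect_equal(units[["k2_wt"]], "uM^-2 s^-1")
  expect_equal(units[["k2p_mut"]], "uM^-1 s^-1")
})

test_that("packaged profiles carry the yeast assay concentrations", {
  g1 <- grx_profile("grx1")
  expect_equal(unname(g1$species[c("NADPH", "NADP", "GSH", "GSSG", "HED")]),
               c(250, 1, 998, 1, 70))
  expect_equal(unname(g1$species["GrxSH2"]), 0.12)
  expect_equal(g1$params$grx_tot, 0.24)
  g2 <- grx_profile("grx2_table1")
  expect_equal(g2$params$k2_wt, 6.74e-5)
  expect_equal(g2$params$k_hed, 0.252)
  expect_equal(g2$params$grx_tot, 0.04)
})

test_that("mass-action rate law multiplies constants and ordered powers", {
  expect_equal(mass_action_rate(2, c(A = 3), c(A = 1)), 6)
  expect_equal(mass_action_rate(1, c(GrxSS = 1, GSH = 2),
                                c(GrxSS = 1, GSH = 2)), 4)
  # net rate vanishes when the mass-action ratio equals Keq
  conc <- c(GrxSH2 = 2, PSSG = 3, GrxSS = 1, PSH = 2, GSH = 3)
  keq <- (1 * 2 * 3) / (2 * 3)
  expect_equal(mass_action_rate(0.7, conc, c(GrxSH2 = 1, PSSG = 1),
                                reverse_order = c(GrxSS = 1, PSH = 1,
                                                  GSH = 1),
                                keq = keq), 0)
  expect_error(mass_action_rate(1, c(A = -1), c(A = 1)), "negative")
  expect_error(mass_action_rate(1, c(A = 1), c(A = 1),
                                reverse_order = c(A = 1), keq = 0),
               "keq")
})

test_that("generic two-substrate law saturates and half-saturates", {
  expect_equal(generic_two_substrate_rate(900, 0.02, 1e9, 15, 1e9, 74.6),
               900 * 0.02, tolerance = 1e-6)
  expect_equal(generic_two_substrate_rate(2, 3, 15, 15, 74.6, 74.6),
               2 * 3 / 4)
  # glutathione-reductase operating point, against direct arithmetic
  a <- 250 / 15
  b <- 1 / 74.6
  expect_equal(generic_two_substrate_rate(900, 0.02, 250, 15, 1, 74.6),
               900 * 0.02 * a * b / ((1 + a) * (1 + b)))
  expect_error(generic_two_substrate_rate(1, 1, 1, 0, 1, 1), "positive")
})

test_that("wild-type core reproduces the two-reaction scheme", {
  p <- grx_params(k1 = 1, k2_wt = 1, grx_tot = 1)
  # no substrate -> zero flux
  m0 <- build_wildtype_core(p, pssg = 0, gsh = 1)
  expect_equal(steady_state_flux(m0), 0)
  # k1*PSSG == k2*GSH^2 puts half the moiety in the oxidized form
  m <- build_wildtype_core(p, pssg = 2, gsh = sqrt(2))
  ss <- steady_state(m)
  expect_equal(unname(ss$state[["GrxSS"]]), 0.5, tolerance = 1e-9)
  # steady state balances the two reactions
  expect_lt(abs(ss$fluxes[["v1"]] - ss$fluxes[["v2"]]), 1e-10)
  expect_error(build_wildtype_core(grx_params(k1 = 1, k2_wt = 1), 1, 1),
               "grx_tot")
  expect_error(build_wildtype_core(p, pssg = -1, gsh = 1), ">= 0")
})

test_that("wild-type steady-state flux matches a long stiff integration", {
  m <- wt_core_grx1()
  ss <- steady_state(m)
  # independent oracle: integrate the two-ODE system to convergence
  tc <- time_course(m, t_end = 2000, n_points = 11, rtol = 1e-11,
                    atol = 1e-13)
  flux_tc <- tc[nrow(tc), "flux.v2"]
  expect_equal(ss$fluxes[["v2"]], flux_tc, tolerance = 1e-6)
})

test_that("mutant core is first order in glutathione", {
  p <- grx_params(k1 = 1, k2p_mut = 1, grx_tot = 1)
  expect_equal(steady_state_flux(build_mutant_core(p, pssg = 0, gsh = 5)),
               0)
  # k1*PSSG == k2'*GSH: half-oxidized moiety
  m <- build_mutant_core(p, pssg = 2, gsh = 2)
  expect_equal(unname(steady_state(m)$state[["GrxSSG"]]), 0.5,
               tolerance = 1e-9)
  # numerical flux equals the closed form across magnitudes
  withr::with_seed(11, {
    for (i in 1:5) {
      k1 <- draw_log_uniform(1, 0.1)
      k2p <- draw_log_uniform(1, 0.01)
      gt <- draw_log_uniform(1, 1)
      pssg <- draw_log_uniform(1, 10)
      gsh <- draw_log_uniform(1, 300)
      m <- build_mutant_core(grx_params(k1 = k1, k2p_mut = k2p,
                                        grx_tot = gt), pssg, gsh)
      expect_equal(steady_state_flux(m),
                   v_mut(k1, k2p, gt, pssg, gsh), tolerance = 1e-6)
    }
  })
})

test_that("coupled-system builder enforces its clamping contract", {
  ep <- ecoli_default_params()
  expect_error(build_ecoli_system(ep, clamped = c(GSH = 1, PSSG = 1)),
               "NADPH and NADP")
  expect_error(build_ecoli_system(ep, reversible = TRUE,
                                  clamped = c(NADPH = 250, NADP = 1,
                                              GSH = 1000, PSSG = 5)),
               "PSH")
  expect_error(build_ecoli_system(ep, clamped = c(NADPH = 250, NADP = 1,
                                                  PSSG = 5, XYZ = 1)),
               "named")
  # equilibrium: reverse mass-action ratio equal to Keq nulls the net rate
  m <- build_ecoli_system(ep, reversible = TRUE,
                          clamped = c(NADPH = 250, NADP = 1, GSH = 2,
                                      PSSG = 3, PSH = 4))
  # choose the glutaredoxin split so GrxSS*PSH*GSH/(GrxSH2*PSSG) = Keq = 1
  # GrxSS*8 = GrxSH2*3 with GrxSH2+GrxSS = 1
  grxss <- 3 / 11
  cm <- grxkin:::.compile_model(m)
  conc <- cm$conc0
  conc[cm$idx[["GrxSS"]]] <- grxss
  conc[cm$idx[["GrxSH2"]]] <- 1 - grxss
  rates <- grxkin:::.rates(cm, conc)
  expect_equal(unname(rates[match("deglut", cm$rxn)]), 0, tolerance = 1e-14)
})

test_that("reciprocal substrate response of the irreversible system is linear", {
  m <- ecoli_model()
  d <- saturation_curve(m, "PSSG", log_grid(0.1, 20, 15L))
  r <- to_reciprocal(d)
  fit <- lm(inv_rate ~ inv_x, data = r)
  expect_gt(r_squared(r$inv_rate, fitted(fit)), 0.9999)
})

test_that("HED-assay builder wires the three-reaction assay", {
  prof <- grx_profile("grx1")
  expect_error(build_hed_assay(prof$params, prof$species[-3]), "GSH")
  m <- hed_model_grx1()
  # the assay readout (NADPH consumption via GR) equals the HED flux at
  # steady state
  ss <- steady_state(m)
  expect_equal(ss$fluxes[["GR"]], ss$fluxes[["HEDRed"]],
               tolerance = 1e-9)
  # no HED -> no flux
  expect_equal(steady_state_flux(set_clamped(m, "HED", 0)), 0)
  # rates across an HED grid match an independent time-course oracle
  grid <- c(10, 70, 500)
  d <- saturation_curve(m, "HED", grid)
  for (i in seq_along(grid)) {
    tc <- time_course(set_clamped(m, "HED", grid[i]), t_end = 5000,
                      n_points = 6, rtol = 1e-11, atol = 1e-13)
    expect_equal(d$rate[i], tc[nrow(tc), "flux.GR"], tolerance = 1e-6)
  }
})

test_that("model builders are pure and clamps stay put", {
  expect_identical(wt_core_grx1(), wt_core_grx1())
  expect_identical(hed_model_grx1(), hed_model_grx1())
  tc <- time_course(wt_core_grx1(), t_end = 50, n_points = 21)
  expect_true(all(tc$PSSG == 70))
  expect_true(all(tc$GSH == 998))
  expect_error(set_clamped(wt_core_grx1(), "GrxSS", 1), "not clamped")
})
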