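test_that("assay datasets validate their geometry", {
  expect_error(assay_dataset(c(1, 1), c(2, 3)), "unique")
  d <- assay_dataset(c(1, 2, 1, 2), c(2, 3, 2.1, 3.1),
                     replicate = c(1, 1, 2, 2))
  expect_equal(nrow(d), 4L)
  expect_error(assay_dataset(-1, 1), ">= 0")
  expect_error(assay_dataset(1, -1), ">= 0")
})

test_that("reciprocal transform inverts and drops unusable points", {
  d <- assay_dataset(c(2, 4, 8), c(4, 8, 16))
  r <- to_reciprocal(d)
  expect_equal(r$inv_x[1L], 0.5)
  expect_equal(r$inv_rate[1L], 0.25)
  expect_equal(attr(r, "n_dropped"), 0L)
  d0 <- assay_dataset(c(0, 2, 4, 8), c(0, 4, 8, 16))
  r0 <- to_reciprocal(d0)
  expect_equal(nrow(r0), 3L)
  expect_equal(attr(r0, "n_dropped"), 1L)
  expect_error(to_reciprocal(assay_dataset(c(0, 1, 2), c(0, 1, 2))),
               "insufficient")
})

test_that("saturation curves match the analytic law and are sigmoidal", {
  m <- wt_core_grx1()
  gsh <- log_grid(50, 5000, 9L)
  d <- saturation_curve(m, "GSH", gsh)
  expect_equal(d$rate, v_wt(0.073, 4.23e-6, 0.24, 70, gsh),
               tolerance = 1e-6)
  expect_true(all(diff(d$rate) > 0))
  # sigmoid on linear axes: curvature changes sign once, + then -
  gshl <- seq(200, 3000, length.out = 25)
  vl <- v_wt(0.073, 4.23e-6, 0.24, 70, gshl)
  curv <- diff(vl, differences = 2)
  expect_gt(curv[1L], 0)
  expect_lt(curv[length(curv)], 0)
  expect_equal(sum(diff(sign(curv)) != 0), 1L)
  expect_error(saturation_curve(m, "GrxSS", 1:3), "clamped")
})

test_that("line families classify parallel vs converging patterns", {
  # two identical datasets are exactly parallel
  pssg <- log_grid(0.1, 20, 10L)
  mk <- function(gsh, scale = 1)
    assay_dataset(pssg, scale * v_wt(0.1, 4.23e-6, 1, pssg, gsh),
                  varied_species = "PSSG", fixed = c(GSH = gsh))
  same <- classify_line_family(list(mk(150), mk(150 + 1e-9)))
  expect_equal(same$classification, "parallel")
  expect_lt(same$slope_spread, 1e-9)
  # analytic wild-type lines at different GSH are parallel by the
  # GSH-free slope
  fam <- list(mk(150), mk(250), mk(1000))
  cls <- classify_line_family(fam)
  expect_equal(cls$classification, "parallel")
  expect_lt(cls$slope_spread, 1e-6)
  # invariant to input order and to uniform rate rescaling
  expect_equal(classify_line_family(rev(fam))$classification, "parallel")
  scaled <- classify_line_family(list(mk(150, 60), mk(250, 60),
                                      mk(1000, 60)))
  expect_equal(scaled$slope_spread, cls$slope_spread, tolerance = 1e-9)
  expect_error(classify_line_family(fam[1L]), "at least 2")
  expect_error(classify_line_family(list(mk(150), mk(150))), "distinct")
})

test_that("reciprocal intercepts fall as the square of glutathione", {
  pssg <- log_grid(0.1, 20, 12L)
  gsh_levels <- c(150, 250, 500, 1000, 2000)
  ints <- vapply(gsh_levels, function(g) {
    d <- assay_dataset(pssg, v_wt(0.1, 4.23e-6, 1, pssg, g),
                       varied_species = "PSSG", fixed = c(GSH = g))
    unname(coef(lm(inv_rate ~ inv_x, data = to_reciprocal(d)))[1L])
  }, numeric(1L))
  slope <- unname(coef(lm(log(ints) ~ log(gsh_levels)))[2L])
  expect_equal(slope, -2, tolerance = 0.01)
})

test_that("parallelism survives 5% multiplicative noise", {
  m <- ecoli_model()
  fam <- generate_pssg_family(m, noise = noise_model(cv = 0.05,
                                                     replicates = 3L,
                                                     seed = 42L))
  cls <- classify_line_family(fam)
  expect_lt(cls$slope_spread, 0.05)
  expect_equal(cls$classification, "parallel")
})

test_that("Hill fitting recovers exact generating parameters", {
  x <- log_grid(0.5, 200, 12L)
  s <- (x / 10)^2
  d <- assay_dataset(x, 1 * s / (1 + s))
  fit <- fit_hill(d)
  expect_true(fit$converged)
  expect_equal(fit$V, 1, tolerance = 1e-6)
  expect_equal(fit$K_half, 10, tolerance = 1e-6)
  expect_equal(fit$n, 2, tolerance = 1e-6)
  expect_gt(fit$r2, 0.999999)
  # fixing the exponent removes it from the fit
  fit1 <- fit_hill(d, fix_n = 2)
  expect_equal(fit1$n, 2)
  expect_equal(fit1$K_half, 10, tolerance = 1e-6)
  expect_error(fit_hill(assay_dataset(1:3, 1:3)), "at least 5")
})

test_that("Hill exponents separate the wild-type and mutant cores under noise", {
  p <- grx1_params()
  dwt <- generate_gsh_dataset("wildtype", p, pssg_fixed = 70,
                              noise = noise_model(cv = 0.05,
                                                  replicates = 3L,
                                                  seed = 99L))
  dmu <- generate_gsh_dataset("mutant", p, pssg_fixed = 70,
                              gsh_grid = log_grid(5, 2e5, 15L),
                              noise = noise_model(cv = 0.05,
                                                  replicates = 3L,
                                                  seed = 99L))
  expect_equal(fit_hill(dwt)$n, 2, tolerance = 0.2)
  expect_equal(fit_hill(dmu)$n, 1, tolerance = 0.2)
})

test_that("an out-of-range half-saturation guess is flagged, not fatal", {
  x <- seq(1000, 2000, length.out = 8)
  s <- (x / 1)^2
  d <- assay_dataset(x, s / (1 + s)) # fully saturated curve
  fit <- fit_hill(d)
  expect_false(is.null(fit$meta$range_warning))
})
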