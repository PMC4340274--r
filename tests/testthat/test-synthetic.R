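test_that("the noise model refuses silent nondeterminism", {
  expect_error(noise_model(cv = 0.05), "seed")
  expect_error(noise_model(cv = -1, seed = 1), "cv")
  expect_error(noise_model(replicates = 0, seed = 1), "replicates")
})

test_that("zero-noise generation equals the model curve exactly", {
  prof <- grx_profile("grx1")
  grid <- log_grid(10, 500, 8L)
  d <- generate_hed_dataset(prof$params, "grx1", hed_grid = grid,
                            noise = noise_model(cv = 0, seed = 1L))
  m <- build_hed_assay(prof$params, prof$species)
  truth <- saturation_curve(m, "HED", grid)
  expect_identical(d$rate, truth$rate)
  expect_true(all(diff(d$rate) > 0))
})

test_that("generators are pure functions of settings and seed", {
  prof <- grx_profile("grx1")
  n <- noise_model(cv = 0.05, replicates = 2L, seed = 77L)
  d1 <- generate_hed_dataset(prof$params, "grx1", noise = n)
  d2 <- generate_hed_dataset(prof$params, "grx1", noise = n)
  expect_identical(d1, d2)
  # and they do not disturb the session RNG
  set.seed(1)
  before <- .Random.seed
  invisible(generate_hed_dataset(prof$params, "grx1", noise = n))
  expect_identical(.Random.seed, before)
  # a different seed gives different noise
  d3 <- generate_hed_dataset(prof$params, "grx1",
                             noise = noise_model(cv = 0.05,
                                                 replicates = 2L,
                                                 seed = 78L))
  expect_false(identical(d1$rate, d3$rate))
})

test_that("glutathione datasets reproduce the core laws and saturate", {
  p <- grx1_params()
  d <- generate_gsh_dataset("wildtype", p, pssg_fixed = 70,
                            noise = noise_model(cv = 0, seed = 1L))
  expect_equal(d$rate, v_wt(p$k1, p$k2_wt, p$grx_tot, 70, d$x))
  expect_equal(fit_hill(d)$n, 2, tolerance = 0.01)
  dm <- generate_gsh_dataset("mutant", p, pssg_fixed = 70,
                             noise = noise_model(cv = 0, seed = 1L))
  expect_equal(fit_hill(dm)$n, 1, tolerance = 0.01)
  # far above the half-saturation constant the curve is flat at V
  K <- sqrt(p$k1 * 70 / p$k2_wt)
  dflat <- generate_gsh_dataset("wildtype", p, pssg_fixed = 70,
                                gsh_grid = log_grid(100 * K, 1000 * K, 6L),
                                noise = noise_model(cv = 0, seed = 1L))
  V <- p$grx_tot * p$k1 * 70
  expect_true(all(abs(dflat$rate / V - 1) < 1e-3))
})

test_that("substrate families feed the classifier reproducibly", {
  fam <- generate_pssg_family(ecoli_model(),
                              noise = noise_model(cv = 0, seed = 1L))
  expect_length(fam, 3L)
  expect_equal(classify_line_family(fam)$classification, "parallel")
  famr <- generate_pssg_family(ecoli_model(reversible = TRUE),
                               noise = noise_model(cv = 0, seed = 1L))
  expect_equal(classify_line_family(famr)$classification, "converging")
  # replicate structure shares the x grid
  famn <- generate_pssg_family(ecoli_model(),
                               noise = noise_model(cv = 0.05,
                                                   replicates = 3L,
                                                   seed = 5L))
  expect_equal(nrow(famn[[1L]]), 45L)
  expect_equal(sort(unique(famn[[1L]]$replicate)), 1:3)
})

test_that("a single noiseless recovery run is unbiased by construction", {
  prof <- grx_profile("grx1")
  rep <- recovery_experiment(prof$params, cv = 0,
                             hed_grid = log_grid(10, 500, 8L),
                             n_seeds = 1L, seed0 = 1L,
                             init = c(k2_wt = 1e-6, k_hed = 0.02))
  expect_equal(rep$n_failed, 0L)
  expect_true(all(abs(rep$summary$rel_bias) < 1e-3))
})
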