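# Seeded synthetic assay data. The generators emulate steady-state
# initial-rate datasets (rate vs one varied concentration) with
# multiplicative Gaussian noise of constant coefficient of variation --
# the error structure typical of spectrophotometric enzyme assays, where
# scatter scales with the signal.

#' Noise model for synthetic assay data
#'
#' Multiplicative Gaussian noise: observed = true * (1 + eps),
#' eps ~ N(0, cv^2) truncated below at -0.99 so rates stay positive
#' (truncation events are counted in the generated dataset's metadata).
#' A seed is mandatory — there is no silent nondeterminism.
#'
#' @param cv coefficient of variation (>= 0; default 0.05).
#' @param replicates number of replicate measurements per grid point
#'   (>= 1).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, replicates = 1L, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("noise_model requires an explicit integer seed", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(kind = "multiplicative-Gaussian", cv = cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# evaluate fn with a temporary RNG state so generators are pure functions
# of (settings, seed)
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# apply a noise model to a vector of true rates; returns observed rates for
# all replicates plus the truncation count
.apply_noise <- function(true_rates, noise) {
  n <- length(true_rates) * noise$replicates
  .with_seed(noise$seed, function() {
    eps <- stats::rnorm(n, mean = 0, sd = noise$cv)
    truncated <- sum(eps < -0.99)
    eps <- pmax(eps, -0.99)
    list(rates = rep(true_rates, times = noise$replicates) * (1 + eps),
         truncated = truncated)
  })
}

#' Default log-spaced concentration grids
#'
#' @param from,to grid limits, uM.
#' @param n number of points.
#' @return Numeric vector of log-spaced concentrations.
#' @export
log_grid <- function(from, to, n = 15L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Generate a synthetic HED-assay dataset
#'
#' Emulates an HED (beta-hydroxyethyl disulphide) activity-assay dataset:
#' steady-state NADPH-consumption rate against HED concentration, with the
#' background species held at the chosen profile's concentrations. True
#' rates come from solving [build_hed_assay()] to steady state at each grid
#' value; noise is applied per [noise_model()].
#'
#' @param params a [grx_params()] object (needs `k2_wt`, `k_hed` and the GR
#'   parameters).
#' @param profile `"grx1"`, `"grx2"` or `"custom"` (then supply `table1`).
#' @param table1 named species-concentration vector (used when
#'   `profile = "custom"`, otherwise taken from [grx_profile()]).
#' @param hed_grid HED concentrations, uM (default 15 log-spaced points
#'   spanning 10-500 uM around the 70 uM reference value).
#' @param noise a [noise_model()].
#' @return An [assay_dataset()]; `meta` records the generator settings,
#'   seed and truncation count.
#' @export
#' @examples
#' d <- generate_hed_dataset(grx_profile("grx1")$params, "grx1",
#'                           noise = noise_model(cv = 0, seed = 1))
generate_hed_dataset <- function(params, profile = c("grx1", "grx2",
                                                     "custom"),
                                 table1 = NULL,
                                 hed_grid = log_grid(10, 500, 15L),
                                 noise = noise_model(cv = 0.05, seed = 1L)) {
  profile <- match.arg(profile)
  if (any(hed_grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  if (profile != "custom") table1 <- grx_profile(profile)$species
  if (is.null(table1))
    stop("profile 'custom' requires a table1 concentration vector",
         call. = FALSE)
  model <- build_hed_assay(params, table1)
  truth <- saturation_curve(model, "HED", hed_grid)
  noisy <- .apply_noise(truth$rate, noise)
  assay_dataset(x = rep(hed_grid, times = noise$replicates),
                rate = noisy$rates,
                sd = if (noise$cv > 0)
                  rep(noise$cv * truth$rate, times = noise$replicates),
                replicate = rep(seq_len(noise$replicates),
                                each = length(hed_grid)),
                varied_species = "HED",
                fixed = attr(truth, "fixed"),
                meta = list(generator = "generate_hed_dataset",
                            profile = profile, cv = noise$cv,
                            replicates = noise$replicates,
                            seed = noise$seed,
                            truncated = noisy$truncated))
}

#' Generate a synthetic glutathione-saturation dataset
#'
#' Rate against glutathione at fixed substrate for the wild-type or mutant
#' glutaredoxin core; true rates are the closed-form steady-state laws
#' ([v_wt()] / [v_mut()]), which coincide with the numerical cores.
#'
#' @param core `"wildtype"` or `"mutant"`.
#' @param params a [grx_params()] (needs `k1`, `grx_tot` and `k2_wt` or
#'   `k2p_mut`).
#' @param pssg_fixed fixed substrate concentration, uM.
#' @param gsh_grid GSH concentrations, uM; default 15 log-spaced points
#'   over 0.1-4000 uM (a super-set of the usual 0.1-4 mM assay range, so a
#'   fitted half-saturation constant is interior).
#' @param noise a [noise_model()].
#' @return An [assay_dataset()] with `GSH` as the varied species.
#' @export
generate_gsh_dataset <- function(core = c("wildtype", "mutant"), params,
                                 pssg_fixed,
                                 gsh_grid = log_grid(0.1, 4000, 15L),
                                 noise = noise_model(cv = 0.05, seed = 1L)) {
  core <- match.arg(core)
  if (any(gsh_grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  truth <- if (core == "wildtype") {
    .require_params(params, c("k1", "k2_wt", "grx_tot"))
    v_wt(params$k1, params$k2_wt, params$grx_tot, pssg_fixed, gsh_grid)
  } else {
    .require_params(params, c("k1", "k2p_mut", "grx_tot"))
    v_mut(params$k1, params$k2p_mut, params$grx_tot, pssg_fixed, gsh_grid)
  }
  noisy <- .apply_noise(truth, noise)
  assay_dataset(x = rep(gsh_grid, times = noise$replicates),
                rate = noisy$rates,
                sd = if (noise$cv > 0)
                  rep(noise$cv * truth, times = noise$replicates),
                replicate = rep(seq_len(noise$replicates),
                                each = length(gsh_grid)),
                varied_species = "GSH",
                fixed = c(PSSG = pssg_fixed),
                meta = list(generator = "generate_gsh_dataset", core = core,
                            cv = noise$cv, replicates = noise$replicates,
                            seed = noise$seed, truncated = noisy$truncated))
}

#' Generate a family of substrate-saturation datasets at several GSH levels
#'
#' One dataset per glutathione concentration over a shared substrate
#' (PSSG) grid — the input expected by [classify_line_family()]. Each GSH
#' level gets its own derived seed so the family is reproducible as a
#' whole.
#'
#' @param model a `grx_model` with clamped `PSSG` and `GSH` (e.g. from
#'   [build_ecoli_system()]).
#' @param pssg_grid substrate grid, uM (default 15 log-spaced points over
#'   0.1-20 uM).
#' @param gsh_values glutathione concentrations, uM (e.g.
#'   `c(150, 250, 1000)`).
#' @param noise a [noise_model()].
#' @return List of [assay_dataset()] objects, one per GSH value.
#' @export
generate_pssg_family <- function(model, pssg_grid = log_grid(0.1, 20, 15L),
                                 gsh_values = c(150, 250, 1000),
                                 noise = noise_model(cv = 0.05, seed = 1L)) {
  stopifnot(inherits(model, "grx_model"))
  lapply(seq_along(gsh_values), function(i) {
    m <- set_clamped(model, "GSH", gsh_values[i])
    truth <- saturation_curve(m, "PSSG", pssg_grid)
    sub_noise <- noise
    sub_noise$seed <- noise$seed + i - 1L
    noisy <- .apply_noise(truth$rate, sub_noise)
    assay_dataset(x = rep(pssg_grid, times = noise$replicates),
                  rate = noisy$rates,
                  sd = if (noise$cv > 0)
                    rep(noise$cv * truth$rate, times = noise$replicates),
                  replicate = rep(seq_len(noise$replicates),
                                  each = length(pssg_grid)),
                  varied_species = "PSSG",
                  fixed = attr(truth, "fixed"),
                  meta = list(generator = "generate_pssg_family",
                              gsh = gsh_values[i], cv = noise$cv,
                              replicates = noise$replicates,
                              seed = sub_noise$seed,
                              truncated = noisy$truncated))
  })
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Loops generate-then-fit over seeds: at each seed a synthetic HED-assay
#' dataset is generated at the true parameters and the free parameters are
#' re-estimated with [fit_rate_constants()]. The fits are 1/sd weighted
#' (the generated datasets carry their known constant-CV noise SDs), which
#' makes the asymptotic confidence intervals calibrated under the
#' multiplicative error model. Reports per-parameter relative
#' bias of the mean estimate, relative RMSE, and the fraction of successful
#' fits whose 95% confidence interval covers the truth.
#'
#' @param true_params a [grx_params()] holding the generating values.
#' @param free_params parameters to recover (default
#'   `c("k2_wt", "k_hed")`).
#' @param profile,table1,hed_grid passed to [generate_hed_dataset()].
#' @param cv,replicates noise settings.
#' @param n_seeds number of Monte-Carlo repetitions (>= 1).
#' @param seed0 base seed; repetition i uses seed `seed0 + i - 1`.
#' @param init optional fixed starting values forwarded to the fits.
#' @return An object of class `recovery_report`: data.frame `summary`
#'   (parameter, truth, mean_estimate, rel_bias, rel_rmse, coverage),
#'   matrix `estimates` (seeds x parameters), count `n_failed`.
#' @export
recovery_experiment <- function(true_params,
                                free_params = c("k2_wt", "k_hed"),
                                profile = "grx1", table1 = NULL,
                                hed_grid = log_grid(10, 500, 20L),
                                cv = 0.05, replicates = 1L,
                                n_seeds = 100L, seed0 = 1L, init = NULL) {
  stopifnot(n_seeds >= 1L)
  prof_species <- if (identical(profile, "custom")) table1
                  else grx_profile(profile)$species
  model <- build_hed_assay(true_params, prof_species)
  truth <- unlist(true_params[free_params])
  ests <- matrix(NA_real_, n_seeds, length(free_params),
                 dimnames = list(NULL, free_params))
  covered <- matrix(NA, n_seeds, length(free_params),
                    dimnames = list(NULL, free_params))
  n_failed <- 0L
  for (i in seq_len(n_seeds)) {
    d <- generate_hed_dataset(true_params, profile = profile,
                              table1 = table1, hed_grid = hed_grid,
                              noise = noise_model(cv = cv,
                                                  replicates = replicates,
                                                  seed = seed0 + i - 1L))
    fit <- tryCatch(
      fit_rate_constants(model, free_params, d, init = init,
                         weights = "sd"),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    ests[i, ] <- fit$estimates[free_params]
    if (!is.null(fit$ci))
      covered[i, ] <- truth >= fit$ci[free_params, "lower"] &
        truth <= fit$ci[free_params, "upper"]
  }
  ok <- stats::complete.cases(ests)
  summary <- data.frame(
    parameter = free_params,
    truth = unname(truth),
    mean_estimate = colMeans(ests[ok, , drop = FALSE]),
    rel_bias = colMeans(ests[ok, , drop = FALSE]) / truth - 1,
    rel_rmse = sqrt(colMeans((t(t(ests[ok, , drop = FALSE]) / truth) -
                                1)^2)),
    coverage = colMeans(covered[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL)
  structure(list(summary = summary, estimates = ests, n_failed = n_failed,
                 settings = list(cv = cv, replicates = replicates,
                                 n_seeds = n_seeds, seed0 = seed0,
                                 hed_grid = hed_grid, profile = profile)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$settings
  cat("Parameter recovery: ", s$n_seeds, " seeds, cv = ", s$cv,
      ", ", length(s$hed_grid), " grid points, ", x$n_failed,
      " failed fit(s)\n", sep = "")
  print(transform(x$summary,
                  rel_bias = sprintf("%+.2f%%", 100 * rel_bias),
                  rel_rmse = sprintf("%.2f%%", 100 * rel_rmse),
                  coverage = sprintf("%.0f%%", 100 * coverage)),
        digits = 4)
  invisible(x)
}
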