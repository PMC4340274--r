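# Run configuration and one-command pipelines. Configs are flat key-value
# text (same syntax as the parameter files); presets encode the packaged
# simulation protocols so the headline analyses are single commands.

.run_config_keys <- c(
  preset = "character", model = "character", profile = "character",
  seed = "integer", cv = "numeric", replicates = "integer",
  pssg = "numeric", gsh = "numeric",
  grid_min = "numeric", grid_max = "numeric", grid_n = "integer",
  gsh_levels = "numeric_vector", verbose = "logical",
  k1 = "numeric", k2_wt = "numeric", k2p_mut = "numeric",
  k_hed = "numeric", keq_deglut = "numeric", grx_tot = "numeric")

.known_presets <- c("fig4", "fig5", "hill", "grx1_fit_synthetic")

#' Parse and validate a run configuration
#'
#' Accepts flat key-value text (`key = value`, `#` comments). Recognised
#' keys: `preset` (one of `fig4`, `fig5`, `hill`, `grx1_fit_synthetic`),
#' `model`, `profile`, `seed`, `cv`, `replicates`, `pssg`, `gsh`,
#' `grid_min`/`grid_max`/`grid_n`, `gsh_levels` (space-separated),
#' `verbose`, and rate-constant overrides (`k1`, `k2_wt`, `k2p_mut`,
#' `k_hed`, `keq_deglut`, `grx_tot`). Validation reports *every* problem,
#' not just the first: unknown keys are named, types are checked, and a
#' positive noise `cv` requires a `seed`.
#'
#' @param text character vector of config lines, or a length-1 path to a
#'   config file.
#' @return An object of class `run_config` (a named list with defaults
#'   filled in from the selected profile).
#' @export
#' @examples
#' cfg <- parse_run_config(c("preset = hill", "cv = 0", "seed = 1"))
#' cfg$preset
parse_run_config <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  kv <- .read_kv_lines(text)
  problems <- character(0)
  unknown <- setdiff(names(kv), names(.run_config_keys))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key: ", unknown))
  cfg <- list(preset = NA_character_, model = "wildtype",
              profile = "grx1", seed = NA_integer_, cv = 0,
              replicates = 1L, verbose = FALSE)
  for (nm in intersect(names(kv), names(.run_config_keys))) {
    raw <- kv[[nm]]
    type <- .run_config_keys[[nm]]
    val <- switch(type,
      character = raw,
      logical = as.logical(raw),
      integer = suppressWarnings(as.integer(raw)),
      numeric = suppressWarnings(as.numeric(raw)),
      numeric_vector = suppressWarnings(
        as.numeric(strsplit(raw, "[ ,]+")[[1L]])))
    if (anyNA(val))
      problems <- c(problems,
                    paste0("key '", nm, "': cannot parse '", raw,
                           "' as ", type))
    cfg[[nm]] <- val
  }
  if (!is.na(cfg$preset) && !cfg$preset %in% .known_presets)
    problems <- c(problems, paste0("unknown preset: ", cfg$preset))
  if (!cfg$model %in% c("wildtype", "mutant", "ecoli", "hed_assay"))
    problems <- c(problems, paste0("unknown model: ", cfg$model))
  if (!is.na(cfg$cv) && cfg$cv > 0 && is.na(cfg$seed))
    problems <- c(problems, "cv > 0 requires a seed")
  if (length(problems))
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) == 1L && is.na(v)) next
    cat("  ", nm, " = ", paste(format(v), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialise a run configuration back to key-value text
#'
#' @param config a `run_config`.
#' @return Character vector of `key = value` lines;
#'   `parse_run_config(write_run_config(cfg))` reproduces `cfg`.
#' @export
write_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- character(0)
  for (nm in names(config)) {
    v <- config[[nm]]
    if (length(v) == 1L && is.na(v)) next
    out <- c(out, paste0(nm, " = ", paste(format(v, digits = 17),
                                          collapse = " ")))
  }
  out
}

# 32-bit polynomial rolling hash of the serialised config, for artifact
# manifests (stays within exact double-precision integer range)
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(write_run_config(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536L), as.integer(h %% 65536L))
}

.manifest <- function(config) {
  c(sprintf("# package: grxkin %s",
            as.character(utils::packageVersion("grxkin"))),
    sprintf("# config_hash: %s", .config_hash(config)),
    sprintf("# seed: %s", if (is.na(config$seed)) "none" else config$seed))
}

.write_report <- function(lines, config, path) {
  writeLines(c(.manifest(config), lines), path)
  path
}

#' Run a packaged analysis pipeline
#'
#' Executes the stage chain selected by `config$preset` and writes datasets
#' and plain-text reports (each artifact carries a manifest header with the
#' package version, config hash and seed):
#' \describe{
#'   \item{`fig4`}{irreversible coupled system; steady-state rate versus
#'     substrate (PSSG 0.1-20 uM at 1 mM GSH) and versus glutathione
#'     (0.1-4 mM at 5 uM PSSG), with the reciprocal-plot linearity
#'     analysis of each axis.}
#'   \item{`fig5`}{reciprocal line families at GSH 150/250/1000 uM for the
#'     irreversible and the reversible (Keq 1 uM) deglutathionylation
#'     variants, classified parallel/converging.}
#'   \item{`hill`}{glutathione saturation curve of the selected core and a
#'     free-exponent Hill fit.}
#'   \item{`grx1_fit_synthetic`}{synthetic HED-assay dataset at the
#'     selected profile's constants, refitted from scratch.}
#' }
#'
#' @param config a [parse_run_config()] object (or character config text).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths) and `results` (the computed R objects).
#' @export
run_pipeline <- function(config, out_dir = tempfile("grxkin_run_")) {
  if (!inherits(config, "run_config")) config <- parse_run_config(config)
  if (is.na(config$preset))
    stop("config must select a preset", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  res <- list()
  log <- function(...) if (isTRUE(config$verbose)) message(...)
  prof <- grx_profile(config$profile)
  overrides <- config[intersect(names(config),
                                c("k1", "k2_wt", "k2p_mut", "k_hed",
                                  "keq_deglut", "grx_tot"))]
  overrides <- overrides[!vapply(overrides, function(v) anyNA(v), TRUE)]
  params <- do.call(set_params, c(list(prof$params), overrides))

  t0 <- Sys.time()
  if (config$preset == "fig4") {
    ep <- do.call(set_params, c(list(ecoli_default_params()), overrides))
    m <- build_ecoli_system(ep, clamped = c(NADPH = 250, NADP = 1,
                                            GSH = 1000, PSSG = 5))
    pssg_grid <- log_grid(0.1, 20, 15L)
    d_pssg <- saturation_curve(m, "PSSG", pssg_grid)
    gsh_grid <- log_grid(100, 4000, 15L)
    d_gsh <- saturation_curve(set_clamped(m, "PSSG", 5), "GSH", gsh_grid)
    r_pssg <- to_reciprocal(d_pssg)
    lin <- stats::lm(inv_rate ~ inv_x, data = r_pssg)
    r_gsh <- to_reciprocal(d_gsh)
    quad <- stats::lm(inv_rate ~ inv_x + I(inv_x^2), data = r_gsh)
    art <- c(art,
             write_assay_csv(d_pssg, file.path(out_dir, "fig4_pssg.csv")),
             write_assay_csv(d_gsh, file.path(out_dir, "fig4_gsh.csv")))
    rep_lines <- c(
      sprintf("pssg_reciprocal_r2 = %.10f",
              r_squared(r_pssg$inv_rate, stats::fitted(lin))),
      sprintf("gsh_quadratic_p = %.3g",
              suppressWarnings(summary(quad)$coefficients[3L, 4L])))
    art <- c(art, .write_report(rep_lines, config,
                                file.path(out_dir, "fig4_report.txt")))
    res <- list(pssg = d_pssg, gsh = d_gsh, linearity = lin,
                quadratic = quad)
  } else if (config$preset == "fig5") {
    ep <- do.call(set_params, c(list(ecoli_default_params()), overrides))
    gsh_levels <- if (!is.null(config$gsh_levels)) config$gsh_levels
                  else c(150, 250, 1000)
    noise <- noise_model(cv = config$cv, replicates = config$replicates,
                         seed = if (is.na(config$seed)) 1L else config$seed)
    out <- list()
    for (variant in c("irreversible", "reversible")) {
      m <- build_ecoli_system(ep, reversible = variant == "reversible",
                              clamped = c(NADPH = 250, NADP = 1,
                                          GSH = 1000, PSSG = 5, PSH = 1))
      fam <- generate_pssg_family(m, gsh_values = gsh_levels,
                                  noise = noise)
      cls <- classify_line_family(fam)
      for (i in seq_along(fam))
        art <- c(art, write_assay_csv(fam[[i]], file.path(
          out_dir, sprintf("fig5_%s_gsh%g.csv", variant, gsh_levels[i]))))
      rep_lines <- c(sprintf("classification = %s", cls$classification),
                     sprintf("slope_spread = %.6g", cls$slope_spread))
      art <- c(art, .write_report(rep_lines, config, file.path(
        out_dir, sprintf("fig5_%s_report.txt", variant))))
      out[[variant]] <- cls
      log("fig5 ", variant, ": ", cls$classification)
    }
    res <- out
  } else if (config$preset == "hill") {
    core <- if (config$model == "mutant") "mutant" else "wildtype"
    p <- params
    if (is.na(p$k1)) p <- set_params(p, k1 = p$k_hed)
    if (core == "mutant" && is.na(p$k2p_mut))
      stop("hill preset on the mutant core needs k2p_mut", call. = FALSE)
    pssg <- if (!is.null(config$pssg) && !is.na(config$pssg)) config$pssg
            else 70
    K_half <- if (core == "wildtype") sqrt(p$k1 * pssg / p$k2_wt)
              else p$k1 * pssg / p$k2p_mut
    grid <- log_grid(K_half / 100, K_half * 100, 21L)
    noise <- noise_model(cv = config$cv, replicates = config$replicates,
                         seed = if (is.na(config$seed)) 1L else config$seed)
    d <- generate_gsh_dataset(core, p, pssg_fixed = pssg, gsh_grid = grid,
                              noise = noise)
    hf <- fit_hill(d)
    art <- c(art, write_assay_csv(d, file.path(out_dir, "hill_data.csv")))
    rep_lines <- c(sprintf("core = %s", core),
                   sprintf("V = %.10g", hf$V),
                   sprintf("K_half = %.10g", hf$K_half),
                   sprintf("n = %.10g", hf$n),
                   sprintf("r2 = %.10g", hf$r2),
                   sprintf("converged = %s", hf$converged))
    art <- c(art, .write_report(rep_lines, config,
                                file.path(out_dir, "hill_report.txt")))
    res <- list(dataset = d, fit = hf)
  } else if (config$preset == "grx1_fit_synthetic") {
    noise <- noise_model(cv = config$cv, replicates = config$replicates,
                         seed = if (is.na(config$seed)) 1L else config$seed)
    d <- generate_hed_dataset(params, profile = config$profile,
                              noise = noise)
    m <- build_hed_assay(params, prof$species)
    fit <- fit_rate_constants(m, c("k2_wt", "k_hed"), d)
    art <- c(art, write_assay_csv(d, file.path(out_dir, "hed_data.csv")))
    rep_lines <- c(
      sprintf("k2_wt = %.10g", fit$estimates[["k2_wt"]]),
      sprintf("k_hed = %.10g", fit$estimates[["k_hed"]]),
      if (!is.null(fit$std_errors))
        c(sprintf("k2_wt_se = %.4g", fit$std_errors[["k2_wt"]]),
          sprintf("k_hed_se = %.4g", fit$std_errors[["k_hed"]])),
      sprintf("r2 = %.10g", fit$r2),
      sprintf("converged = %s", fit$converged))
    art <- c(art, .write_report(rep_lines, config,
                                file.path(out_dir, "fit_report.txt")))
    res <- list(dataset = d, fit = fit)
  }
  log("pipeline '", config$preset, "' finished in ",
      format(Sys.time() - t0))
  invisible(list(status = 0L, artifacts = art, results = res,
                 out_dir = out_dir))
}
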