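#' Kinetic parameter set for glutaredoxin models
#'
#' Bundles every rate constant and enzyme parameter used by the model
#' builders. All values are in micromolar/second units. The wild-type and
#' mutant glutathione-oxidation constants carry different units and are
#' deliberately kept in separate fields so they can never be interchanged:
#' `k2_wt` is third order overall (uM^-2 s^-1, two GSH molecules reduce
#' oxidized Grx), while `k2p_mut` is second order (uM^-1 s^-1, a single GSH
#' reduces the Grx-SSG mixed disulphide).
#'
#' Fields not needed by a given model may be left `NA`; each model builder
#' validates the fields it actually uses.
#'
#' @param k1 deglutathionylation forward rate constant, uM^-1 s^-1.
#' @param k2_wt wild-type Grx reduction constant (order 2 in GSH), uM^-2 s^-1.
#' @param k2p_mut mutant GrxSSG reduction constant (order 1 in GSH), uM^-1 s^-1.
#' @param k_hed HED-reduction rate constant, uM^-1 s^-1.
#' @param keq_deglut equilibrium constant of the reversible
#'   deglutathionylation step, uM.
#' @param gr_kcat glutathione reductase turnover number, s^-1.
#' @param gr_K_NADPH glutathione reductase half-saturation constant for
#'   NADPH, uM.
#' @param gr_K_GSSG glutathione reductase half-saturation constant for
#'   GSSG, uM.
#' @param gr_conc glutathione reductase concentration, uM.
#' @param grx_tot total glutaredoxin moiety concentration, uM.
#' @return An object of class `grx_params` (a named list with a unit table
#'   attached as an attribute).
#' @seealso [grx_profile()] for the packaged yeast Grx1/Grx2 parameter sets.
#' @export
#' @examples
#' p <- grx_params(k1 = 0.1, k2_wt = 4.23e-6, grx_tot = 0.24)
#' p
grx_params <- function(k1 = NA_real_, k2_wt = NA_real_, k2p_mut = NA_real_,
                       k_hed = NA_real_, keq_deglut = 1,
                       gr_kcat = 900, gr_K_NADPH = 15, gr_K_GSSG = 74.6,
                       gr_conc = 0.02, grx_tot = NA_real_) {
  p <- list(k1 = k1, k2_wt = k2_wt, k2p_mut = k2p_mut, k_hed = k_hed,
            keq_deglut = keq_deglut, gr_kcat = gr_kcat,
            gr_K_NADPH = gr_K_NADPH, gr_K_GSSG = gr_K_GSSG,
            gr_conc = gr_conc, grx_tot = grx_tot)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("parameter '", nm, "' must be a single numeric value", call. = FALSE)
    if (!is.na(v) && v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  structure(p, units = .grx_param_units, class = "grx_params")
}

.grx_param_units <- c(
  k1 = "uM^-1 s^-1", k2_wt = "uM^-2 s^-1", k2p_mut = "uM^-1 s^-1",
  k_hed = "uM^-1 s^-1", keq_deglut = "uM", gr_kcat = "s^-1",
  gr_K_NADPH = "uM", gr_K_GSSG = "uM", gr_conc = "uM", grx_tot = "uM")

#' @export
print.grx_params <- function(x, ...) {
  cat("Glutaredoxin kinetic parameters\n")
  units <- attr(x, "units")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-11s %-12s %s\n", nm,
                if (is.na(v)) "NA" else format(v), units[[nm]]))
  }
  invisible(x)
}

#' Update fields of a parameter set
#'
#' @param params a [grx_params()] object.
#' @param ... named replacement values, e.g. `k2_wt = 1e-5`.
#' @return The updated `grx_params` object.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "grx_params"))
  upd <- list(...)
  if (length(upd) == 0L) return(params)
  bad <- setdiff(names(upd), names(params))
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(grx_params, utils::modifyList(unclass(params), upd))
}

#' Packaged parameter and concentration profiles for the yeast HED assay
#'
#' Returns the default parameter set and species concentrations used for the
#' yeast Grx1 and Grx2 HED-assay models: background metabolite levels
#' (NADPH 250, NADP 1, GSH 998, GSSG 1, HED 70 uM), the glutaredoxin redox
#' couple (Grx1: 0.12/0.12 uM; Grx2: 0.02/0.02 uM reduced/oxidized) and
#' glutathione reductase (0.02 uM; kcat 900 s^-1, K_NADPH 15 uM,
#' K_GSSG 74.6 uM). The rate constants are the fitted values for
#' glutaredoxin (GSH oxidation) and HED reduction: Grx1 4.23e-6 uM^-2 s^-1
#' and 0.073 uM^-1 s^-1; Grx2 6.74e-5 uM^-2 s^-1 and 0.252 uM^-1 s^-1.
#'
#' @param profile `"grx1"` or `"grx2"` (the aliases `"grx1_table1"` /
#'   `"grx2_table1"` are accepted).
#' @return A list with elements `params` ([grx_params()]) and `species`
#'   (named concentration vector, uM: NADPH, NADP, GSH, GSSG, HED, GrxSH2,
#'   GrxSS).
#' @export
#' @examples
#' grx_profile("grx1")$params
grx_profile <- function(profile = c("grx1", "grx2", "grx1_table1",
                                    "grx2_table1")) {
  profile <- match.arg(profile)
  profile <- sub("_table1$", "", profile)
  species <- c(NADPH = 250, NADP = 1, GSH = 998, GSSG = 1, HED = 70)
  if (profile == "grx1") {
    species <- c(species, GrxSH2 = 0.12, GrxSS = 0.12)
    params <- grx_params(k2_wt = 4.23e-6, k_hed = 0.073, grx_tot = 0.24)
  } else {
    species <- c(species, GrxSH2 = 0.02, GrxSS = 0.02)
    params <- grx_params(k2_wt = 6.74e-5, k_hed = 0.252, grx_tot = 0.04)
  }
  list(params = params, species = species, name = profile)
}

# check that the named fields of a grx_params object are usable (positive,
# non-NA); used by the model builders.
.require_params <- function(params, fields) {
  stopifnot(inherits(params, "grx_params"))
  for (nm in fields) {
    v <- params[[nm]]
    if (is.null(v) || is.na(v) || v <= 0)
      stop("invalid model: parameter '", nm,
           "' must be a positive number for this model (got ",
           if (is.null(v)) "NULL" else v, ")", call. = FALSE)
  }
  invisible(TRUE)
}
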