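#' Elementary rate laws
#'
#' `mass_action_rate()` evaluates a (possibly reversible) mass-action rate:
#' the rate constant times the product of concentrations raised to their
#' kinetic orders. For the reversible form the net rate is
#' `k * (prod(forward) - prod(reverse)/keq)`, i.e. the reverse rate constant
#' is `k / keq`.
#'
#' @param k rate constant (units depend on the overall kinetic order).
#' @param conc named non-negative concentration vector, uM.
#' @param kinetic_order named non-negative exponents for the forward term;
#'   names must be present in `conc`.
#' @param reverse_order named exponents for the reverse term (reversible
#'   form only).
#' @param keq equilibrium constant (finite, positive; reversible form only).
#' @return Net flux in uM s^-1.
#' @export
#' @examples
#' mass_action_rate(2, c(A = 3), c(A = 1))              # 6
#' mass_action_rate(1, c(GrxSS = 1, GSH = 2), c(GrxSS = 1, GSH = 2))  # 4
mass_action_rate <- function(k, conc, kinetic_order, reverse_order = NULL,
                             keq = NULL) {
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  miss <- setdiff(c(names(kinetic_order), names(reverse_order)), names(conc))
  if (length(miss))
    stop("species missing from concentration vector: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- k * prod(conc[names(kinetic_order)]^kinetic_order)
  if (!is.null(reverse_order)) {
    if (is.null(keq) || !is.finite(keq) || keq <= 0)
      stop("reversible rate law requires a finite positive keq", call. = FALSE)
    v <- v - (k / keq) * prod(conc[names(reverse_order)]^reverse_order)
  }
  v
}

#' @rdname mass_action_rate
#' @details `generic_two_substrate_rate()` is the irreversible generic
#' two-substrate law used for glutathione reductase,
#' `v = kcat * E * (A/Ka)(B/Kb) / ((1 + A/Ka)(1 + B/Kb))`.
#' It reduces to a Michaelis-Menten dependence in each substrate and
#' saturates at `kcat * E`.
#' @param kcat turnover number, s^-1.
#' @param E enzyme concentration, uM.
#' @param A,B substrate concentrations, uM (may be 0).
#' @param Ka,Kb half-saturation constants, uM (strictly positive).
#' @export
generic_two_substrate_rate <- function(kcat, E, A, Ka, B, Kb) {
  if (Ka <= 0 || Kb <= 0) stop("Ka and Kb must be positive", call. = FALSE)
  if (kcat <= 0 || E <= 0) stop("kcat and E must be positive", call. = FALSE)
  if (A < 0 || B < 0) stop("negative concentration", call. = FALSE)
  a <- A / Ka
  b <- B / Kb
  kcat * E * (a * b) / ((1 + a) * (1 + b))
}

# internal reaction constructor. Rate constants are stored as *references*
# into the model's grx_params object so that refitting a constant updates
# every reaction that uses it.
.reaction <- function(id, stoich, rate) {
  stopifnot(is.character(id), length(id) == 1L, is.numeric(stoich),
            !is.null(names(stoich)))
  list(id = id, stoich = stoich, rate = rate)
}

.rate_mass_action <- function(k_ref, order, reverse_order = NULL,
                              keq_ref = NULL) {
  list(type = "mass_action", k_ref = k_ref, order = order,
       reverse_order = reverse_order, keq_ref = keq_ref,
       reversible = !is.null(reverse_order))
}

.rate_two_substrate <- function(kcat_ref, E_ref, A, Ka_ref, B, Kb_ref) {
  list(type = "two_substrate", kcat_ref = kcat_ref, E_ref = E_ref,
       A = A, Ka_ref = Ka_ref, B = B, Kb_ref = Kb_ref, reversible = FALSE)
}

#' Construct a kinetic model object
#'
#' Low-level constructor; users normally call one of the builders
#' ([build_wildtype_core()], [build_mutant_core()], [build_ecoli_system()],
#' [build_hed_assay()]). Validates that every reaction only touches declared
#' species, that clamped/dynamic roles are consistent, that concentrations
#' are non-negative, and that every registered moiety-conservation relation
#' is annihilated by every reaction's stoichiometry.
#'
#' @param species data.frame with columns `name`, `role`
#'   (`"dynamic"`/`"clamped"`) and `conc` (initial or clamped value, uM).
#' @param reactions list of internal reaction objects.
#' @param conservation list of moiety relations, each
#'   `list(name =, coef = named numeric, total = numeric)`.
#' @param params a [grx_params()] object the reactions reference.
#' @param observable id of the reaction whose steady-state flux is the
#'   measured assay rate.
#' @return An object of class `grx_model`.
#' @keywords internal
grx_model <- function(species, reactions, conservation, params, observable) {
  stopifnot(is.data.frame(species),
            all(c("name", "role", "conc") %in% names(species)))
  if (anyDuplicated(species$name))
    stop("invalid model: duplicated species name", call. = FALSE)
  if (any(species$conc < 0))
    stop("invalid model: negative concentration", call. = FALSE)
  if (!all(species$role %in% c("dynamic", "clamped")))
    stop("invalid model: species role must be 'dynamic' or 'clamped'",
         call. = FALSE)
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("invalid model: duplicated reaction id", call. = FALSE)
  names(reactions) <- ids
  for (rx in reactions) {
    touched <- c(names(rx$stoich), names(rx$rate$order),
                 names(rx$rate$reverse_order))
    miss <- setdiff(touched, species$name)
    if (length(miss))
      stop("invalid model: reaction '", rx$id,
           "' references undeclared species ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  # every reaction must leave every registered moiety sum unchanged
  for (cons in conservation) {
    for (rx in reactions) {
      common <- intersect(names(cons$coef), names(rx$stoich))
      net <- sum(cons$coef[common] * rx$stoich[common])
      if (abs(net) > 1e-12)
        stop("invalid model: reaction '", rx$id, "' changes moiety '",
             cons$name, "' by ", net, call. = FALSE)
    }
  }
  if (!observable %in% ids)
    stop("invalid model: observable reaction '", observable, "' not found",
         call. = FALSE)
  structure(list(species = species, reactions = reactions,
                 conservation = conservation, params = params,
                 observable = observable),
            class = "grx_model")
}

#' @export
print.grx_model <- function(x, ...) {
  ndyn <- sum(x$species$role == "dynamic")
  cat("grx_model: ", length(x$reactions), " reactions, ",
      nrow(x$species), " species (", ndyn, " dynamic), ",
      length(x$conservation), " conserved moiet",
      if (length(x$conservation) == 1L) "y" else "ies", "\n", sep = "")
  for (i in seq_len(nrow(x$species))) {
    s <- x$species[i, ]
    cat(sprintf("  %-8s %-8s %g uM\n", s$name, s$role, s$conc))
  }
  for (rx in x$reactions) {
    lhs <- rx$stoich[rx$stoich < 0]
    rhs <- rx$stoich[rx$stoich > 0]
    fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                    paste0(abs(v), " ", names(v))),
                             collapse = " + ")
    cat(sprintf("  %s: %s %s %s  [%s%s]\n", rx$id, fmt(lhs),
                if (isTRUE(rx$rate$reversible)) "<->" else "->", fmt(rhs),
                rx$rate$type,
                if (isTRUE(rx$rate$reversible)) ", reversible" else ""))
  }
  for (cons in x$conservation)
    cat(sprintf("  conserved: %s = %g uM\n", cons$name, cons$total))
  invisible(x)
}

#' Override a clamped species concentration
#'
#' @param model a `grx_model`.
#' @param species name of a clamped species.
#' @param value new concentration, uM (>= 0).
#' @return The modified model.
#' @export
set_clamped <- function(model, species, value) {
  stopifnot(inherits(model, "grx_model"))
  i <- match(species, model$species$name)
  if (is.na(i)) stop("unknown species '", species, "'", call. = FALSE)
  if (model$species$role[i] != "clamped")
    stop("species '", species, "' is not clamped", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("clamped concentration must be a single value >= 0", call. = FALSE)
  model$species$conc[i] <- value
  model
}

#' Replace model parameters
#'
#' Substitutes new values for rate constants referenced by the model's
#' reactions (used by the fitting routines).
#'
#' @inheritParams set_clamped
#' @param ... named parameter replacements passed to [set_params()].
#' @export
set_model_params <- function(model, ...) {
  stopifnot(inherits(model, "grx_model"))
  model$params <- set_params(model$params, ...)
  model
}

#' Build the wild-type dithiol glutaredoxin core model
#'
#' Two irreversible mass-action reactions over the glutaredoxin redox
#' couple, with the glutathionylated substrate (PSSG) and glutathione (GSH)
#' clamped:
#' \deqn{v_1 = k_1\,[PSSG][Grx(SH)_2], \qquad v_2 = k_2\,[GrxSS][GSH]^2}
#' The glutaredoxin moiety `GrxSH2 + GrxSS = grx_tot` is registered as a
#' conservation relation. The initial state is fully reduced glutaredoxin.
#'
#' @param params a [grx_params()] object; `k1`, `k2_wt` and `grx_tot` must
#'   be set.
#' @param pssg,gsh clamped concentrations, uM (>= 0).
#' @return A `grx_model` whose observable flux is `v2` (equal to `v1` at
#'   steady state).
#' @export
#' @examples
#' m <- build_wildtype_core(grx_params(k1 = 0.073, k2_wt = 4.23e-6,
#'                                     grx_tot = 0.24),
#'                          pssg = 70, gsh = 998)
#' steady_state(m)
build_wildtype_core <- function(params, pssg, gsh) {
  .require_params(params, c("k1", "k2_wt", "grx_tot"))
  if (pssg < 0 || gsh < 0)
    stop("clamped concentrations must be >= 0", call. = FALSE)
  species <- data.frame(
    name = c("GrxSH2", "GrxSS", "PSSG", "GSH", "GSSG"),
    role = c("dynamic", "dynamic", "clamped", "clamped", "clamped"),
    conc = c(params$grx_tot, 0, pssg, gsh, 0))
  reactions <- list(
    .reaction("v1", c(GrxSH2 = -1, PSSG = -1, GrxSS = 1, GSH = 1),
              .rate_mass_action("k1", c(PSSG = 1, GrxSH2 = 1))),
    .reaction("v2", c(GrxSS = -1, GSH = -2, GrxSH2 = 1, GSSG = 1),
              .rate_mass_action("k2_wt", c(GrxSS = 1, GSH = 2))))
  conservation <- list(list(name = "Grx", coef = c(GrxSH2 = 1, GrxSS = 1),
                            total = params$grx_tot))
  grx_model(species, reactions, conservation, params, observable = "v2")
}

#' Build the active-site mutant glutaredoxin core model
#'
#' The single-cysteine mutant cycles through the Grx-SSG mixed disulphide
#' instead of the intramolecular disulphide; its reduction by glutathione is
#' first order in GSH:
#' \deqn{v_1 = k_1\,[PSSG][GrxSH], \qquad v_2 = k_2'\,[GrxSSG][GSH]}
#' with the moiety `GrxSH + GrxSSG = grx_tot`.
#'
#' @param params a [grx_params()] object; `k1`, `k2p_mut` and `grx_tot`
#'   must be set.
#' @inheritParams build_wildtype_core
#' @return A `grx_model` with observable `v2`.
#' @export
build_mutant_core <- function(params, pssg, gsh) {
  .require_params(params, c("k1", "k2p_mut", "grx_tot"))
  if (pssg < 0 || gsh < 0)
    stop("clamped concentrations must be >= 0", call. = FALSE)
  species <- data.frame(
    name = c("GrxSH", "GrxSSG", "PSSG", "PSH", "GSH", "GSSG"),
    role = c("dynamic", "dynamic", "clamped", "clamped", "clamped",
             "clamped"),
    conc = c(params$grx_tot, 0, pssg, 0, gsh, 0))
  reactions <- list(
    .reaction("v1", c(GrxSH = -1, PSSG = -1, GrxSSG = 1, PSH = 1),
              .rate_mass_action("k1", c(PSSG = 1, GrxSH = 1))),
    .reaction("v2", c(GrxSSG = -1, GSH = -1, GrxSH = 1, GSSG = 1),
              .rate_mass_action("k2p_mut", c(GrxSSG = 1, GSH = 1))))
  conservation <- list(list(name = "Grx", coef = c(GrxSH = 1, GrxSSG = 1),
                            total = params$grx_tot))
  grx_model(species, reactions, conservation, params, observable = "v2")
}

#' Build the glutathione-reductase-coupled deglutathionylation system
#'
#' Three reactions modelled after a bacterial glutaredoxin system:
#' glutathione reductase (generic irreversible two-substrate law on NADPH
#' and GSSG), glutaredoxin reduction by two GSH (mass action, order 2 in
#' GSH), and deglutathionylation of a clamped substrate PSSG.
#' With `reversible = TRUE` the deglutathionylation step carries the net
#' rate \eqn{k_1([Grx(SH)_2][PSSG] - [GrxSS][PSH][GSH]/K_{eq})}, with
#' `keq_deglut` in uM.
#'
#' NADPH and NADP must be supplied in `clamped` and are always clamped, as
#' is the reduced substrate PSH (a pure product in the irreversible variant,
#' and required for the reverse rate; without clamping it no steady state
#' would exist). GSH may be clamped (reciprocal-plot protocols) or left
#' dynamic, in which case the glutathione moiety `GSH + 2 GSSG` is
#' registered.
#'
#' @param params a [grx_params()] object; needs `k1`, `k2_wt`, `grx_tot`,
#'   the GR parameters and, if `reversible`, `keq_deglut`.
#' @param reversible logical; make the deglutathionylation step reversible.
#' @param clamped named concentration vector, uM. Must include `NADPH` and
#'   `NADP`; recognised names: NADPH, NADP, GSH, GSSG, PSSG, PSH.
#' @param gsh_init,gssg_init initial values (uM) used when GSH is left
#'   dynamic.
#' @return A `grx_model` with observable `deglut`.
#' @export
#' @examples
#' m <- build_ecoli_system(ecoli_default_params(),
#'                         clamped = c(NADPH = 250, NADP = 1, GSH = 1000,
#'                                     PSSG = 5))
#' steady_state(m)
build_ecoli_system <- function(params, reversible = FALSE, clamped,
                               gsh_init = 1000, gssg_init = 1) {
  .require_params(params, c("k1", "k2_wt", "grx_tot",
                            "gr_kcat", "gr_K_NADPH", "gr_K_GSSG", "gr_conc"))
  if (reversible) .require_params(params, "keq_deglut")
  known <- c("NADPH", "NADP", "GSH", "GSSG", "PSSG", "PSH")
  if (is.null(names(clamped)) || !all(names(clamped) %in% known))
    stop("clamped must be a named vector over ",
         paste(known, collapse = ", "), call. = FALSE)
  if (!all(c("NADPH", "NADP") %in% names(clamped)))
    stop("invalid model: NADPH and NADP must be clamped", call. = FALSE)
  if (reversible && !"PSH" %in% names(clamped))
    stop("invalid model: reversible deglutathionylation requires a clamped ",
         "PSH concentration", call. = FALSE)
  if (!"PSSG" %in% names(clamped))
    stop("invalid model: PSSG must be clamped", call. = FALSE)
  if (!"PSH" %in% names(clamped)) clamped["PSH"] <- 1
  gsh_clamped <- "GSH" %in% names(clamped)

  conc0 <- c(NADPH = NA, NADP = NA, PSSG = NA, PSH = NA,
             GSH = gsh_init, GSSG = gssg_init)
  conc0[names(clamped)] <- clamped
  role <- ifelse(names(conc0) %in% names(clamped), "clamped", "dynamic")
  species <- data.frame(
    name = c(names(conc0), "GrxSH2", "GrxSS"),
    role = c(role, "dynamic", "dynamic"),
    conc = c(unname(conc0), params$grx_tot, 0))

  deglut_rate <- if (reversible)
    .rate_mass_action("k1", c(GrxSH2 = 1, PSSG = 1),
                      reverse_order = c(GrxSS = 1, PSH = 1, GSH = 1),
                      keq_ref = "keq_deglut")
  else .rate_mass_action("k1", c(GrxSH2 = 1, PSSG = 1))

  reactions <- list(
    .reaction("GR", c(NADPH = -1, GSSG = -1, GSH = 2, NADP = 1),
              .rate_two_substrate("gr_kcat", "gr_conc",
                                  "NADPH", "gr_K_NADPH", "GSSG", "gr_K_GSSG")),
    .reaction("GrxRed", c(GrxSS = -1, GSH = -2, GrxSH2 = 1, GSSG = 1),
              .rate_mass_action("k2_wt", c(GrxSS = 1, GSH = 2))),
    .reaction("deglut", c(GrxSH2 = -1, PSSG = -1, GrxSS = 1, PSH = 1,
                          GSH = 1),
              deglut_rate))
  # Only the glutaredoxin moiety is registered: the deglutathionylation step
  # releases one GSH per clamped PSSG consumed, so with GSH dynamic the
  # free-glutathione pool gains a GSH per catalytic cycle (the donor PSSG
  # being clamped) and GSH + 2 GSSG is not invariant. Reciprocal-plot
  # protocols clamp GSH anyway.
  if (!gsh_clamped && "GSSG" %in% names(clamped))
    stop("invalid model: GSSG cannot be clamped while GSH is dynamic",
         call. = FALSE)
  conservation <- list(list(name = "Grx", coef = c(GrxSH2 = 1, GrxSS = 1),
                            total = params$grx_tot))
  grx_model(species, reactions, conservation, params, observable = "deglut")
}

#' Default placeholder parameters for the coupled system
#'
#' Representative magnitudes for [build_ecoli_system()]: `k1` 0.1 uM^-1
#' s^-1, `k2_wt` 4.23e-6 uM^-2 s^-1, `grx_tot` 1 uM, `keq_deglut` 1 uM and
#' the glutathione-reductase constants of [grx_profile()]. These are
#' documentation-level placeholders for a system whose literature constants
#' are not packaged; analyses built on this model are pattern-level
#' (linearity, parallel versus converging reciprocal lines), not
#' value-level.
#'
#' @return A [grx_params()] object.
#' @export
ecoli_default_params <- function() {
  grx_params(k1 = 0.1, k2_wt = 4.23e-6, grx_tot = 1, keq_deglut = 1)
}

#' Build the yeast HED activity-assay model
#'
#' The standard glutaredoxin activity assay couples HED
#' (beta-hydroxyethyl disulphide) reduction to NADPH consumption through
#' glutathione reductase. Three reactions: glutathione reductase (generic
#' two-substrate law), glutaredoxin reduction by two GSH (`k2_wt`), and the
#' lumped HED-reduction step `GrxSH2 + HED -> GrxSS` with rate
#' `k_hed * [GrxSH2][HED]`. HED enters as the glutathionylated substrate of
#' the lumped reaction; the spontaneous HED + GSH pre-equilibrium is not
#' modelled separately, so the step is net glutathione-neutral. NADPH, NADP
#' and HED are clamped; GSH/GSSG and the glutaredoxin couple are dynamic
#' with their moieties registered. The measured assay flux (NADPH
#' consumption) is the GR flux, which equals the HED-reduction flux at
#' steady state.
#'
#' @param params a [grx_params()] object; needs `k2_wt`, `k_hed` and the GR
#'   parameters (`grx_tot` is taken from the species table).
#' @param table1 named species concentration vector with entries NADPH,
#'   NADP, GSH, GSSG, HED, GrxSH2, GrxSS (uM); defaults to the Grx1 profile
#'   of [grx_profile()].
#' @return A `grx_model` with observable `GR`.
#' @export
#' @examples
#' prof <- grx_profile("grx1")
#' m <- build_hed_assay(prof$params, prof$species)
#' steady_state(m)
build_hed_assay <- function(params, table1 = grx_profile("grx1")$species) {
  .require_params(params, c("k2_wt", "k_hed",
                            "gr_kcat", "gr_K_NADPH", "gr_K_GSSG", "gr_conc"))
  need <- c("NADPH", "NADP", "GSH", "GSSG", "HED", "GrxSH2", "GrxSS")
  miss <- setdiff(need, names(table1))
  if (length(miss))
    stop("configuration error: missing species concentration(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  grx_tot <- unname(table1["GrxSH2"] + table1["GrxSS"])
  if (grx_tot <= 0)
    stop("invalid model: total glutaredoxin must be positive", call. = FALSE)
  params <- set_params(params, grx_tot = grx_tot)
  species <- data.frame(
    name = need,
    role = c("clamped", "clamped", "dynamic", "dynamic", "clamped",
             "dynamic", "dynamic"),
    conc = unname(table1[need]))
  reactions <- list(
    .reaction("GR", c(NADPH = -1, GSSG = -1, GSH = 2, NADP = 1),
              .rate_two_substrate("gr_kcat", "gr_conc",
                                  "NADPH", "gr_K_NADPH", "GSSG", "gr_K_GSSG")),
    .reaction("GrxRed", c(GrxSS = -1, GSH = -2, GrxSH2 = 1, GSSG = 1),
              .rate_mass_action("k2_wt", c(GrxSS = 1, GSH = 2))),
    .reaction("HEDRed", c(GrxSH2 = -1, HED = -1, GrxSS = 1),
              .rate_mass_action("k_hed", c(GrxSH2 = 1, HED = 1))))
  conservation <- list(
    list(name = "Grx", coef = c(GrxSH2 = 1, GrxSS = 1), total = grx_tot),
    list(name = "glutathione", coef = c(GSH = 1, GSSG = 2),
         total = unname(table1["GSH"] + 2 * table1["GSSG"])))
  grx_model(species, reactions, conservation, params, observable = "GR")
}
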