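# --- compiled model form -----------------------------------------------------
#
# Steady-state solving inside fitting loops evaluates the network thousands
# of times, so the declarative model is "compiled" once into index-based
# closures: a rate evaluator over an unnamed concentration vector and the
# stoichiometric matrix restricted to dynamic species.

.compile_model <- function(model) {
  sp <- model$species
  idx <- stats::setNames(seq_len(nrow(sp)), sp$name)
  dyn <- which(sp$role == "dynamic")
  nrx <- length(model$reactions)

  rate_funs <- lapply(model$reactions, function(rx) {
    r <- rx$rate
    if (r$type == "mass_action") {
      oi <- idx[names(r$order)]
      oe <- unname(r$order)
      k_ref <- r$k_ref
      if (!isTRUE(r$reversible)) {
        function(conc, p) p[[k_ref]] * prod(conc[oi]^oe)
      } else {
        ri <- idx[names(r$reverse_order)]
        re <- unname(r$reverse_order)
        keq_ref <- r$keq_ref
        function(conc, p)
          p[[k_ref]] * (prod(conc[oi]^oe) - prod(conc[ri]^re) / p[[keq_ref]])
      }
    } else { # two_substrate
      ai <- idx[[r$A]]; bi <- idx[[r$B]]
      kc <- r$kcat_ref; er <- r$E_ref; ka <- r$Ka_ref; kb <- r$Kb_ref
      function(conc, p) {
        a <- conc[ai] / p[[ka]]
        b <- conc[bi] / p[[kb]]
        p[[kc]] * p[[er]] * a * b / ((1 + a) * (1 + b))
      }
    }
  })

  S <- matrix(0, nrow = nrow(sp), ncol = nrx,
              dimnames = list(sp$name, names(model$reactions)))
  for (j in seq_len(nrx)) {
    st <- model$reactions[[j]]$stoich
    S[idx[names(st)], j] <- st
  }
  # clamped species never change
  S_dyn <- S
  S_dyn[sp$role == "clamped", ] <- 0

  list(idx = idx, dyn = dyn, conc0 = sp$conc, rate_funs = rate_funs,
       S = S, S_dyn = S_dyn, params = model$params,
       species = sp$name, rxn = names(model$reactions),
       conservation = model$conservation)
}

.rates <- function(cm, conc) {
  vapply(cm$rate_funs, function(f) f(conc, cm$params), numeric(1L))
}

.derivs <- function(cm, conc) {
  drop(cm$S_dyn %*% .rates(cm, conc))
}

#' Integrate a model in time
#'
#' Solves the model's ODE system with a stiff-capable integrator
#' ([deSolve::lsoda()]); the packaged assay model mixes rate constants of
#' order 900 s^-1 and 1e-6 uM^-2 s^-1, so stiffness is the norm. Clamped
#' species are held at their set values.
#'
#' @param model a `grx_model`.
#' @param t_end end time, s (> 0).
#' @param n_points number of equally spaced output times (including 0).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param times optional explicit output-time vector overriding
#'   `t_end`/`n_points`.
#' @return A `grx_trajectory`: a data.frame with column `time`, one column
#'   per species (uM) and one flux column per reaction (`flux.<id>`,
#'   uM s^-1).
#' @export
#' @examples
#' m <- build_wildtype_core(grx_params(k1 = 1, k2_wt = 1, grx_tot = 1),
#'                          pssg = 2, gsh = sqrt(2))
#' tc <- time_course(m, t_end = 10)
#' tail(tc, 1)
time_course <- function(model, t_end, n_points = 201, rtol = 1e-8,
                        atol = 1e-10, times = NULL) {
  stopifnot(inherits(model, "grx_model"))
  if (is.null(times)) {
    if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                               call. = FALSE)
    times <- seq(0, t_end, length.out = n_points)
  }
  cm <- .compile_model(model)
  y0 <- cm$conc0[cm$dyn]
  names(y0) <- cm$species[cm$dyn]
  conc <- cm$conc0
  rhs <- function(t, y, parms) {
    conc[cm$dyn] <- pmax(y, 0) # guard against negative trial values
    list(.derivs(cm, conc)[cm$dyn])
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integration failure (non-convergence); last valid time ",
         max(sol[, 1L]), call. = FALSE)
  states <- matrix(rep(cm$conc0, each = nrow(sol)), nrow = nrow(sol),
                   dimnames = list(NULL, cm$species))
  states[, cm$species[cm$dyn]] <- sol[, -1L, drop = FALSE]
  if (any(states < -atol))
    stop("negative concentration in integration output", call. = FALSE)
  states[states < 0] <- 0
  fluxes <- t(apply(states, 1L, function(conc) .rates(cm, conc)))
  colnames(fluxes) <- paste0("flux.", cm$rxn)
  out <- data.frame(time = sol[, 1L], states, fluxes, check.names = FALSE)
  class(out) <- c("grx_trajectory", "data.frame")
  attr(out, "model") <- model
  out
}

#' Moiety-conservation drift of a trajectory
#'
#' @param trajectory a `grx_trajectory`.
#' @return Named vector of maximal relative drifts, one per registered
#'   moiety.
#' @export
conservation_drift <- function(trajectory) {
  model <- attr(trajectory, "model")
  vapply(model$conservation, function(cons) {
    tot <- as.matrix(trajectory[names(cons$coef)]) %*% cons$coef
    max(abs(tot - cons$total)) / cons$total
  }, numeric(1L)) |>
    stats::setNames(vapply(model$conservation, `[[`, "", "name"))
}

# --- steady state ------------------------------------------------------------

# choose, per conservation relation, one dynamic species to eliminate; the
# remaining dynamic species are the free root-finding variables.
.reduction_plan <- function(cm) {
  dyn_names <- cm$species[cm$dyn]
  elim <- integer(0)
  cons_list <- list()
  for (cons in cm$conservation) {
    members <- intersect(names(cons$coef), dyn_names)
    members <- setdiff(members, cm$species[elim])
    if (length(members) == 0L)
      stop("conservation relation '", cons$name,
           "' has no dynamic species left to eliminate", call. = FALSE)
    pick <- members[[length(members)]]
    elim <- c(elim, cm$idx[[pick]])
    cons_list[[length(cons_list) + 1L]] <-
      list(elim = cm$idx[[pick]], coef_elim = cons$coef[[pick]],
           others = cm$idx[setdiff(names(cons$coef), pick)],
           coef_others = cons$coef[setdiff(names(cons$coef), pick)],
           total = cons$total)
  }
  free <- setdiff(cm$dyn, elim)
  list(free = free, elim = elim, cons = cons_list)
}

.apply_conservation <- function(conc, plan) {
  for (cs in plan$cons)
    conc[cs$elim] <- (cs$total -
                        sum(cs$coef_others * conc[cs$others])) / cs$coef_elim
  conc
}

# rescale free moiety members so that every eliminated species is
# non-negative (used to repair infeasible starting points)
.project_feasible <- function(conc, plan) {
  for (cs in plan$cons) {
    if (length(cs$others) == 0L) next
    occupied <- sum(cs$coef_others * conc[cs$others])
    if (occupied > cs$total)
      conc[cs$others] <- conc[cs$others] * (cs$total / occupied)
  }
  .apply_conservation(conc, plan)
}

#' Solve a model to steady state
#'
#' Finds concentrations at which every dynamic species has zero net rate,
#' subject to the registered moiety-conservation relations (one species per
#' moiety is eliminated algebraically before root finding, which keeps the
#' Jacobian non-singular for moiety-closed mass-action networks). Strategy:
#' damped Newton iteration with a finite-difference Jacobian, initialized
#' from the model's state (or `init`); if Newton stalls, the system is
#' relaxed by stiff time integration over geometrically growing horizons
#' and Newton is retried.
#'
#' @param model a `grx_model` with at least one dynamic species.
#' @param atol convergence tolerance on `max |d[x]/dt|`, uM s^-1. The
#'   effective tolerance is `atol` relaxed by the double-precision rounding
#'   floor of the derivative evaluation (estimated from the Jacobian and
#'   state magnitudes); the implied concentration error remains at relative
#'   machine precision, so accepting that floor costs no accuracy.
#' @param init optional named concentration vector used as the starting
#'   point (defaults to the model's initial state).
#' @param on_fail `"error"` to raise on non-convergence, `"flag"` to return
#'   with `converged = FALSE`.
#' @return A `grx_steady_state`: list with `state` (all species, uM),
#'   `fluxes` (per reaction, uM s^-1), `residual` (max |d[x]/dt|),
#'   `converged`.
#' @export
steady_state <- function(model, atol = 1e-10, init = NULL,
                         on_fail = c("error", "flag")) {
  stopifnot(inherits(model, "grx_model"))
  on_fail <- match.arg(on_fail)
  cm <- .compile_model(model)
  if (length(cm$dyn) == 0L)
    stop("model has no dynamic species", call. = FALSE)
  res <- .steady_state_cm(cm, atol = atol, init = init)
  if (!res$converged && on_fail == "error")
    stop("no steady state found (residual ", format(res$residual),
         " uM/s after relaxation; a dynamic species may grow without ",
         "bound)", call. = FALSE)
  state <- res$conc
  names(state) <- cm$species
  fluxes <- .rates(cm, res$conc)
  names(fluxes) <- cm$rxn
  structure(list(state = state, fluxes = fluxes, residual = res$residual,
                 converged = res$converged, model = model),
            class = "grx_steady_state")
}

# core solver on a compiled model; used directly by the fitting loop.
.steady_state_cm <- function(cm, atol = 1e-10, init = NULL) {
  conc <- cm$conc0
  if (!is.null(init)) { # init only seeds dynamic species; clamps are fixed
    i <- match(names(init), cm$species)
    keep <- !is.na(i) & i %in% cm$dyn
    conc[i[keep]] <- init[keep]
  }
  conc <- .apply_conservation(conc, plan <- .reduction_plan(cm))
  conc[cm$dyn] <- pmax(conc[cm$dyn], 0)

  try_newton <- function(conc) .newton_ss(cm, plan, conc, atol)
  res <- try_newton(conc)
  if (res$converged) return(res)

  # relaxation fallback: integrate over growing horizons, then re-try Newton
  t_end <- 1
  for (k in 1:14) {
    conc <- .relax(cm, res$conc, t_end)
    res <- try_newton(conc)
    if (res$converged) return(res)
    t_end <- t_end * 10
  }
  res
}

.relax <- function(cm, conc, t_end) {
  y0 <- conc[cm$dyn]
  rhs <- function(t, y, parms) {
    conc[cm$dyn] <- pmax(y, 0)
    list(.derivs(cm, conc)[cm$dyn])
  }
  sol <- try(suppressWarnings(
    deSolve::lsoda(y = y0, times = c(0, t_end), func = rhs,
                   parms = NULL, rtol = 1e-10, atol = 1e-12)),
    silent = TRUE)
  if (!inherits(sol, "try-error") && nrow(sol) == 2L)
    conc[cm$dyn] <- pmax(sol[2L, -1L], 0)
  conc
}

.newton_ss <- function(cm, plan, conc, atol, max_iter = 60L) {
  free <- plan$free
  free_pos <- match(free, cm$dyn)
  conc[cm$dyn] <- pmax(conc[cm$dyn], 0)
  conc <- .project_feasible(conc, plan)
  scale <- pmax(abs(conc[cm$dyn]), 1e-3)
  g_of <- function(y) {
    conc[free] <- y
    conc <- .apply_conservation(conc, plan)
    if (any(conc[cm$dyn] < 0)) return(NULL)
    .derivs(cm, conc)[cm$dyn]
  }
  # convergence is judged against atol relaxed by the double-precision
  # rounding floor of the derivative evaluation, estimated as
  # ||J|| * ||y||: cancellation between opposing fluxes (and inside the
  # moiety subtractions) makes a smaller residual unattainable for very
  # fast parameter regimes. The implied concentration error stays at
  # residual/||J||, i.e. relative machine precision.
  tol_rates <- function(y) {
    conc[free] <- y
    conc <- .apply_conservation(conc, plan)
    max(atol, 1e-12 * max(abs(.rates(cm, pmax(conc, 0)))))
  }
  wrap <- function(y, g_all, converged) {
    list(conc = .apply_conservation(`[<-`(conc, free, y), plan),
         residual = max(abs(g_all)), converged = converged)
  }
  y <- conc[free]
  g_all <- g_of(y)
  if (is.null(g_all)) # infeasible despite projection: give up here
    return(list(conc = conc, residual = Inf, converged = FALSE))
  if (length(free) == 0L)
    return(wrap(y, g_all, max(abs(g_all)) < tol_rates(y)))
  gy <- g_all[free_pos]
  tol <- tol_rates(y)
  for (iter in seq_len(max_iter)) {
    if (max(abs(g_all)) < tol) return(wrap(y, g_all, TRUE))
    # forward-difference Jacobian of the free-species derivatives
    J <- matrix(0, length(free), length(free))
    ys <- pmax(abs(y), scale[free_pos])
    for (j in seq_along(free)) {
      h <- 1e-7 * ys[j]
      yp <- y; yp[j] <- yp[j] + h
      gp <- g_of(yp)
      if (is.null(gp)) { yp[j] <- y[j] - h; h <- -h; gp <- g_of(yp) }
      if (is.null(gp)) return(wrap(y, g_all, FALSE))
      J[, j] <- (gp[free_pos] - gy) / h
    }
    tol <- max(tol, 1e-13 * max(abs(J) %*% ys))
    if (max(abs(g_all)) < tol) return(wrap(y, g_all, TRUE))
    step <- try(solve(J, -gy), silent = TRUE)
    if (inherits(step, "try-error")) {
      step <- try(qr.solve(J, -gy, tol = 1e-300), silent = TRUE)
      if (inherits(step, "try-error")) return(wrap(y, g_all, FALSE))
    }
    # damping: shrink until inside the positive orthant and norm decreases
    alpha <- 1
    improved <- FALSE
    for (half in 1:40) {
      y_new <- y + alpha * step
      g_new <- if (any(y_new < 0)) NULL else g_of(y_new)
      if (!is.null(g_new) &&
          max(abs(g_new[free_pos])) <=
            (1 - 1e-4 * alpha) * max(abs(gy)) + atol / 2) {
        y <- y_new
        g_all <- g_new
        gy <- g_new[free_pos]
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) return(wrap(y, g_all, max(abs(g_all)) < tol))
  }
  wrap(y, g_all, max(abs(g_all)) < tol)
}

#' @export
print.grx_steady_state <- function(x, ...) {
  cat("Steady state (", if (x$converged) "converged" else "NOT converged",
      "; residual ", format(x$residual, digits = 3), " uM/s)\n", sep = "")
  cat("  species (uM):\n")
  for (nm in names(x$state))
    cat(sprintf("    %-8s %g\n", nm, x$state[[nm]]))
  cat("  fluxes (uM/s):\n")
  for (nm in names(x$fluxes))
    cat(sprintf("    %-8s %g\n", nm, x$fluxes[[nm]]))
  invisible(x)
}

#' Steady-state flux of one reaction
#'
#' Convenience projection of [steady_state()].
#'
#' @inheritParams steady_state
#' @param reaction_id reaction id; defaults to the model's observable
#'   reaction.
#' @param ... passed to [steady_state()].
#' @return Flux in uM s^-1.
#' @export
steady_state_flux <- function(model, reaction_id = model$observable, ...) {
  ss <- steady_state(model, ...)
  if (!reaction_id %in% names(ss$fluxes))
    stop("unknown reaction id '", reaction_id, "'", call. = FALSE)
  unname(ss$fluxes[[reaction_id]])
}
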