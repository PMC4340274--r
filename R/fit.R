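#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot` for observed/predicted rate vectors.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return Dimensionless r-squared (<= 1; can be negative for fits worse
#'   than the mean).
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("observed and predicted must have equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed rates have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit rate constants of a kinetic model to an assay dataset
#'
#' Nonlinear least squares by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). For each trial parameter vector, the whole
#' reaction system is solved to steady state at every dataset point (the
#' varied species clamped at the point's x); residuals are
#' `observed - predicted` steady-state observable flux, optionally 1/sd
#' weighted. Parameters are optimised on the log scale, so estimates are
#' positive by construction; trial points where the steady-state solver
#' fails incur a large penalty residual instead of aborting the
#' optimisation.
#'
#' When `init` is not given, a crude 5-per-parameter log-spaced grid search
#' spanning one decade below and above the template's current values picks
#' the starting point.
#'
#' Standard errors are asymptotic, from the residual Jacobian at the
#' optimum (delta method back from the log scale), and are reported only
#' when that Jacobian is full rank; 95% confidence intervals are
#' `exp(log(est) +/- t_{0.975, n-p} * se_log)`.
#'
#' @param model a `grx_model` template; the dataset's varied species must
#'   be clamped in it.
#' @param free_params character vector of parameter names to estimate
#'   (fields of [grx_params()] referenced by the model's reactions).
#' @param dataset an [assay_dataset()].
#' @param init optional named numeric starting values (native units).
#' @param bounds optional list with named numeric vectors `lower`/`upper`
#'   (native units) enforced during optimisation.
#' @param weights `"none"` or `"sd"`.
#' @param atol steady-state tolerance used inside the objective.
#' @return An object of class `grx_fit`: estimates, std_errors, ci, r2,
#'   n_points, converged, residuals, init_used, fitted.values and the data.
#' @seealso [generate_hed_dataset()] for synthetic data to fit;
#'   [recovery_experiment()] for Monte-Carlo recovery studies.
#' @export
#' @examples
#' \donttest{
#' prof <- grx_profile("grx1")
#' m <- build_hed_assay(prof$params, prof$species)
#' d <- generate_hed_dataset(prof$params, "grx1",
#'                           noise = noise_model(cv = 0, seed = 1))
#' fit <- fit_rate_constants(m, c("k2_wt", "k_hed"), d)
#' summary(fit)
#' }
fit_rate_constants <- function(model, free_params, dataset, init = NULL,
                               bounds = NULL, weights = c("none", "sd"),
                               atol = 1e-10) {
  stopifnot(inherits(model, "grx_model"), inherits(dataset, "assay_dataset"))
  weights <- match.arg(weights)
  bad <- setdiff(free_params, names(model$params))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  varied <- attr(dataset, "varied_species")
  i <- match(varied, model$species$name)
  if (is.na(i) || model$species$role[i] != "clamped")
    stop("dataset's varied species '", varied,
         "' is not a clamped species of the model", call. = FALSE)

  x <- dataset$x
  y <- dataset$rate
  w <- if (weights == "sd" && !is.null(dataset$sd)) 1 / dataset$sd
       else rep(1, length(x))
  penalty <- 100 * max(abs(y), 1)
  obs_id <- model$observable
  varied_idx <- i

  cm0 <- .compile_model(model)
  obs_j <- match(obs_id, cm0$rxn)
  ux <- sort(unique(x))
  ord <- match(x, ux)

  # predicted observable flux at each unique x for trial params (native)
  predict_rates <- function(theta) {
    p <- cm0$params
    p[free_params] <- as.list(theta)
    cm <- cm0
    cm$params <- p
    out <- numeric(length(ux))
    init_state <- NULL
    ok <- TRUE
    for (k in seq_along(ux)) {
      cm$conc0[varied_idx] <- ux[k]
      res <- .steady_state_cm(cm, atol = atol, init = init_state)
      if (!res$converged) { out[k] <- NA_real_; ok <- FALSE; next }
      out[k] <- .rates(cm, res$conc)[obs_j]
      init_state <- stats::setNames(res$conc, cm$species)
    }
    list(rates = out[ord], ok = ok)
  }

  # starting point: supplied, else crude grid search around template values
  if (is.null(init)) {
    centre <- unlist(model$params[free_params])
    if (anyNA(centre))
      stop("model template has no value for ",
           paste(free_params[is.na(centre)], collapse = ", "),
           "; supply init", call. = FALSE)
    grids <- lapply(centre, function(v) 10^seq(log10(v) - 1, log10(v) + 1,
                                               length.out = 5))
    combos <- as.matrix(expand.grid(grids))
    ssr <- apply(combos, 1L, function(theta) {
      pr <- predict_rates(theta)$rates
      if (anyNA(pr)) Inf else sum((w * (y - pr))^2)
    })
    init <- stats::setNames(combos[which.min(ssr), ], free_params)
  } else {
    init <- init[free_params]
    if (anyNA(init) || any(init <= 0))
      stop("init must supply a positive value for every free parameter",
           call. = FALSE)
  }

  lower <- rep(-Inf, length(free_params))
  upper <- rep(Inf, length(free_params))
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower))
      lower[match(names(bounds$lower), free_params)] <- log(bounds$lower)
    if (!is.null(bounds$upper))
      upper[match(names(bounds$upper), free_params)] <- log(bounds$upper)
  }

  n_fail <- 0L
  resid_fun <- function(lp) {
    pr <- predict_rates(exp(lp))
    r <- w * (y - pr$rates)
    if (anyNA(r)) {
      n_fail <<- n_fail + 1L
      r[is.na(r)] <- penalty
    }
    r
  }
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid_fun,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-12))
  lp <- fit$par
  estimates <- stats::setNames(exp(lp), free_params)
  final <- predict_rates(estimates)
  converged <- fit$info %in% 1:4 && final$ok
  pred <- final$rates
  resids <- y - pred

  se <- NULL
  ci <- NULL
  cov_try <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov_try) && all(is.finite(cov_try))) {
    dof <- max(length(y) - length(lp), 1L)
    se_log <- sqrt(pmax(diag(cov_try) * fit$deviance / dof, 0))
    se <- stats::setNames(estimates * se_log, free_params)
    tq <- stats::qt(0.975, dof) # residual variance is estimated: t, not z
    ci <- cbind(lower = exp(lp - tq * se_log),
                upper = exp(lp + tq * se_log))
    rownames(ci) <- free_params
  }

  structure(list(estimates = estimates, std_errors = se, ci = ci,
                 r2 = if (anyNA(pred)) NA_real_ else r_squared(y, pred),
                 n_points = length(y), converged = converged,
                 residuals = resids, fitted.values = pred,
                 init_used = init, n_solver_failures = n_fail,
                 deviance = fit$deviance, info = fit$info,
                 message = fit$message,
                 model = model, dataset = dataset,
                 free_params = free_params),
            class = "grx_fit")
}

#' @export
print.grx_fit <- function(x, ...) {
  cat("Rate-constant fit (Levenberg-Marquardt on steady-state rates)\n")
  cat("  ", x$n_points, " points, r2 = ",
      formatC(x$r2, digits = 6, format = "fg"),
      if (!x$converged) ", NOT converged", "\n", sep = "")
  for (nm in x$free_params) {
    cat(sprintf("  %-9s %-12.6g", nm, x$estimates[[nm]]))
    if (!is.null(x$std_errors))
      cat(sprintf(" +/- %.3g", x$std_errors[[nm]]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.grx_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$ci)) {
    cat("  95% confidence intervals:\n")
    for (nm in object$free_params)
      cat(sprintf("    %-9s [%.6g, %.6g]\n", nm,
                  object$ci[nm, "lower"], object$ci[nm, "upper"]))
  }
  cat("  residual SS: ", format(object$deviance), "; solver failures ",
      "during optimisation: ", object$n_solver_failures, "\n", sep = "")
  cat("  optimizer: ", object$message, "\n", sep = "")
  invisible(object)
}

#' @export
coef.grx_fit <- function(object, ...) object$estimates

#' @export
residuals.grx_fit <- function(object, ...) object$residuals

#' Predict steady-state rates from a fitted model
#'
#' @param object a `grx_fit`.
#' @param newdata optional numeric vector of varied-species concentrations
#'   (uM); defaults to the fitted dataset's x values.
#' @param ... unused.
#' @return Predicted observable rates, uM s^-1.
#' @export
predict.grx_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$dataset$x else newdata
  model <- do.call(set_model_params,
                   c(list(object$model), as.list(object$estimates)))
  varied <- attr(object$dataset, "varied_species")
  vapply(x, function(xi)
    steady_state_flux(set_clamped(model, varied, xi)), numeric(1L))
}

#' Plot a rate-constant fit
#'
#' Observed rates against the varied concentration with the fitted
#' steady-state curve overlaid.
#'
#' @param x a `grx_fit`.
#' @param n_curve number of points for the fitted curve.
#' @param ... passed to [plot()].
#' @export
plot.grx_fit <- function(x, n_curve = 60, ...) {
  d <- x$dataset
  varied <- attr(d, "varied_species")
  plot(d$x, d$rate, xlab = paste0(varied, " (uM)"),
       ylab = "rate (uM/s)", log = "x", ...)
  xs <- exp(seq(log(min(d$x[d$x > 0])), log(max(d$x)),
                length.out = n_curve))
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}
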