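#' Enzyme-assay dataset container
#'
#' A data.frame of (varied concentration, steady-state rate) points with
#' assay metadata attached: the name of the varied species, the fixed
#' concentrations of everything else, optional per-point rate standard
#' deviations, and free-form provenance. Replicate measurements share the
#' same `x`; `x` must be unique within each replicate.
#'
#' @param x varied species concentrations, uM (>= 0).
#' @param rate steady-state rates, uM s^-1 (>= 0).
#' @param sd optional rate standard deviations, uM s^-1.
#' @param replicate optional integer replicate index (default all 1).
#' @param varied_species name of the varied species.
#' @param fixed named numeric vector of fixed concentrations, uM.
#' @param meta list of free-form provenance entries (generator settings,
#'   seed, ...).
#' @return An object of class `assay_dataset` (a data.frame with columns
#'   `x`, `rate`, optionally `sd`, and `replicate`).
#' @export
assay_dataset <- function(x, rate, sd = NULL, replicate = NULL,
                          varied_species = "x", fixed = numeric(0),
                          meta = list()) {
  stopifnot(length(x) == length(rate))
  if (any(x < 0)) stop("x values must be >= 0", call. = FALSE)
  if (any(rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (is.null(replicate)) replicate <- rep(1L, length(x))
  stopifnot(length(replicate) == length(x))
  for (r in unique(replicate))
    if (anyDuplicated(x[replicate == r]))
      stop("x values must be unique within a replicate", call. = FALSE)
  d <- data.frame(x = x, rate = rate)
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(x))
    d$sd <- sd
  }
  d$replicate <- as.integer(replicate)
  structure(d, varied_species = varied_species, fixed = fixed, meta = meta,
            class = c("assay_dataset", "data.frame"))
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat("Assay dataset: rate vs ", attr(x, "varied_species"), ", ",
      nrow(x), " points (", length(unique(x$replicate)), " replicate",
      if (length(unique(x$replicate)) > 1L) "s", ")\n", sep = "")
  fixed <- attr(x, "fixed")
  if (length(fixed))
    cat("  fixed: ", paste(names(fixed), "=", fixed, "uM",
                           collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more rows\n", sep = "")
  invisible(x)
}

#' Steady-state saturation curve of a model
#'
#' Sweeps a clamped species over a concentration grid, solving the model to
#' steady state at each value (warm-starting each solve from the previous
#' solution) and recording the observable reaction flux.
#'
#' @param model a `grx_model`.
#' @param varied_species name of a clamped species in the model.
#' @param values concentration grid, uM (>= 0).
#' @param reaction_id reaction whose flux is recorded (default: the model's
#'   observable).
#' @param atol steady-state tolerance passed to [steady_state()].
#' @return An [assay_dataset()] with the remaining clamped concentrations
#'   in its `fixed` attribute.
#' @export
#' @examples
#' m <- build_wildtype_core(grx_params(k1 = 0.073, k2_wt = 4.23e-6,
#'                                     grx_tot = 0.24), pssg = 70, gsh = 998)
#' saturation_curve(m, "GSH", c(100, 300, 1000, 3000))
saturation_curve <- function(model, varied_species, values,
                             reaction_id = model$observable, atol = 1e-10) {
  stopifnot(inherits(model, "grx_model"))
  i <- match(varied_species, model$species$name)
  if (is.na(i) || model$species$role[i] != "clamped")
    stop("varied species '", varied_species,
         "' must be a clamped species of the model", call. = FALSE)
  if (any(values < 0)) stop("grid values must be >= 0", call. = FALSE)
  rates <- numeric(length(values))
  init <- NULL
  for (j in seq_along(values)) {
    mj <- set_clamped(model, varied_species, values[j])
    ss <- steady_state(mj, atol = atol, init = init, on_fail = "flag")
    if (!ss$converged)
      stop("steady-state solver failed at ", varied_species, " = ",
           values[j], " uM (residual ", format(ss$residual), ")",
           call. = FALSE)
    rates[j] <- ss$fluxes[[reaction_id]]
    init <- ss$state
  }
  fixed_i <- model$species$role == "clamped" & model$species$name != varied_species
  fixed <- stats::setNames(model$species$conc[fixed_i],
                           model$species$name[fixed_i])
  assay_dataset(values, rates, varied_species = varied_species,
                fixed = fixed,
                meta = list(reaction = reaction_id, source = "steady_state"))
}

#' Double-reciprocal transform of an assay dataset
#'
#' Returns (1/x, 1/rate) for all points with strictly positive x and rate;
#' zero or near-zero points are dropped and counted.
#'
#' @param dataset an [assay_dataset()].
#' @param eps positivity threshold below which points are dropped.
#' @return A data.frame with columns `inv_x` and `inv_rate`; the number of
#'   excluded points is in `attr(, "n_dropped")`.
#' @export
to_reciprocal <- function(dataset, eps = .Machine$double.xmin) {
  keep <- dataset$x > eps & dataset$rate > eps
  out <- data.frame(inv_x = 1 / dataset$x[keep],
                    inv_rate = 1 / dataset$rate[keep])
  if (sum(keep) < 3L)
    stop("insufficient data: fewer than 3 usable points after dropping ",
         sum(!keep), " zero/near-zero point(s)", call. = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Classify a family of reciprocal lines as ping-pong or sequential
#'
#' Fits an unweighted ordinary-least-squares line to the double-reciprocal
#' transform of each dataset (the classical Lineweaver-Burk reading) and
#' classifies the family by the spread of the slopes: `"parallel"` (the
#' apparent ping-pong pattern) if the maximal relative slope spread is
#' below `slope_tol`, `"converging"` (apparent sequential pattern) if the
#' spread exceeds the tolerance *and* the slopes are strictly monotone in
#' the glutathione concentration, otherwise `"neither"`. The result is
#' invariant to dataset ordering and to a uniform rescaling of the rates.
#'
#' @param datasets list of [assay_dataset()] objects measured at distinct
#'   GSH concentrations (each must carry `GSH` in its `fixed` attribute, or
#'   be a GSH-varied dataset's sibling; at least 2 datasets with >= 3
#'   usable points each).
#' @param slope_tol relative slope-spread threshold (default 0.05; the
#'   visual parallel-vs-converging call made quantitative).
#' @return An object of class `line_family`: list with `lines`
#'   (data.frame: gsh, slope, intercept, r2), `slope_spread` and
#'   `classification`.
#' @export
classify_line_family <- function(datasets, slope_tol = 0.05) {
  if (length(datasets) < 2L)
    stop("need at least 2 datasets", call. = FALSE)
  gsh <- vapply(datasets, function(d) {
    fx <- attr(d, "fixed")
    if (!"GSH" %in% names(fx))
      stop("each dataset must record a fixed GSH concentration",
           call. = FALSE)
    unname(fx[["GSH"]])
  }, numeric(1L))
  if (anyDuplicated(gsh))
    stop("datasets must be at distinct GSH concentrations", call. = FALSE)
  fits <- lapply(datasets, function(d) {
    r <- to_reciprocal(d)
    fit <- stats::lm(inv_rate ~ inv_x, data = r)
    c(slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r2 = r_squared(r$inv_rate, stats::fitted(fit)))
  })
  lines <- data.frame(gsh = gsh, do.call(rbind, fits))
  lines <- lines[order(lines$gsh), ]
  rownames(lines) <- NULL
  s <- lines$slope
  slope_spread <- if (all(s == s[1L])) 0 else
    (max(s) - min(s)) / abs(mean(s))
  monotone <- all(diff(s) > 0) || all(diff(s) < 0)
  classification <- if (slope_spread < slope_tol) "parallel"
    else if (monotone) "converging" else "neither"
  structure(list(lines = lines, slope_spread = slope_spread,
                 classification = classification, slope_tol = slope_tol),
            class = "line_family")
}

#' @export
print.line_family <- function(x, ...) {
  cat("Reciprocal line family: ", x$classification,
      " (relative slope spread ", format(x$slope_spread, digits = 3),
      ", tolerance ", x$slope_tol, ")\n", sep = "")
  print(x$lines, digits = 6)
  invisible(x)
}

#' Fit a Hill equation to a saturation dataset
#'
#' Least-squares fit of `v = V * s^n / (1 + s^n)`, `s = x / K_half`, on the
#' untransformed rates (no Hill linearisation) by Levenberg-Marquardt with
#' the parameters optimised on the log scale, so positivity holds by
#' construction. Initialisation: `V` at the maximal observed rate, `K_half`
#' at the interpolated half-maximal x, `n = 1`.
#'
#' @param dataset an [assay_dataset()] (>= 5 points; the x-range should
#'   bracket the half-saturation point, otherwise a warning is recorded in
#'   the result's `meta`).
#' @param fix_n optional fixed Hill exponent (e.g. 1 or 2); when given only
#'   `V` and `K_half` are fitted.
#' @param weights `"none"` (default) or `"sd"` for 1/sd weighting when the
#'   dataset carries standard deviations.
#' @return An object of class `hill_fit`: list with `V`, `K_half`, `n`,
#'   `r2`, `converged`, `std_errors`, `meta`. Non-convergence is flagged,
#'   not thrown.
#' @export
#' @examples
#' d <- assay_dataset(x = c(1, 3, 10, 30, 100),
#'                    rate = 2 * (c(1, 3, 10, 30, 100) / 10)^2 /
#'                      (1 + (c(1, 3, 10, 30, 100) / 10)^2))
#' fit_hill(d)
fit_hill <- function(dataset, fix_n = NULL, weights = c("none", "sd")) {
  weights <- match.arg(weights)
  x <- dataset$x
  y <- dataset$rate
  meta <- list()
  if (length(x) < 5L)
    stop("need at least 5 points for a Hill fit", call. = FALSE)
  w <- if (weights == "sd" && !is.null(dataset$sd)) 1 / dataset$sd
       else rep(1, length(x))

  V0 <- max(y)
  K0 <- {
    o <- order(x)
    xo <- x[o]; yo <- y[o]
    half <- V0 / 2
    i <- which(yo >= half)[1L]
    if (is.na(i)) stats::median(xo)
    else if (i == 1L) xo[1L] / 2 # already above half-max at the first point
    else xo[i - 1L] + (half - yo[i - 1L]) * (xo[i] - xo[i - 1L]) /
      (yo[i] - yo[i - 1L])
  }
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(x[x > 0])
  if (K0 < min(x[x > 0]) || K0 > max(x)) {
    meta$range_warning <- paste0(
      "initial K_half estimate (", signif(K0, 4),
      " uM) lies outside the x-range; the fit may be poorly constrained")
  }

  free_n <- is.null(fix_n)
  par0 <- if (free_n) log(c(V = V0, K = K0, n = 1)) else log(c(V = V0, K = K0))
  resid_fun <- function(lp) {
    V <- exp(lp[[1L]]); K <- exp(lp[[2L]])
    n <- if (free_n) exp(lp[[3L]]) else fix_n
    s <- (x / K)^n
    w * (y - V * s / (1 + s))
  }
  fit <- try(minpack.lm::nls.lm(par = par0, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-14,
                                  ptol = 1e-14)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(V = V0, K_half = K0, n = if (free_n) 1 else fix_n,
                          r2 = NA_real_, converged = FALSE,
                          std_errors = NULL,
                          meta = c(meta, list(error = as.character(fit)))),
                     class = "hill_fit"))
  }
  lp <- fit$par
  V <- exp(lp[[1L]]); K <- exp(lp[[2L]])
  n <- if (free_n) exp(lp[[3L]]) else fix_n
  pred <- { s <- (x / K)^n; V * s / (1 + s) }
  converged <- fit$info %in% 1:4
  se <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance /
      max(length(x) - length(lp), 1L)
    se_log <- sqrt(pmax(diag(covm), 0))
    ests <- c(V = V, K_half = K, if (free_n) c(n = n))
    stats::setNames(ests * se_log, names(ests)) # delta method from log scale
  }, error = function(e) NULL)
  structure(list(V = V, K_half = K, n = n,
                 r2 = r_squared(y, pred), converged = converged,
                 std_errors = se, fitted = pred, meta = meta),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit", if (!x$converged) " (NOT converged)", ":\n", sep = "")
  cat(sprintf("  V      = %g uM/s\n  K_half = %g uM\n  n      = %g\n",
              x$V, x$K_half, x$n))
  cat(sprintf("  r2     = %.6f\n", x$r2))
  if (!is.null(x$meta$range_warning))
    cat("  note: ", x$meta$range_warning, "\n", sep = "")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(V = object$V, K_half = object$K_half, n = object$n)
}

#' @export
predict.hill_fit <- function(object, x, ...) {
  s <- (x / object$K_half)^object$n
  object$V * s / (1 + s)
}
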