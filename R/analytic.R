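# Closed-form steady-state rate laws for the glutaredoxin cores. These are
# exact algebraic consequences of the two-reaction mass-action schemes and
# double as the oracle for the numerical steady-state solver.

.check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(args[[nm]] < 0))
      stop("'", nm, "' must be non-negative", call. = FALSE)
}

.check_pos <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(args[[nm]] <= 0))
      stop("'", nm, "' must be strictly positive", call. = FALSE)
}

#' Steady-state rate of the wild-type dithiol glutaredoxin cycle
#'
#' The harmonic-sum form
#' \deqn{v_{wt} = \frac{Grx_{tot}}{\frac{1}{k_2\,GSH^2} + \frac{1}{k_1\,PSSG}}}
#' Returns the continuous limit 0 when `pssg` or `gsh` is zero, so
#' saturation-curve grids may include the origin.
#'
#' @param k1 deglutathionylation rate constant, uM^-1 s^-1.
#' @param k2 wild-type GSH-oxidation rate constant, uM^-2 s^-1.
#' @param grx_tot total glutaredoxin, uM.
#' @param pssg,gsh substrate and glutathione concentrations, uM
#'   (vectorised).
#' @return Rate in uM s^-1.
#' @export
#' @examples
#' v_wt(k1 = 0.073, k2 = 4.23e-6, grx_tot = 0.24, pssg = 70, gsh = 998)
v_wt <- function(k1, k2, grx_tot, pssg, gsh) {
  .check_pos(k1 = k1, k2 = k2, grx_tot = grx_tot)
  .check_nonneg(pssg = pssg, gsh = gsh)
  num <- grx_tot * k1 * k2 * pssg * gsh^2
  den <- k1 * pssg + k2 * gsh^2
  ifelse(den == 0, 0, num / den)
}

#' Steady-state oxidized fraction of wild-type glutaredoxin
#'
#' \deqn{\frac{GrxSS}{Grx_{tot}} = \frac{k_1\,PSSG}{k_1\,PSSG + k_2\,GSH^2}}
#' Monotone increasing in `pssg` and decreasing in `gsh`; equals 1 when
#' glutathione is absent.
#'
#' @inheritParams v_wt
#' @return Dimensionless fraction in \[0, 1\].
#' @export
grxss_fraction <- function(k1, k2, pssg, gsh) {
  .check_pos(k1 = k1, k2 = k2)
  .check_nonneg(pssg = pssg, gsh = gsh)
  den <- k1 * pssg + k2 * gsh^2
  if (any(den == 0))
    stop("denominator k1*PSSG + k2*GSH^2 is zero", call. = FALSE)
  k1 * pssg / den
}

#' Steady-state rate of the active-site mutant glutaredoxin cycle
#'
#' As [v_wt()] but first order in glutathione:
#' \deqn{v_{mu} = \frac{Grx_{tot}}{\frac{1}{k_2'\,GSH} + \frac{1}{k_1\,PSSG}}}
#'
#' @inheritParams v_wt
#' @param k2p mutant GSH-oxidation rate constant, uM^-1 s^-1.
#' @return Rate in uM s^-1.
#' @export
v_mut <- function(k1, k2p, grx_tot, pssg, gsh) {
  .check_pos(k1 = k1, k2p = k2p, grx_tot = grx_tot)
  .check_nonneg(pssg = pssg, gsh = gsh)
  num <- grx_tot * k1 * k2p * pssg * gsh
  den <- k1 * pssg + k2p * gsh
  ifelse(den == 0, 0, num / den)
}

#' Ratio of wild-type to mutant steady-state rates
#'
#' Computed exactly from the two closed forms (the total glutaredoxin
#' cancels). At saturating substrate the ratio tends to
#' [rate_ratio_limit()], `k2 * GSH / k2p`: any activity difference between
#' wild-type and mutant at high substrate is carried entirely by the
#' GSH-oxidation constants and the glutathione concentration.
#'
#' @inheritParams v_wt
#' @inheritParams v_mut
#' @return Dimensionless rate ratio.
#' @export
rate_ratio <- function(k1, k2, k2p, pssg, gsh) {
  .check_pos(k1 = k1, k2 = k2, k2p = k2p, pssg = pssg, gsh = gsh)
  vm <- v_mut(k1, k2p, 1, pssg, gsh)
  if (any(vm == 0)) stop("mutant rate is zero", call. = FALSE)
  v_wt(k1, k2, 1, pssg, gsh) / vm
}

#' @rdname rate_ratio
#' @details `rate_ratio_limit()` returns the saturating-substrate limit
#'   `k2 * gsh / k2p`.
#' @export
rate_ratio_limit <- function(k2, k2p, gsh) {
  .check_pos(k2 = k2, gsh = gsh)
  if (any(k2p <= 0)) stop("'k2p' must be strictly positive", call. = FALSE)
  k2 * gsh / k2p
}

#' Double-reciprocal (Lineweaver-Burk) coefficients of the wild-type core
#'
#' In reciprocal form the wild-type rate law is
#' \deqn{\frac{1}{v_{wt}} = \frac{1}{Grx_{tot}k_1}\frac{1}{PSSG}
#'       + \frac{1}{Grx_{tot}k_2}\frac{1}{GSH^2}}
#' so a plot of 1/v against 1/PSSG is a straight line whose slope,
#' `1/(grx_tot*k1)`, is independent of glutathione — the signature
#' (apparent ping-pong) parallel-line pattern — while the intercept scales
#' as `GSH^-2`.
#'
#' @inheritParams v_wt
#' @return An object of class `reciprocal_coefficients`: list with `slope`
#'   (s, per uM^-1 of 1/PSSG) and `intercept` (s uM^-1).
#' @export
reciprocal_coefficients <- function(k1, k2, grx_tot, gsh) {
  .check_pos(k1 = k1, k2 = k2, grx_tot = grx_tot, gsh = gsh)
  structure(list(slope = 1 / (grx_tot * k1),
                 intercept = 1 / (grx_tot * k2 * gsh^2), gsh = gsh),
            class = "reciprocal_coefficients")
}

#' @export
print.reciprocal_coefficients <- function(x, ...) {
  cat("1/v = ", format(x$slope), " * (1/PSSG) + ", format(x$intercept),
      "   [GSH = ", x$gsh, " uM]\n", sep = "")
  invisible(x)
}

#' Hill form of the glutathione dependence
#'
#' At fixed substrate the wild-type rate law is algebraically a Hill
#' equation in glutathione, `v = V * s^n / (1 + s^n)` with
#' `s = GSH / GSH_0.5`, exponent `n = 2`, maximal rate
#' `V = grx_tot * k1 * pssg` and half-saturation
#' `GSH_0.5 = sqrt(k1 * pssg / k2)`. The mutant form is hyperbolic
#' (`n = 1`) with `GSH_0.5 = k1 * pssg / k2p`. These are identities, not
#' fits; `predict()` evaluates the curve.
#'
#' @inheritParams v_wt
#' @inheritParams v_mut
#' @return An object of class `hill_form`: list with `V` (uM s^-1),
#'   `K_half` (uM) and `n`.
#' @export
#' @examples
#' hf <- hill_form_wt(k1 = 1, k2 = 1, grx_tot = 1, pssg = 4)
#' hf$K_half  # 2
#' predict(hf, gsh = 2)  # V/2
hill_form_wt <- function(k1, k2, grx_tot, pssg) {
  .check_pos(k1 = k1, k2 = k2, grx_tot = grx_tot, pssg = pssg)
  structure(list(V = grx_tot * k1 * pssg, K_half = sqrt(k1 * pssg / k2),
                 n = 2), class = "hill_form")
}

#' @rdname hill_form_wt
#' @export
hill_form_mut <- function(k1, k2p, grx_tot, pssg) {
  .check_pos(k1 = k1, k2p = k2p, grx_tot = grx_tot, pssg = pssg)
  structure(list(V = grx_tot * k1 * pssg, K_half = k1 * pssg / k2p,
                 n = 1), class = "hill_form")
}

#' @export
predict.hill_form <- function(object, gsh, ...) {
  .check_nonneg(gsh = gsh)
  s <- (gsh / object$K_half)^object$n
  object$V * s / (1 + s)
}

#' @export
print.hill_form <- function(x, ...) {
  cat("Hill form: V = ", format(x$V), " uM/s, GSH_0.5 = ", format(x$K_half),
      " uM, n = ", x$n, "\n", sep = "")
  invisible(x)
}
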