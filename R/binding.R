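#' Construct a saturation binding curve
#'
#' A titration record: the concentration series of the titrant (for the
#' FRET assay, the PDZ domain titrated from 2 to 38 uM against 1 uM
#' dansyl-labelled peptide) and the normalized fluorescence signal, plus
#' the constant competitor concentration, 0 when absent.
#'
#' @param concentrations Titrant concentrations, uM, non-negative; at least
#'   4 distinct values are required for fitting.
#' @param signal Normalized signal, same length, finite.
#' @param inhibitor_conc Constant inhibitor concentration, uM (default 0).
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(concentrations, signal, inhibitor_conc = 0) {
  concentrations <- as.numeric(concentrations)
  signal <- as.numeric(signal)
  if (length(concentrations) != length(signal)) {
    stop("concentrations and signal must have equal length", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("signal must be finite", call. = FALSE)
  structure(list(concentrations = concentrations, signal = signal,
                 inhibitor_conc = as.numeric(inhibitor_conc)),
            class = "binding_curve")
}

#' Fit a hyperbolic saturation binding model
#'
#' Least-squares fit of `F(c) = F0 + Fmax * c / (Kd + c)` to a titration,
#' the standard one-site binding hyperbola used for normalized fluorescence
#' saturation data. Parameter standard errors come from the local curvature
#' of the least-squares objective (the covariance of the converged fit).
#'
#' @param curve A [binding_curve()], or a data.frame with columns
#'   `concentration` and `signal` (uM, signal units).
#' @return An object of class `hyperbolic_fit`: list with `Kd` (uM),
#'   `Fmax`, `F0`, `se` (named vector of standard errors), `fitted`,
#'   `residuals` and the underlying `nls` fit.
#' @seealso [apparent_kd()], [generate_binding_curve()]
#' @export
fit_hyperbolic <- function(curve) {
  if (is.data.frame(curve)) {
    curve <- binding_curve(curve$concentration, curve$signal,
                           if ("inhibitor_uM" %in% names(curve))
                             curve$inhibitor_uM[1] else 0)
  }
  stopifnot(inherits(curve, "binding_curve"))
  c_ <- curve$concentrations
  y <- curve$signal
  if (length(unique(c_)) < 4L) {
    stop("need at least 4 distinct concentrations to fit", call. = FALSE)
  }
  if (diff(range(y)) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    stop("signal is constant: no saturation information to fit",
         call. = FALSE)
  }
  dat <- data.frame(c_ = c_, y = y)
  f0_start <- min(y)
  fmax_start <- max(y) - f0_start
  half <- f0_start + fmax_start / 2
  kd_start <- c_[which.min(abs(y - half))]
  if (kd_start <= 0) kd_start <- stats::median(c_[c_ > 0])
  fit <- minpack.lm::nlsLM(
    y ~ F0 + Fmax * c_ / (Kd + c_), data = dat,
    start = list(F0 = f0_start, Fmax = fmax_start, Kd = kd_start),
    lower = c(F0 = -Inf, Fmax = -Inf, Kd = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv) stop("hyperbolic fit did not converge",
                                 call. = FALSE)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(Kd = unname(est["Kd"]), Fmax = unname(est["Fmax"]),
                 F0 = unname(est["F0"]), se = se,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), fit = fit),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic binding fit: Kd = %.4g +/- %.2g uM, Fmax = %.4g, F0 = %.4g\n",
              x$Kd, x$se["Kd"], x$Fmax, x$F0))
  invisible(x)
}

#' Apparent Kd under competitive binding
#'
#' For a competitive inhibitor at concentration `I` with inhibition
#' constant `Ki`, the measured (apparent) dissociation constant of the
#' reporter complex is `Kd * (1 + I / Ki)`: strictly increasing in the
#' inhibitor concentration and decreasing in Ki.
#'
#' @param Kd True dissociation constant, uM, > 0.
#' @param Ki Inhibition constant of the competitor, uM, > 0.
#' @param inhibitor_conc Competitor concentration, uM, >= 0.
#' @return Apparent Kd, uM.
#' @seealso [ki_from_shift()]
#' @export
apparent_kd <- function(Kd, Ki, inhibitor_conc) {
  if (any(Kd <= 0) || any(Ki <= 0)) {
    stop("Kd and Ki must be positive", call. = FALSE)
  }
  if (any(inhibitor_conc < 0)) {
    stop("inhibitor_conc must be non-negative", call. = FALSE)
  }
  Kd * (1 + inhibitor_conc / Ki)
}

#' Inhibition constant from a competitive Kd shift
#'
#' Inverse of [apparent_kd()]: given the dissociation constant measured
#' without inhibitor and the apparent value measured at inhibitor
#' concentration `I`, the competitive model gives
#' `Ki = I / (Kd_apparent / Kd - 1)`. When the apparent value does not
#' exceed the uninhibited one there is no measurable competitive
#' inhibition; this is reported as a distinct condition (`NA` with a
#' warning), not an error.
#'
#' @param Kd Uninhibited dissociation constant, uM, > 0.
#' @param Kd_apparent Apparent dissociation constant at inhibitor, uM.
#' @param inhibitor_conc Inhibitor concentration, uM, > 0.
#' @return Ki in uM, or `NA` (with a warning) when `Kd_apparent <= Kd`.
#' @export
ki_from_shift <- function(Kd, Kd_apparent, inhibitor_conc) {
  if (any(Kd <= 0)) stop("Kd must be positive", call. = FALSE)
  if (any(inhibitor_conc <= 0)) {
    stop("inhibitor_conc must be positive", call. = FALSE)
  }
  if (Kd_apparent <= Kd) {
    warning("Kd_apparent <= Kd: no measurable competitive inhibition",
            call. = FALSE)
    return(NA_real_)
  }
  inhibitor_conc / (Kd_apparent / Kd - 1)
}

#' Construct a dose-response series
#'
#' @param doses Doses, uM, non-negative; at least 5 distinct values are
#'   required for 4PL fitting.
#' @param response Response values (fraction or percent of activity,
#'   viability or recruitment).
#' @param replicate Optional replicate index (default 1).
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(doses, response, replicate = 1L) {
  doses <- as.numeric(doses)
  response <- as.numeric(response)
  if (length(doses) != length(response)) {
    stop("doses and response must have equal length", call. = FALSE)
  }
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(response))) stop("response must be finite",
                                      call. = FALSE)
  structure(list(doses = doses, response = response,
                 replicate = as.integer(replicate)),
            class = "dose_response")
}

#' Fit a four-parameter logistic (4PL) dose-response model
#'
#' Least-squares fit of
#' `response(d) = bottom + (top - bottom) / (1 + (d / EC50)^hill)`,
#' the standard 4PL used for EC50 estimation by nonlinear regression.
#' With `hill > 0` the curve runs from `top` at zero dose to `bottom` at
#' saturating dose, so inhibition data fit with `top > bottom` and
#' activation data with `top < bottom`. Initialization takes the plateaus
#' from the responses at the dose extremes, EC50 from the doses bracketing
#' the half-range crossing, and hill = 1; EC50 is bounded positive and
#' hill to [0.1, 10]. Standard errors come from the curvature of the
#' least-squares objective at the optimum.
#'
#' @param dr A [dose_response()], or a data.frame with columns `dose_uM`
#'   and `response`.
#' @return An object of class `logistic_fit`: list with `EC50` (uM),
#'   `hill`, `top`, `bottom`, `se`, `fitted`, `residuals`, `fit`.
#' @seealso [generate_dose_response()]
#' @export
fit_logistic <- function(dr) {
  if (is.data.frame(dr)) dr <- dose_response(dr$dose_uM, dr$response)
  stopifnot(inherits(dr, "dose_response"))
  d <- dr$doses
  y <- dr$response
  if (length(unique(d)) < 5L) {
    stop("need at least 5 distinct doses for a 4PL fit", call. = FALSE)
  }
  if (diff(range(y)) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    stop("response is flat: no dose dependence to fit", call. = FALSE)
  }
  ord <- order(d)
  top_start <- y[ord][1]              # response at the lowest dose
  bottom_start <- y[ord][length(y)]   # response at the highest dose
  half <- (top_start + bottom_start) / 2
  pos <- d > 0
  ec_start <- {
    dd <- d[ord][pos[ord]]; yy <- y[ord][pos[ord]]
    cross <- which(diff(sign(yy - half)) != 0)
    if (length(cross)) sqrt(dd[cross[1]] * dd[cross[1] + 1])
    else exp(mean(log(range(dd))))
  }
  dat <- data.frame(d = d, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + (d / EC50)^hill), data = dat,
    start = list(bottom = bottom_start, top = top_start,
                 EC50 = ec_start, hill = 1),
    lower = c(bottom = -Inf, top = -Inf, EC50 = 1e-12, hill = 0.1),
    upper = c(bottom = Inf, top = Inf, EC50 = Inf, hill = 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$convInfo$isConv) stop("4PL fit did not converge", call. = FALSE)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(EC50 = unname(est["EC50"]), hill = unname(est["hill"]),
                 top = unname(est["top"]), bottom = unname(est["bottom"]),
                 se = se, fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("4PL fit: EC50 = %.4g +/- %.2g uM, hill = %.3g, top = %.4g, bottom = %.4g\n",
              x$EC50, x$se["EC50"], x$hill, x$top, x$bottom))
  invisible(x)
}

#' Cell-growth inhibition rate from optical densities
#'
#' `100 * (control_od - sample_od) / control_od`, the fraction of growth
#' suppressed relative to the untreated control, in percent. Values are not
#' clamped: growth stimulation yields negative percentages. (Assay
#' write-ups sometimes print this formula with the division applied to the
#' sample term only, which is dimensionally inconsistent and cannot yield
#' the percentages actually reported; the standard relative difference is
#' used here.)
#'
#' @param control_od Absorbance of the untreated control, > 0.
#' @param sample_od Absorbance of the treated sample, >= 0.
#' @return Inhibition rate in percent.
#' @export
inhibition_rate <- function(control_od, sample_od) {
  if (any(control_od <= 0)) stop("control_od must be positive",
                                 call. = FALSE)
  if (any(sample_od < 0)) stop("sample_od must be non-negative",
                               call. = FALSE)
  100 * (control_od - sample_od) / control_od
}
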