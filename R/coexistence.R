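#' Volume fractions of a state
#'
#' Monomer (or ion) volume fraction \eqn{\phi = \sum (\pi/6) d_i^3 / V} over
#' the selected particles; the water fraction is defined by complement,
#' \eqn{\phi_{water} = 1 - \phi_{mon} - \phi_{ion}}.
#'
#' @param state a [system_state()].
#' @param which `"monomers"`, `"ions"` or `"water"`.
#' @return fraction in \[0, 1\].
#' @export
volume_fraction <- function(state, which = c("monomers", "ions", "water")) {
  which <- match.arg(which)
  if (which == "water")
    return(1 - volume_fraction(state, "monomers") -
             volume_fraction(state, "ions"))
  is_mon <- state$species_table$monomer[state$species_idx]
  sel <- if (which == "monomers") is_mon else !is_mon
  d <- state$species_table$diameter[state$species_idx[sel]]
  sum(pi / 6 * d^3) / state$L^3
}

#' Collect a pressure-composition point
#'
#' @param phi_mon monomer volume fraction.
#' @param dP mean pressure difference PEC - supernatant, reduced units.
#' @param stderr standard error of `dP`.
#' @param demixed flag from the structure-factor criterion
#'   ([demixing_flag()]).
#' @return one-row data frame.
#' @export
pressure_point <- function(phi_mon, dP, stderr = 0, demixed = FALSE) {
  stopifnot(all(phi_mon > 0), all(phi_mon < 1), all(stderr >= 0))
  data.frame(phi_mon = phi_mon, dP = dP, stderr = stderr, demixed = demixed)
}

.dp_model <- function(phi, a0, a1, a2) a0 + a1 / tan(phi - a2)

#' Fit the pressure-composition curve and locate coexistence
#'
#' Fits the phenomenological form \eqn{\Delta P(\phi) = a_0 + a_1 /
#' \tan(\phi - a_2)} to the branch with \eqn{\Delta P \gtrsim 0} (points
#' with \eqn{\Delta P > -2\,\mathrm{stderr}} are included, excluding the
#' demixing-prone negative branch) by weighted nonlinear least squares, then
#' finds the coexistence volume fraction \eqn{\phi^0} where the fitted curve
#' crosses zero by bracketed root finding inside the fitted \eqn{\phi}
#' range. The uncertainty on \eqn{\phi^0} is propagated by parametric
#' resampling of the fit covariance. The result is only marked `valid` when
#' a root exists and the nearest pressure point is not flagged as demixed
#' (the self-consistency rule: the coexisting PEC must be a homogeneous
#' single phase).
#'
#' @param points data frame with columns `phi_mon`, `dP`, `stderr`,
#'   `demixed` (see [pressure_point()]).
#' @param weights `"inverse_variance"` (default) or `"uniform"`.
#' @param n_resample draws for the `phi0` uncertainty.
#' @return object of class `coexistence_result`: `phi0`, `phi0_stderr`,
#'   `coef`, `vcov`, `valid`, `reason`, `fit_points`.
#' @export
fit_dp_curve <- function(points, weights = c("inverse_variance", "uniform"),
                         n_resample = 500L) {
  weights <- match.arg(weights)
  stopifnot(all(c("phi_mon", "dP") %in% names(points)))
  if (is.null(points$stderr)) points$stderr <- 0
  if (is.null(points$demixed)) points$demixed <- FALSE
  use <- points$dP > -2 * points$stderr
  fitpts <- points[use, , drop = FALSE]
  fitpts <- fitpts[order(fitpts$phi_mon), ]
  if (nrow(fitpts) < 4)
    stop("need at least 4 points with dP > -2*stderr to fit")
  w <- if (weights == "inverse_variance" && any(fitpts$stderr > 0))
    1 / pmax(fitpts$stderr, 1e-3 * max(fitpts$stderr))^2
  else rep(1, nrow(fitpts))

  # starting values: a2 slightly below the smallest phi so tan(phi - a2) > 0
  # and decreasing toward small phi; a0/a1 from a linear solve
  rng <- range(fitpts$phi_mon)
  a2_0 <- rng[1] - 0.25 * (rng[2] - rng[1] + 1e-3)
  basis <- 1 / tan(fitpts$phi_mon - a2_0)
  ab <- stats::lm.wfit(cbind(1, basis), fitpts$dP, w)$coefficients
  fit <- minpack.lm::nlsLM(
    dP ~ a0 + a1 / tan(phi_mon - a2), data = fitpts, weights = w,
    start = list(a0 = ab[1], a1 = ab[2], a2 = a2_0),
    lower = c(-Inf, -Inf, rng[1] - pi / 2 + 1e-6),
    upper = c(Inf, Inf, rng[1] - 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(0, 3, 3))

  f <- function(phi) .dp_model(phi, cf[1], cf[2], cf[3])
  # root bracketing over the full supplied phi range (never extrapolating
  # beyond the data); the negative branch is excluded from the fit only
  lo <- min(points$phi_mon); hi <- max(points$phi_mon)
  hi <- min(hi, cf[3] + pi - 1e-9) # stay on the fitted branch of 1/tan
  root <- NULL
  if (f(lo) * f(hi) < 0)
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (is.null(root)) {
    return(structure(list(phi0 = NA_real_, phi0_stderr = NA_real_,
                          coef = cf, vcov = vc, valid = FALSE,
                          reason = "no coexistence detected: fitted curve has no sign change over the data range",
                          fit_points = fitpts),
                     class = "coexistence_result"))
  }
  # parametric resampling of the covariance for the phi0 uncertainty
  se <- NA_real_
  if (any(vc != 0)) {
    ch <- tryCatch(chol(vc), error = function(e) NULL)
    if (!is.null(ch)) {
      draws <- matrix(stats::rnorm(3 * n_resample), n_resample, 3) %*% ch
      roots <- apply(draws, 1, function(d) {
        g <- function(phi) .dp_model(phi, cf[1] + d[1], cf[2] + d[2],
                                     cf[3] + d[3])
        if (is.finite(g(lo)) && is.finite(g(hi)) && g(lo) * g(hi) < 0)
          stats::uniroot(g, c(lo, hi), tol = 1e-10)$root else NA_real_
      })
      se <- stats::sd(roots, na.rm = TRUE)
    }
  }
  nearest <- fitpts[which.min(abs(fitpts$phi_mon - root)), ]
  valid <- !isTRUE(nearest$demixed)
  structure(list(phi0 = root, phi0_stderr = se, coef = cf, vcov = vc,
                 valid = valid,
                 reason = if (valid) "ok" else
                   "PEC at phi0 flagged as demixed (self-consistency rule)",
                 fit_points = fitpts),
            class = "coexistence_result")
}

#' @export
print.coexistence_result <- function(x, ...) {
  if (is.na(x$phi0)) {
    cat("<coexistence_result> no coexistence detected\n")
  } else {
    cat(sprintf("<coexistence_result> phi0 = %.4f +- %.4f (%s)\n",
                x$phi0, x$phi0_stderr, if (x$valid) "valid" else x$reason))
  }
  invisible(x)
}

#' Demixing criterion from the structure factor
#'
#' A box is flagged as demixing (in-box phase separation into polymer-rich
#' and polymer-poor domains) when the smallest-wavevector bin of the
#' spherically averaged structure factor is its global maximum.
#'
#' @param sk data frame or list with components `k` (ascending) and `S`.
#' @return logical flag.
#' @export
demixing_flag <- function(sk) {
  k <- sk$k; S <- sk$S
  if (length(k) < 3) stop("need at least 3 k-bins to classify")
  if (is.unsorted(k)) stop("k bins must be sorted ascending")
  S[1] > max(S[-1]) # strictly the global maximum (a flat curve is mixed)
}

#' Tie-line concentrations and partition coefficients
#'
#' \eqn{K_i = c_i^{pec} / c_i^{sup}} for every exchangeable species, with
#' errors propagated from the two phase summaries; \eqn{K > 1} means
#' accumulation in the PEC.
#'
#' @param pec_summary,sup_summary outputs of [run_phase()] for the PEC box
#'   at \eqn{\phi^0} and the supernatant box, run with matching constants.
#' @param min_conc species below this mean concentration (mol/L) in both
#'   phases are dropped.
#' @return data frame: species, c_sup, c_pec, K, K_stderr.
#' @export
tie_line <- function(pec_summary, sup_summary, min_conc = 1e-12) {
  cp <- pec_summary$concentrations
  cs <- sup_summary$concentrations
  if (!is.null(cp$exchangeable)) cp <- cp[cp$exchangeable, ]
  if (!is.null(cs$exchangeable)) cs <- cs[cs$exchangeable, ]
  m <- merge(cs[names(cs) != "exchangeable"], cp[names(cp) != "exchangeable"],
             by = "species", suffixes = c("_sup", "_pec"))
  m <- m[m$mean_sup > min_conc | m$mean_pec > min_conc, ]
  if (any(m$mean_sup <= 0))
    stop("zero supernatant concentration for species: ",
         paste(m$species[m$mean_sup <= 0], collapse = ", "))
  K <- m$mean_pec / m$mean_sup
  K_se <- K * sqrt((m$stderr_pec / m$mean_pec)^2 +
                   (m$stderr_sup / m$mean_sup)^2)
  data.frame(species = m$species, c_sup = m$mean_sup, c_pec = m$mean_pec,
             K = K, K_stderr = K_se, row.names = NULL)
}

#' Partition coefficient from gravimetric measurements
#'
#' The experiment-style estimator: a solute is distributed between a PEC of
#' mass `m_pec` and a supernatant of mass `m_sup`; the supernatant
#' concentration is measured relative to a polyelectrolyte-free control
#' (`c_sup_norm`, 1 = control). Assuming the hydrated PEC has approximately
#' the density of water, the mass balance gives
#' \eqn{K = [(m^{pec} + m^{sup}) - c\, m^{sup}] / (c\, m^{pec})}.
#'
#' @param m_pec,m_sup masses of the hydrated PEC and of the supernatant.
#' @param c_sup_norm supernatant concentration normalized to the control
#'   (fraction, not percent).
#' @return partition coefficient.
#' @export
partition_from_masses <- function(m_pec, m_sup, c_sup_norm) {
  stopifnot(m_pec > 0, m_sup >= 0, c_sup_norm > 0)
  ((m_pec + m_sup) - c_sup_norm * m_sup) / (c_sup_norm * m_pec)
}
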