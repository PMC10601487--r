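## Spectral-density representations, energy-gap TCF processing and the
## equal-reorganization discretization into normal modes.
##
## Convention (centralized here; changing it is a one-line edit of the two
## prefactor constants below).  For a classical energy-gap autocorrelation
## C(t) = <dU(0) dU(t)> at inverse temperature beta:
##
##   J(omega) = TCF_FORWARD_PREFAC * beta * omega * int_0^inf C(t) cos(omega t) dt
##   C(t)     = TCF_INVERSE_PREFAC / beta * int_0^inf (J(omega)/omega) cos(omega t) domega
##   E_r      = beta * C(0) / 2
##   E_r(J)   = (1/pi) int_0^inf J(omega)/omega domega
##
## These four relations are mutually consistent (C(0) = 2 E_r k_B T for a
## harmonic bath), and under them the Debye density
## J = 2 lambda omega omega_c / (omega^2 + omega_c^2) carries E_r = lambda.
TCF_FORWARD_PREFAC <- 1          # J = prefac * beta * omega * cosine transform
TCF_INVERSE_PREFAC <- 2 / pi     # C = prefac / beta * inverse cosine transform

#' Spectral density of a harmonic bath
#'
#' Frequency-resolved system--bath coupling strength J(omega).  Analytic
#' Ohmic and Debye forms are supported, as well as tabulated densities
#' interpolated with a monotone piecewise cubic.
#'
#' Forms (atomic units):
#' \itemize{
#'   \item Ohmic: \eqn{J(\omega) = \eta\,\omega\, e^{-\omega/\omega_c}},
#'     maximal at \eqn{\omega=\omega_c}, reorganization energy
#'     \eqn{E_r = \eta\omega_c/\pi}.
#'   \item Debye: \eqn{J(\omega) = 2\lambda\,\omega\,\omega_c/(\omega^2+\omega_c^2)},
#'     reorganization energy \eqn{E_r = \lambda}.
#' }
#'
#' @param kind `"ohmic"`, `"debye"` or `"tabulated"`.
#' @param eta Ohmic friction coefficient (dimensionless, > 0).
#' @param omega_c cutoff frequency in a.u. (> 0).
#' @param lambda Debye reorganization energy in a.u. (> 0).
#' @param table two-column matrix/data.frame `(omega, J)` in a.u. for
#'   `kind = "tabulated"`; the omega grid must be strictly increasing and
#'   J must be nonnegative.
#' @return an object of class `"spectral_density"`, callable via
#'   [density_value()].
#' @seealso [density_value()], [reorg_of_density()], [discretize_bath()]
#' @export
spectral_density <- function(kind = c("ohmic", "debye", "tabulated"),
                             eta = NULL, omega_c = NULL, lambda = NULL,
                             table = NULL) {
  kind <- match.arg(kind)
  sd <- list(kind = kind)
  if (kind == "ohmic") {
    if (is.null(eta) || is.null(omega_c) || eta <= 0 || omega_c <= 0)
      stop("ohmic density requires eta > 0 and omega_c > 0", call. = FALSE)
    sd$eta <- eta; sd$omega_c <- omega_c
  } else if (kind == "debye") {
    if (is.null(lambda) || is.null(omega_c) || lambda <= 0 || omega_c <= 0)
      stop("debye density requires lambda > 0 and omega_c > 0", call. = FALSE)
    sd$lambda <- lambda; sd$omega_c <- omega_c
  } else {
    table <- as.matrix(table)
    if (ncol(table) != 2 || nrow(table) < 2)
      stop("tabulated density needs a two-column (omega, J) table", call. = FALSE)
    if (any(diff(table[, 1]) <= 0))
      stop("tabulated omega grid must be strictly increasing", call. = FALSE)
    if (any(table[, 2] < 0))
      stop("tabulated J(omega) must be nonnegative", call. = FALSE)
    if (table[1, 1] > 0) table <- rbind(c(0, 0), table)
    table[1, 2] <- 0  # J(0) = 0 enforced
    sd$table <- table
    sd$interp <- stats::splinefun(table[, 1], table[, 2], method = "monoH.FC")
  }
  class(sd) <- "spectral_density"
  sd
}

#' Evaluate a spectral density
#'
#' @param sd a [spectral_density()] object.
#' @param omega frequencies in a.u. (vectorized).  Values outside a
#'   tabulated grid evaluate to zero with a warning.
#' @return J(omega) in a.u.
#' @export
density_value <- function(sd, omega) {
  stopifnot(inherits(sd, "spectral_density"))
  out <- switch(sd$kind,
    ohmic = sd$eta * omega * exp(-omega / sd$omega_c),
    debye = 2 * sd$lambda * omega * sd$omega_c / (omega^2 + sd$omega_c^2),
    tabulated = {
      hi <- max(sd$table[, 1])
      v <- sd$interp(pmin(pmax(omega, 0), hi))
      outside <- omega > hi | omega < 0
      if (any(outside)) {
        warning("omega outside the tabulated range; returning 0 there")
        v[outside] <- 0
      }
      pmax(v, 0)
    })
  out[omega == 0] <- 0
  out
}

#' Total reorganization energy carried by a spectral density
#'
#' Computes \eqn{E_r = (1/\pi)\int_0^\infty J(\omega)/\omega\, d\omega} by
#' adaptive quadrature (analytic kinds) or trapezoid on the table.
#'
#' @param sd a [spectral_density()] object.
#' @return reorganization energy in a.u.
#' @export
reorg_of_density <- function(sd) {
  stopifnot(inherits(sd, "spectral_density"))
  switch(sd$kind,
    ohmic = sd$eta * sd$omega_c / pi,
    debye = sd$lambda,
    tabulated = {
      w <- sd$table[, 1]; j <- sd$table[, 2]
      f <- ifelse(w > 0, j / w, 0)
      if (w[1] == 0 && length(w) > 1) f[1] <- f[2]  # J ~ omega near 0
      sum(diff(w) * (f[-1] + f[-length(f)]) / 2) / pi
    })
}

## Cumulative weight F(omega) = int_0^omega J/omega' domega' used by the
## equal-reorganization discretization.  Returns a function and F(inf).
.density_cumulative <- function(sd) {
  switch(sd$kind,
    ohmic = list(F = function(w) sd$eta * sd$omega_c * (1 - exp(-w / sd$omega_c)),
                 Finf = sd$eta * sd$omega_c,
                 Finv = function(p) -sd$omega_c * log1p(-p)),
    debye = list(F = function(w) 2 * sd$lambda * atan(w / sd$omega_c),
                 Finf = sd$lambda * pi,
                 Finv = function(p) sd$omega_c * tan(p * pi / 2)),
    tabulated = {
      w <- sd$table[, 1]; j <- sd$table[, 2]
      f <- ifelse(w > 0, j / w, 0)
      if (w[1] == 0 && length(w) > 1) f[1] <- f[2]
      cum <- c(0, cumsum(diff(w) * (f[-1] + f[-length(f)]) / 2))
      Ffun <- stats::approxfun(w, cum, rule = 2)
      list(F = Ffun, Finf = cum[length(cum)], Finv = NULL, grid = w)
    })
}

#' Discretize a spectral density into equal-reorganization normal modes
#'
#' Each of the N modes carries the same share E_r/N of the total
#' reorganization energy.  Frequencies solve
#' \eqn{F(\omega_j) = f_j\, F(\infty)} with
#' \eqn{F(\omega)=\int_0^{\omega} J(\omega')/\omega'\,d\omega'} and the
#' midpoint fractions \eqn{f_j=(j-1/2)/N} (alternative `"j/(N+1)"`
#' available).  Equilibrium displacements are
#' \eqn{R_j^{eq} = \sqrt{2 E_r/N}/\omega_j} and couplings
#' \eqn{c_j = \omega_j^2 R_j^{eq}/2}.
#'
#' @param sd a [spectral_density()] object with integrable J(omega)/omega.
#' @param n_modes number of modes N (>= 2; N = 1 is allowed with a warning
#'   and places the single mode at the median of F).
#' @param er_total total reorganization energy E_r in a.u. (> 0).  Defaults
#'   to the density's own [reorg_of_density()].
#' @param fractions `"midpoint"` for (j-1/2)/N or `"j/(N+1)"`.
#' @return an object of class `"discretized_bath"` with fields `n_modes`,
#'   `omegas` (ascending, a.u.), `er`, `req`, `couplings`.
#' @export
discretize_bath <- function(sd, n_modes, er_total = reorg_of_density(sd),
                            fractions = c("midpoint", "j/(N+1)")) {
  stopifnot(inherits(sd, "spectral_density"))
  fractions <- match.arg(fractions)
  if (n_modes < 1) stop("n_modes must be >= 1", call. = FALSE)
  if (n_modes == 1) warning("N = 1 is a degenerate discretization")
  if (er_total <= 0) stop("er_total must be positive", call. = FALSE)
  N <- as.integer(n_modes)
  fj <- if (fractions == "midpoint") (seq_len(N) - 0.5) / N else seq_len(N) / (N + 1)
  cumF <- .density_cumulative(sd)
  if (!is.finite(cumF$Finf) || cumF$Finf <= 0)
    stop("divergent or empty cumulative weight: J(omega)/omega not integrable",
         call. = FALSE)
  omegas <- if (!is.null(cumF$Finv)) {
    cumF$Finv(fj)
  } else {
    targets <- fj * cumF$Finf
    hi <- max(cumF$grid)
    vapply(targets, function(tg) {
      tryCatch(
        stats::uniroot(function(w) cumF$F(w) - tg, lower = 0, upper = hi,
                       tol = .Machine$double.eps^0.6)$root,
        error = function(e) stop("root not bracketed while inverting F(omega): ",
                                 conditionMessage(e), call. = FALSE))
    }, numeric(1))
  }
  if (any(omegas <= 0) || any(diff(omegas) <= 0))
    stop("discretization produced non-ascending or nonpositive frequencies",
         call. = FALSE)
  req <- sqrt(2 * er_total / N) / omegas
  bath <- list(n_modes = N, omegas = omegas, er = er_total, req = req,
               couplings = omegas^2 * req / 2)
  class(bath) <- "discretized_bath"
  bath
}

#' @export
print.discretized_bath <- function(x, ...) {
  cat("Discretized harmonic bath:", x$n_modes, "modes\n")
  cat(sprintf("  omega range  : %.4g .. %.4g a.u. (%.2f .. %.2f cm^-1)\n",
              min(x$omegas), max(x$omegas),
              from_au(min(x$omegas), "cm-1"), from_au(max(x$omegas), "cm-1")))
  cat(sprintf("  E_r (total)  : %.6g a.u. (%.4f kcal/mol)\n",
              x$er, from_au(x$er, "kcal/mol")))
  invisible(x)
}

#' Energy-gap time correlation function
#'
#' Container for a uniformly sampled classical autocorrelation
#' C(t) = <dU(0) dU(t)> of the energy gap between two electronic states.
#'
#' @param times uniform time grid starting at 0 (a.u.).
#' @param values C(t) values (energy^2, a.u.).
#' @param beta inverse temperature 1/(k_B T) in a.u. (> 0).
#' @return object of class `"gap_tcf"`.
#' @export
gap_tcf <- function(times, values, beta) {
  if (length(times) < 2 || length(times) != length(values))
    stop("need matching time/value series of length >= 2", call. = FALSE)
  dt <- diff(times)
  if (times[1] != 0 || any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time grid must start at 0 and be uniform", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (values[1] < 0) stop("C(0) must be nonnegative", call. = FALSE)
  structure(list(times = times, values = values, beta = beta),
            class = "gap_tcf")
}

#' Reorganization energy from an energy-gap TCF
#'
#' \eqn{E_r = \beta C(0)/2} -- the classical fluctuation relation between
#' the gap variance and the reorganization energy.
#'
#' @param tcf a [gap_tcf()] object.
#' @return E_r in a.u.
#' @export
reorg_from_tcf <- function(tcf) {
  stopifnot(inherits(tcf, "gap_tcf"))
  tcf$beta * tcf$values[1] / 2
}

#' Spectral density from an energy-gap TCF
#'
#' Cosine-transforms a classical gap TCF into a tabulated spectral density,
#' \eqn{J(\omega) = \beta\omega \int_0^\infty C(t)\cos(\omega t)\,dt}
#' (trapezoidal quadrature on the sampled grid; see the convention note in
#' the package vignette).  An optional exponential damping window
#' \eqn{e^{-t/\tau}} can be applied for noisy, truncated series.
#'
#' @param tcf a [gap_tcf()] object; the series should have decayed to ~0 by
#'   its last point (a warning is issued otherwise).
#' @param omega_grid output frequencies in a.u.; default 2048 points spanning
#'   0 to 5000 cm^-1.
#' @param damping_tau optional time constant tau (a.u.) of the damping
#'   window; `NULL` (default) applies no window.
#' @return a tabulated [spectral_density()].
#' @export
tcf_to_spectral_density <- function(tcf, omega_grid = NULL, damping_tau = NULL) {
  stopifnot(inherits(tcf, "gap_tcf"))
  if (is.null(omega_grid))
    omega_grid <- seq(0, to_au(5000, "cm-1"), length.out = 2048)
  ct <- tcf$values
  if (abs(ct[length(ct)]) > 1e-2 * max(abs(ct)))
    warning("TCF has not decayed to ~0 by its last point; ",
            "consider a damping window (damping_tau)")
  if (!is.null(damping_tau)) ct <- ct * exp(-tcf$times / damping_tau)
  dt <- tcf$times[2] - tcf$times[1]
  ## trapezoid weights on the uniform grid
  wts <- rep(dt, length(ct)); wts[c(1, length(ct))] <- dt / 2
  jw <- vapply(omega_grid, function(w)
    TCF_FORWARD_PREFAC * tcf$beta * w * sum(wts * ct * cos(w * tcf$times)),
    numeric(1))
  jw[omega_grid == 0] <- 0
  jw <- pmax(jw, 0)
  spectral_density("tabulated", table = cbind(omega_grid, jw))
}

#' Leggett effective spectral density of the two-state reaction-coordinate
#' (GOA) model
#'
#' Closed-form asymptotic density of the normal modes of a harmonic primary
#' mode (frequency Omega, carrying reorganization energy E_r) bilinearly
#' coupled to an Ohmic secondary bath with friction eta, valid for
#' Omega << omega_c:
#' \deqn{J_{eff}(\omega) = \frac{2 E_r \Omega^2 \eta \omega}
#'   {(\Omega^2-\omega^2)^2 + \eta^2\omega^2}.}
#' Normalized so that \eqn{(1/\pi)\int J_{eff}/\omega\,d\omega = E_r}.
#' Used only as a validation oracle, never in model construction; it can be
#' inaccurate when Omega is comparable to omega_c.
#'
#' @param Omega primary-mode frequency (a.u., > 0).
#' @param eta secondary-bath friction (a.u., > 0).
#' @param omega_c secondary-bath cutoff (a.u., > 0); enters only the
#'   validity condition, not the asymptotic form.
#' @param er reorganization energy carried by the primary mode (a.u.).
#' @return a function of omega returning J_eff(omega).
#' @export
goa_effective_density <- function(Omega, eta, omega_c, er = 1) {
  stopifnot(Omega > 0, eta > 0, omega_c > 0, er > 0)
  function(omega)
    2 * er * Omega^2 * eta * omega / ((Omega^2 - omega^2)^2 + eta^2 * omega^2)
}
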