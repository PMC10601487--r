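#' @title Unit conversion constants and helpers
#' @description All internal computation is in Hartree atomic units
#'   (hbar = 1, mass-weighted coordinates).  User-facing readers and the
#'   packaged fixtures accept cm^-1 for frequencies, kcal/mol and eV for
#'   energies, K for temperature and fs for time.
#' @name units
NULL

## 1 hartree in other energy units
HARTREE_CM  <- 219474.6313632
HARTREE_KCAL <- 627.509474
HARTREE_EV  <- 27.211386245988
## 1 a.u. of time in fs
AU_FS <- 0.02418884254
## Boltzmann constant in hartree / K
KB_AU <- 1 / (HARTREE_CM / 0.6950348004)  # = 3.16681e-6; k_B = 0.69503480 cm^-1/K

#' Convert an energy-like quantity to atomic units
#'
#' @param x numeric value(s).
#' @param unit one of `"au"` (hartree), `"cm-1"`, `"kcal/mol"`, `"ev"`,
#'   `"fs"` (time), `"k"` (temperature, returned as thermal energy k_B T is
#'   *not* applied -- `"k"` is rejected here; use [beta_au()]).
#' @return value(s) in atomic units.
#' @examples
#' to_au(627.509474, "kcal/mol")  # ~1 hartree
#' @export
to_au <- function(x, unit = "au") {
  unit <- tolower(unit)
  switch(unit,
    "au"       = x,
    "hartree"  = x,
    "cm-1"     = ,
    "cm"       = x / HARTREE_CM,
    "kcal/mol" = ,
    "kcal"     = x / HARTREE_KCAL,
    "ev"       = x / HARTREE_EV,
    "fs"       = x / AU_FS,
    stop("unrecognized unit string: '", unit, "'", call. = FALSE))
}

#' Convert a quantity in atomic units to a named unit
#' @inheritParams to_au
#' @return value(s) in `unit`.
#' @export
from_au <- function(x, unit = "au") {
  x / to_au(1, unit)
}

#' Inverse temperature in atomic units
#'
#' @param temperature temperature in kelvin.
#' @return beta = 1/(k_B T) in hartree^-1.
#' @export
beta_au <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (KB_AU * temperature)
}
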