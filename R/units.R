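# Centralized unit registry.  All conversions between eV, cm^-1, Angstrom and
# atomic units go through these CODATA-2018 constants; internal computations
# are in Hartree atomic units, external interfaces use the field's units
# (Angstrom for geometry, eV for electronic energies, cm^-1 for vibrations).

#' Physical constants and unit conversions
#'
#' CODATA-2018 constants used throughout the package.  `plasmovib_constants()`
#' returns them as a named list; the `*_to_*` helpers convert scalars or
#' vectors between the externally used units and Hartree atomic units.
#'
#' @return `plasmovib_constants()` returns a named list with elements
#'   `hartree_ev` (eV per Hartree), `hartree_cm1` (cm^-1 per Hartree),
#'   `bohr_angstrom` (Angstrom per Bohr), `c_au` (speed of light, au),
#'   `amu_me` (electron masses per unified amu) and `kmmol_per_e2amu`
#'   (km/mol of IR intensity per (e^2/amu) of squared dipole derivative).
#' @examples
#' ev_to_au(27.211386)      # ~1 Hartree
#' cm1_to_au(219474.63)     # ~1 Hartree
#' @export
plasmovib_constants <- function() {
  list(
    hartree_ev      = 27.211386245988,
    hartree_cm1     = 219474.6313632,
    bohr_angstrom   = 0.529177210903,
    c_au            = 137.035999084,
    amu_me          = 1822.888486209,
    # I[km/mol] = kmmol_per_e2amu * |d mu / d Q|^2, with the dipole gradient
    # in e * amu^(-1/2) (equivalently 42.2561 km/mol per (D/A/sqrt(amu))^2)
    kmmol_per_e2amu = 974.8801
  )
}

.pv <- plasmovib_constants()

#' @rdname plasmovib_constants
#' @param x numeric vector to convert.
#' @export
ev_to_au <- function(x) x / .pv$hartree_ev

#' @rdname plasmovib_constants
#' @export
au_to_ev <- function(x) x * .pv$hartree_ev

#' @rdname plasmovib_constants
#' @export
cm1_to_au <- function(x) x / .pv$hartree_cm1

#' @rdname plasmovib_constants
#' @export
au_to_cm1 <- function(x) x * .pv$hartree_cm1

#' @rdname plasmovib_constants
#' @export
ang_to_au <- function(x) x / .pv$bohr_angstrom

#' @rdname plasmovib_constants
#' @export
au_to_ang <- function(x) x * .pv$bohr_angstrom

#' @rdname plasmovib_constants
#' @export
ev_to_cm1 <- function(x) x * .pv$hartree_cm1 / .pv$hartree_ev

#' @rdname plasmovib_constants
#' @export
cm1_to_ev <- function(x) x * .pv$hartree_ev / .pv$hartree_cm1
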