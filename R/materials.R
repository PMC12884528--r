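# Material laws: Drude parameters, tunneling damping constants, the graphene
# Fermi-energy density law, and the interband polarizability model.
# All stored values are in Hartree atomic units unless a field name says
# otherwise; constructors take the field's customary units.

#' Material parameter set
#'
#' Holds every constant governing the substrate response: the Drude relaxation
#' time and effective electron density, the effective atomic area entering the
#' neighbor conduction matrix, the Fermi-like tunneling damping constants, the
#' equilibrium nearest-neighbor distance, the effective mass, the Gaussian
#' regularization width of the electrostatic kernels, and (for noble metals)
#' an interband polarizability model.
#'
#' @param tau Drude relaxation time (au).
#' @param n_density effective 3D electron density (au).
#' @param eff_area effective atomic area entering the conduction matrix (au^2).
#' @param tunnel_steepness dimensionless steepness `d` of the Fermi damping.
#' @param tunnel_scale dimensionless onset scale `s` of the Fermi damping.
#' @param r0 equilibrium nearest-neighbor distance (Angstrom).
#' @param m_star effective mass (au); 1 for metals.
#' @param reg_width Gaussian regularization width of the charge distributions
#'   (au); defaults to half the nearest-neighbor distance.
#' @param interband optional interband polarizability model, see
#'   [interband_lorentzian()] / [interband_table()].
#' @param id material key.
#' @return an object of class `material_params`.
#' @seealso [gold_material()], [graphene_material()]
#' @export
material_params <- function(tau, n_density, eff_area,
                            tunnel_steepness = 35, tunnel_scale = 1.2,
                            r0 = 2.885, m_star = 1,
                            reg_width = NULL, interband = NULL,
                            id = "custom") {
  vals <- c(tau = tau, n_density = n_density, eff_area = eff_area,
            tunnel_steepness = tunnel_steepness, tunnel_scale = tunnel_scale,
            r0 = r0, m_star = m_star)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0][1]
    stop(sprintf("material parameter `%s` must be positive and finite", bad))
  }
  if (is.null(reg_width)) reg_width <- 0.5 * ang_to_au(r0)
  if (reg_width <= 0) stop("`reg_width` must be positive")
  structure(
    list(tau = tau, n_density = n_density, eff_area = eff_area,
         tunnel_steepness = tunnel_steepness, tunnel_scale = tunnel_scale,
         r0 = r0, m_star = m_star, reg_width = reg_width,
         interband = interband, id = id),
    class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> '%s'\n", x$id))
  cat(sprintf("  tau = %.4g au, n = %.4g au, eff_area = %.4g au^2\n",
              x$tau, x$n_density, x$eff_area))
  cat(sprintf("  tunneling: d = %.3g, s = %.3g, r0 = %.4g Angstrom\n",
              x$tunnel_steepness, x$tunnel_scale, x$r0))
  cat(sprintf("  reg_width = %.4g au, m* = %.3g\n", x$reg_width, x$m_star))
  if (!is.null(x$interband)) {
    cat(sprintf("  interband model: %s\n", class(x$interband)[1]))
  }
  if (!is.null(x$fermi_energy)) {
    cat(sprintf("  graphene: E_F = %.3g eV, v_F = %.4g au\n",
                x$fermi_energy, x$fermi_velocity))
  }
  invisible(x)
}

#' Default gold parameter set
#'
#' Drude and interband constants for gold.  These are physically motivated
#' stand-ins, to be replaced by the cited literature parametrizations for
#' quantitative resonance targets: `n` is the free-electron density at
#' r_s = 3.01 Bohr, `tau` corresponds to the 0.071 eV bulk Drude damping,
#' and the effective area derives from bulk-conduction matching on the fcc
#' lattice (A = 3*Omega_atom / (Z*r0) with coordination Z = 12).  The default
#' interband model is a three-term Lorentzian fit with a static atomic
#' polarizability of ~19 au^3 reproducing the qualitative gold interband
#' onset; pass a tabulated model for quantitative work.
#'
#' @param interband interband model; `NULL` selects Drude-only response,
#'   `"default"` the shipped Lorentzian fit.
#' @return a [material_params()] object.
#' @export
gold_material <- function(interband = "default") {
  r0 <- 2.885
  r0_au <- ang_to_au(r0)
  omega_atom <- r0_au^3 / sqrt(2)       # fcc volume per atom
  area <- 3 * omega_atom / (12 * r0_au) # bulk-conduction matching, fcc Z = 12
  if (identical(interband, "default")) interband <- gold_interband_default()
  material_params(
    tau = 1 / ev_to_au(0.071),          # ~380 au
    n_density = 3 / (4 * pi * 3.01^3),  # r_s = 3.01 Bohr
    eff_area = area,
    r0 = r0, interband = interband, id = "gold")
}

#' Shipped Lorentzian interband model for gold
#'
#' Three oscillators reproducing the qualitative d-band screening of gold
#' (static atomic polarizability ~19 au^3, onset in the 2.5-4 eV window).
#'
#' @return an `interband_lorentzian` model.
#' @export
gold_interband_default <- function() {
  interband_lorentzian(
    strength = c(0.05, 0.07, 0.18),
    center = c(2.7, 3.05, 4.0),
    width = c(0.6, 0.9, 1.5))
}

#' Default graphene parameter set
#'
#' Graphene response constants for a given Fermi energy.  The effective 3D
#' Drude density follows the linear Fermi-energy law (see
#' [graphene_density()]); the effective atomic area derives from
#' two-dimensional conduction matching on the honeycomb lattice against the
#' Dirac-carrier sheet Drude weight E_F/pi, giving the Fermi-energy
#' independent value A = 2*S_atom*v_F / (3*c), with S_atom the area per atom
#' and c the carbon-carbon bond.  The Fermi velocity defaults to c/300 and
#' the Drude damping to 0.010 eV, stand-ins for the cited graphene
#' parametrization.  With these defaults the disk plasmon follows the
#' expected sqrt(E_F / diameter) law.
#'
#' @param fermi_energy Fermi energy in eV (> 0).
#' @param fermi_velocity Fermi velocity in au.
#' @param damping_ev Drude damping hbar/tau in eV.
#' @param cc_bond carbon-carbon bond length (Angstrom).
#' @return a [material_params()] object with extra fields `fermi_energy` (eV)
#'   and `fermi_velocity` (au).
#' @export
graphene_material <- function(fermi_energy, fermi_velocity = 137.035999084 / 300,
                              damping_ev = 0.010, cc_bond = 1.42) {
  if (fermi_energy <= 0) stop("`fermi_energy` must be positive")
  n <- graphene_density(fermi_energy, fermi_velocity)
  c_au <- ang_to_au(cc_bond)
  s_atom <- (3 * sqrt(3) / 4) * c_au^2
  area <- 2 * s_atom * fermi_velocity / (3 * c_au)
  p <- material_params(
    tau = 1 / ev_to_au(damping_ev),
    n_density = n, eff_area = area, r0 = cc_bond, id = "graphene")
  p$fermi_energy <- fermi_energy
  p$fermi_velocity <- fermi_velocity
  p
}

#' Effective 3D Drude density of graphene
#'
#' The Fermi-energy law `n = E_F / (pi * a0 * hbar * v_F)` in atomic units
#' (a0 = hbar = 1), strictly linear in the Fermi energy.  It follows from the
#' relation `E_F = hbar * v_F * sqrt(pi * n_2D)` between the Fermi energy and
#' the two-dimensional carrier density.
#'
#' @param fermi_energy Fermi energy in eV (>= 0).
#' @param fermi_velocity Fermi velocity in au (default c/300).
#' @return effective 3D electron density in au.
#' @examples
#' graphene_density(0.40)
#' @export
graphene_density <- function(fermi_energy, fermi_velocity = 137.035999084 / 300) {
  if (any(fermi_energy < 0)) stop("`fermi_energy` must be non-negative")
  if (fermi_velocity <= 0) stop("`fermi_velocity` must be positive")
  ev_to_au(fermi_energy) / (pi * fermi_velocity)
}

#' Interband polarizability models
#'
#' Two parameterizations of the frequency-dependent atomic interband
#' polarizability alpha_IB(omega) that screens the d-shell of noble metals:
#' a sum of Lorentzians `alpha(w) = sum_k f_k / (w_k^2 - w^2 - i g_k w)`
#' (passive for all positive frequencies) or a tabulated complex
#' polarizability with linear interpolation (queries outside the table range
#' raise an extrapolation error).
#'
#' @param strength oscillator strengths f_k (au).
#' @param center oscillator centers w_k (eV).
#' @param width oscillator widths g_k (eV).
#' @return an object of class `interband_lorentzian` or `interband_table`.
#' @export
interband_lorentzian <- function(strength, center, width) {
  stopifnot(length(strength) == length(center),
            length(width) == length(center))
  if (any(strength < 0) || any(center <= 0) || any(width <= 0)) {
    stop("oscillator strengths must be >= 0, centers and widths > 0")
  }
  structure(list(strength = strength, center_au = ev_to_au(center),
                 width_au = ev_to_au(width)),
            class = c("interband_lorentzian", "interband_model"))
}

#' @rdname interband_lorentzian
#' @param omega_ev strictly increasing table frequencies (eV).
#' @param alpha complex polarizability values at `omega_ev` (au^3), with
#'   non-negative imaginary part (passivity).
#' @export
interband_table <- function(omega_ev, alpha) {
  stopifnot(length(omega_ev) == length(alpha))
  if (is.unsorted(omega_ev, strictly = TRUE)) {
    stop("table frequencies must be strictly increasing")
  }
  alpha <- as.complex(alpha)
  if (any(Im(alpha) < 0)) stop("passivity violated: Im alpha_IB < 0 in table")
  structure(list(omega_ev = omega_ev, alpha = alpha),
            class = c("interband_table", "interband_model"))
}

#' Evaluate the interband polarizability
#'
#' @param model an interband model.
#' @param omega frequency in eV (may be complex for lifetime-broadened
#'   evaluation of Lorentzian models).
#' @return complex polarizability alpha_IB(omega) in au^3.
#' @export
interband_alpha <- function(model, omega) {
  UseMethod("interband_alpha")
}

#' @export
interband_alpha.interband_lorentzian <- function(model, omega) {
  w <- ev_to_au(omega)
  vapply(w, function(wi) {
    sum(model$strength / (model$center_au^2 - wi^2 -
                            1i * model$width_au * wi))
  }, complex(1))
}

#' @export
interband_alpha.interband_table <- function(model, omega) {
  omega <- Re(omega)
  rng <- range(model$omega_ev)
  if (any(omega < rng[1] - 1e-12) || any(omega > rng[2] + 1e-12)) {
    stop(sprintf(
      "extrapolation error: omega outside interband table range [%.4g, %.4g] eV",
      rng[1], rng[2]))
  }
  re <- stats::approx(model$omega_ev, Re(model$alpha), xout = omega,
                      rule = 2)$y
  im <- stats::approx(model$omega_ev, Im(model$alpha), xout = omega,
                      rule = 2)$y
  complex(real = re, imaginary = im)
}

#' Frequency-dependent diagonal shifts of the response systems
#'
#' `z_q()` is the complex Drude shift acting on the charges,
#' `z_q(w) = -w (w tau + i) / (2 n tau)`; it vanishes in the static limit and
#' has a damping-sign imaginary part for every positive frequency.  The
#' prefactor convention is deliberately isolated here: the shipped effective
#' areas are matched to it so that bulk Drude conduction is recovered (see the
#' methods vignette).  `z_mu()` is the dipole shift `-1/alpha_IB(w)`.
#'
#' @param omega frequency in au for `z_q()` (possibly complex), in eV for
#'   `z_mu()`.
#' @param params a [material_params()] object.
#' @return complex shift (au).
#' @examples
#' z_q(0, gold_material())    # exactly 0
#' @export
z_q <- function(omega, params) {
  stopifnot(inherits(params, "material_params"))
  if (all(Im(omega) == 0) && any(Re(omega) < 0)) {
    stop("`omega` must be non-negative")
  }
  -omega * (omega * params$tau + 1i) / (2 * params$n_density * params$tau)
}

#' @rdname z_q
#' @param model an interband model.
#' @export
z_mu <- function(omega, model) {
  a <- interband_alpha(model, omega)
  if (any(abs(a) == 0)) stop("singularity: alpha_IB(omega) = 0")
  -1 / a
}

#' Read and write material configuration files
#'
#' Human-readable YAML key/value files with explicit units:
#' `tau_au`, `n_density_au` (or `fermi_energy_ev` + `fermi_velocity_au` for
#' graphene), `eff_area_au2`, `tunnel_steepness`, `tunnel_scale`,
#' `r0_angstrom`, `m_star`, `reg_width_au`, and an optional `interband`
#' block (`strength_au`, `center_ev`, `width_ev` for Lorentzian models, or
#' `omega_ev`, `alpha_re_au3`, `alpha_im_au3` for tables).
#'
#' @param path file path of the YAML config.
#' @return `read_material()` returns a [material_params()] object.
#' @export
read_material <- function(path) {
  cfg <- yaml::read_yaml(path)
  ib <- NULL
  if (!is.null(cfg$interband)) {
    b <- cfg$interband
    ib <- if (!is.null(b$omega_ev)) {
      interband_table(b$omega_ev,
                      complex(real = b$alpha_re_au3, imaginary = b$alpha_im_au3))
    } else {
      interband_lorentzian(b$strength_au, b$center_ev, b$width_ev)
    }
  }
  if (!is.null(cfg$fermi_energy_ev)) {
    p <- graphene_material(
      fermi_energy = cfg$fermi_energy_ev,
      fermi_velocity = cfg$fermi_velocity_au %||% (137.035999084 / 300))
    for (f in c("tau_au", "eff_area_au2", "reg_width_au")) {
      tgt <- sub("_au2?$", "", f)
      if (!is.null(cfg[[f]])) p[[tgt]] <- cfg[[f]]
    }
    p$interband <- ib
    return(p)
  }
  material_params(
    tau = cfg$tau_au, n_density = cfg$n_density_au,
    eff_area = cfg$eff_area_au2,
    tunnel_steepness = cfg$tunnel_steepness %||% 35,
    tunnel_scale = cfg$tunnel_scale %||% 1.2,
    r0 = cfg$r0_angstrom %||% 2.885,
    m_star = cfg$m_star %||% 1,
    reg_width = cfg$reg_width_au,
    interband = ib, id = cfg$id %||% "custom")
}

#' @rdname read_material
#' @param params a [material_params()] object.
#' @export
write_material <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  cfg <- list(id = params$id, tau_au = params$tau,
              n_density_au = params$n_density,
              eff_area_au2 = params$eff_area,
              tunnel_steepness = params$tunnel_steepness,
              tunnel_scale = params$tunnel_scale,
              r0_angstrom = params$r0, m_star = params$m_star,
              reg_width_au = params$reg_width)
  if (!is.null(params$fermi_energy)) {
    cfg$fermi_energy_ev <- params$fermi_energy
    cfg$fermi_velocity_au <- params$fermi_velocity
  }
  ib <- params$interband
  if (inherits(ib, "interband_lorentzian")) {
    cfg$interband <- list(strength_au = ib$strength,
                          center_ev = au_to_ev(ib$center_au),
                          width_ev = au_to_ev(ib$width_au))
  } else if (inherits(ib, "interband_table")) {
    cfg$interband <- list(omega_ev = ib$omega_ev,
                          alpha_re_au3 = Re(ib$alpha),
                          alpha_im_au3 = Im(ib$alpha))
  }
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
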