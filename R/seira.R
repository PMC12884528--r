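# Surface-enhanced vibrational intensities: molecular sources driving the
# substrate, the induced "external" dipole, numerically differentiated SEIRA
# intensities, the classical local-field-dressed SERS scheme, and
# enhancement-factor reports (EF, AEF, MEF, i-MEF).

# potential/field of the molecular point multipoles at the substrate atoms,
# evaluated with the same regularized kernels as the substrate-substrate
# interactions (molecular sites are bare points, substrate sites Gaussian).
.mol_sources_at <- function(pos_mol_au, q, mu, sys) {
  res <- .mp_eval(pos_mol_au, 0, q, mu, sys$positions_au, sys$widths)
  external_source(res$V, res$E, descriptor = "molecular")
}

#' Potential and field of the molecular density on the substrate
#'
#' Evaluates the electric potential `V_QM(r_p)` and field `E_QM(r_p)`
#' generated at every substrate atom by the surrogate's point charges (and
#' fixed point dipoles, if any), using the same Gaussian-regularized kernels
#' as the substrate's own interactions.
#'
#' @param mol a placed [molecular_surrogate()].
#' @param substrate a [nanostructure()].
#' @param params a [material_params()] object (provides the kernel widths).
#' @return an [external_source()] with descriptor `"molecular"`.
#' @export
molecular_sources <- function(mol, substrate, params) {
  stopifnot(inherits(mol, "molecular_surrogate"),
            inherits(substrate, "nanostructure"))
  n <- nrow(substrate$positions)
  if (n > 0L) {
    d2 <- .cross_dist2(mol$positions, substrate$positions)
    if (min(d2) < 1.0^2) {
      stop("molecule-substrate distance below kernel regularization validity")
    }
  }
  pos_mol <- ang_to_au(mol$positions)
  w <- rep_len(params$reg_width, n)
  res <- .mp_eval(pos_mol, 0, mol$charges, mol$dipoles,
                  ang_to_au(substrate$positions), w)
  external_source(res$V, res$E, descriptor = "molecular")
}

#' Dipole induced on the substrate by the molecular density
#'
#' Solves the substrate response with the molecular potential and field as
#' the external source and reduces the solution to the induced dipole
#' `d_tilde = sum_p (q_p r_p + mu_p)`, the quantity whose geometric
#' derivative carries the SEIRA enhancement.  Projecting the defining
#' identity `-d_tilde . E_ext = sum_p [q_p V_ext(r_p) - mu_p . E_ext(r_p)]`
#' on uniform probe fields reproduces this sum exactly.
#'
#' @inheritParams molecular_sources
#' @param omega frequency in eV.
#' @param model `"wfq"` or `"wfqfmu"`.
#' @param system optional pre-assembled [response_system()].
#' @return list with `value` (complex 3-vector, au) and `solution` (the
#'   underlying `response_solution`).
#' @export
induced_external_dipole <- function(mol, substrate, params, omega,
                                    model = c("wfq", "wfqfmu"),
                                    system = NULL) {
  model <- match.arg(model)
  if (nrow(substrate$positions) == 0L) {
    return(list(value = complex(3), solution = NULL))
  }
  sys <- system %||% response_system(substrate, params, model)
  src <- molecular_sources(mol, substrate, params)
  out <- .solve_system(sys, omega, list(src))
  sol <- .make_solution(sys, omega, out$X, out$residual, "molecular")
  list(value = sol$induced_dipole, solution = sol)
}

#' SEIRA intensities by numerical differentiation of the external dipole
#'
#' For each normal mode `i` the total "external" dipole - the gas-phase
#' molecular dipole `d` plus the substrate dipole `d_tilde` induced by the
#' molecular density - is differentiated along the cartesian mode vector with
#' a 3-point central scheme (displacement of norm `step` Bohr, default
#' 0.001), the substrate being solved at the mode frequency `w_i`.  The
#' enhanced intensity is `I_i = C |d(d + d_tilde)/dQ_i|^2`; vacuum
#' intensities come from the APTs, and the ratio gives the per-mode
#' enhancement factors.  Without a substrate all enhancement factors are 1.
#'
#' @inheritParams induced_external_dipole
#' @param step differentiation step in Bohr (cartesian norm of the
#'   displacement); 0.0005 mirrors the half-step stability check.
#' @return an [enhancement_report()] with per-mode frequencies attached.
#' @export
seira_intensities <- function(mol, substrate, params,
                              model = c("wfq", "wfqfmu"), step = 0.001,
                              system = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(mol, "molecular_surrogate"))
  cst <- plasmovib_constants()
  gvac <- .dipole_gradients(mol)
  ivac <- cst$kmmol_per_e2amu * colSums(gvac^2)
  m <- length(mol$mode_freq)
  bare <- nrow(substrate$positions) == 0L
  if (!bare) {
    sys <- system %||% response_system(substrate, params, model)
    if (min(.cross_dist2(mol$positions, substrate$positions)) <
          (0.9 * au_to_ang(max(sys$widths)))^2) {
      warning("differentiation step operates inside the kernel regularization core")
    }
  }
  pos0_au <- ang_to_au(mol$positions)
  n <- nrow(mol$positions)
  intens <- numeric(m)
  for (i in seq_len(m)) {
    L <- mol$mode_cart[, i]
    nrmL <- sqrt(sum(L^2))
    evec <- L / nrmL
    dQ <- step / nrmL                      # Bohr * sqrt(amu)
    dvec <- list()
    for (sgn in c(1, -1)) {
      dR <- matrix(sgn * step * evec, ncol = 3L, byrow = TRUE)  # au
      posd <- pos0_au + dR
      ind_mu <- t(vapply(seq_len(n), function(a) {
        drop((mol$apt[[a]] - mol$charges[a] * diag(3)) %*% dR[a, ])
      }, numeric(3)))
      if (!is.null(mol$dipoles)) ind_mu <- ind_mu + mol$dipoles
      d_mol <- drop(crossprod(posd, mol$charges)) + colSums(ind_mu)
      if (bare) {
        d_tot <- as.complex(d_mol)
      } else {
        src <- .mol_sources_at(posd, mol$charges, ind_mu, sys)
        out <- .solve_system(sys, cm1_to_ev(mol$mode_freq[i]), list(src))
        sol <- .make_solution(sys, cm1_to_ev(mol$mode_freq[i]), out$X,
                              out$residual, "molecular")
        d_tot <- d_mol + sol$induced_dipole
      }
      dvec[[as.character(sgn)]] <- d_tot
    }
    deriv <- (dvec[["1"]] - dvec[["-1"]]) / (2 * dQ)
    intens[i] <- cst$kmmol_per_e2amu * sum(Mod(deriv)^2)
  }
  enhancement_report(intens, ivac, frequencies = mol$mode_freq)
}

#' Local field tensor of the substrate
#'
#' `Lambda(w) = I + (scattered field at the point per unit applied uniform
#' field)`: the columns are obtained from three axis solves.  `Lambda`
#' dresses molecular transition moments; it tends to the identity far from
#' the substrate and when the substrate is absent.
#'
#' @param substrate a [nanostructure()].
#' @param params a [material_params()] object.
#' @param point evaluation point (3-vector, Angstrom).
#' @param omega frequency in eV; may be complex (lifetime broadening).
#' @param model `"wfq"` or `"wfqfmu"`.
#' @param system optional pre-assembled [response_system()].
#' @return complex 3 x 3 matrix.
#' @export
local_field_tensor <- function(substrate, params, point, omega,
                               model = c("wfq", "wfqfmu"), system = NULL) {
  model <- match.arg(model)
  if (nrow(substrate$positions) == 0L) return(diag(3) + 0i)
  sys <- system %||% response_system(substrate, params, model)
  lam <- matrix(complex(1), 3L, 3L)
  for (b in 1:3) {
    e <- c(0, 0, 0); e[b] <- 1
    src <- uniform_field_source(sys$structure, e)
    out <- .solve_system(sys, omega, list(src))
    sol <- .make_solution(sys, omega, out$X, out$residual, "uniform")
    sc <- scattered_field_at(sol, matrix(point, 1L, 3L))
    lam[, b] <- e + drop(sc$field)
  }
  lam
}

#' Classical SERS intensities by local-field dressing
#'
#' The classical surrogate of the quantum coupled-perturbed scheme: each
#' mode's polarizability derivative is dressed with the local field tensor at
#' the molecular centroid, `a_eff_i = Lambda^T(w_inc) (dalpha/dQ_i)
#' Lambda(w_inc)`, with a phenomenological lifetime broadening added to the
#' substrate response; intensities follow from the standard Raman rotational
#' invariants of `a_eff_i` and are compared with the gas-phase activities.
#' In the scalar-isotropic limit (`Lambda = lambda I`, isotropic derivative)
#' the SERS enhancement is `|lambda|^4`, the square of the corresponding
#' SEIRA dressing `|lambda|^2` - the quartic versus quadratic local-field
#' scaling of the two spectroscopies.
#'
#' @inheritParams seira_intensities
#' @param omega_inc incident (Raman pump) frequency in eV, typically the
#'   substrate's plasmon resonance frequency.
#' @param lifetime phenomenological broadening in eV added to the substrate
#'   response (default 0.10).
#' @return an [enhancement_report()].
#' @export
sers_intensities <- function(mol, substrate, params, omega_inc,
                             model = c("wfq", "wfqfmu"), lifetime = 0.10,
                             system = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(mol, "molecular_surrogate"))
  svac <- gas_raman_activities(mol)
  if (nrow(substrate$positions) == 0L) {
    return(enhancement_report(svac, svac, frequencies = mol$mode_freq))
  }
  sys <- system %||% response_system(substrate, params, model)
  centroid <- colMeans(mol$positions)
  lam <- local_field_tensor(substrate, params, centroid,
                            omega_inc + 0.5i * lifetime, model = model,
                            system = sys)
  s_enh <- vapply(mol$alpha_deriv, function(adv) {
    .raman_activity(t(lam) %*% adv %*% lam)
  }, numeric(1))
  enhancement_report(s_enh, svac, frequencies = mol$mode_freq)
}

#' Local-field dressing of molecular transition moments
#'
#' Algebraic building blocks of the enhancement schemes, exposed for
#' analysis: `dress_ir_gradient()` applies `Lambda^T` to a dipole gradient
#' (SEIRA route, quadratic in the local field), `dress_raman_tensor()`
#' applies `Lambda^T . Lambda` to a polarizability derivative (SERS
#' route, quartic in the local field).
#'
#' @param lambda complex 3 x 3 local field tensor.
#' @param gradient real or complex dipole-gradient 3-vector.
#' @return the dressed gradient / tensor.
#' @export
dress_ir_gradient <- function(lambda, gradient) {
  drop(t(lambda) %*% gradient)
}

#' @rdname dress_ir_gradient
#' @param alpha_deriv real or complex symmetric 3 x 3 tensor.
#' @export
dress_raman_tensor <- function(lambda, alpha_deriv) {
  t(lambda) %*% alpha_deriv %*% lambda
}

#' Raman activity of a (possibly dressed) tensor
#'
#' Rotational-invariant activity `45 |a|^2 + 7 gamma^2` of a symmetric
#' 3 x 3 (complex) tensor.
#'
#' @param tensor 3 x 3 matrix.
#' @return non-negative activity.
#' @export
raman_activity <- function(tensor) .raman_activity(as.matrix(tensor))

#' Per-mode enhancement factors
#'
#' `EF_i = I_i / I_i_vac`, the averaged enhancement factor
#' `AEF = sum(I) / sum(I_vac)`, the maximum `MEF = max_i EF_i`, and the mode
#' attaining it (`i_mef`, ties broken toward the lowest frequency).  Modes
#' with vanishing vacuum intensity are excluded from the per-mode factors and
#' the MEF but kept in the AEF sums.
#'
#' @param intensities per-mode enhanced intensities (>= 0).
#' @param vac_intensities per-mode vacuum intensities (>= 0, not all zero).
#' @param frequencies optional per-mode frequencies (cm^-1).
#' @return an object of class `enhancement_report` with fields `ef`, `aef`,
#'   `mef`, `i_mef`, `intensities`, `vac_intensities`, `frequencies`.
#' @examples
#' r <- enhancement_report(c(2, 4), c(1, 1))
#' r$aef   # 3
#' r$mef   # 4
#' @export
enhancement_report <- function(intensities, vac_intensities,
                               frequencies = NULL) {
  if (length(intensities) != length(vac_intensities)) {
    stop("intensity lists must have equal length")
  }
  if (any(vac_intensities < 0) || any(intensities < 0)) {
    stop("intensities must be non-negative")
  }
  if (sum(vac_intensities) == 0) {
    stop("undefined AEF: vacuum spectrum is identically zero")
  }
  ef <- ifelse(vac_intensities > 0, intensities / vac_intensities, NA_real_)
  aef <- sum(intensities) / sum(vac_intensities)
  mef <- max(ef, na.rm = TRUE)
  cand <- which(!is.na(ef) & ef == mef)
  i_mef <- if (!is.null(frequencies)) cand[which.min(frequencies[cand])] else
    min(cand)
  structure(list(ef = ef, aef = aef, mef = mef, i_mef = i_mef,
                 intensities = intensities,
                 vac_intensities = vac_intensities,
                 frequencies = frequencies),
            class = "enhancement_report")
}

#' @export
print.enhancement_report <- function(x, ...) {
  cat(sprintf("<enhancement_report> %d modes\n", length(x$ef)))
  cat(sprintf("  AEF = %.4g, MEF = %.4g (mode %d%s)\n", x$aef, x$mef,
              x$i_mef,
              if (!is.null(x$frequencies)) {
                sprintf(", %.0f cm^-1", x$frequencies[x$i_mef])
              } else ""))
  invisible(x)
}

#' Average enhancement reports over configurations
#'
#' Arithmetic mean of the per-mode enhanced and vacuum intensities over a set
#' of adsorption configurations sharing the same mode list; enhancement
#' factors are recomputed from the averaged intensities (normalization after
#' averaging).
#'
#' @param reports list of [enhancement_report()] objects with identical mode
#'   frequencies.
#' @return an [enhancement_report()].
#' @export
average_spectra <- function(reports) {
  stopifnot(length(reports) >= 1L)
  f0 <- reports[[1L]]$frequencies
  for (r in reports) {
    if (length(r$ef) != length(reports[[1L]]$ef) ||
        (!is.null(f0) && !isTRUE(all.equal(r$frequencies, f0)))) {
      stop("mismatched mode lists across reports")
    }
  }
  im <- rowMeans(vapply(reports, function(r) r$intensities,
                        numeric(length(f0 %||% reports[[1L]]$ef))))
  vm <- rowMeans(vapply(reports, function(r) r$vac_intensities,
                        numeric(length(im))))
  enhancement_report(im, vm, frequencies = f0)
}
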