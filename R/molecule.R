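# Molecular vibrational surrogate: point-multipole stand-in for the quantum
# molecule.  Carries geometry, masses, partial charges, atomic polar tensors
# (APTs), normal modes, and polarizability derivatives; everything the
# SEIRA/SERS coupling operators need, without any quantum chemistry.

#' Molecular vibrational surrogate
#'
#' A point-multipole vibrational model of the adsorbed molecule: positions
#' and masses, partial charges (whose oscillation generates the potential and
#' field driving the substrate), per-atom atomic polar tensors `d mu / d R`
#' (3 x 3, au), mass-weighted normal modes with frequencies, and per-mode
#' polarizability derivatives `d alpha / d Q` (3 x 3, au).
#'
#' The gas-phase dipole function is linearized through the APTs:
#' `d(R) = sum_a q_a R_a + sum_a (APT_a - q_a I) (R_a - R_a0)`, so the APTs
#' are independent inputs and reduce to the point-charge derivative when
#' `APT_a = q_a I`.  Displaced geometries carry the charge at the displaced
#' position plus an induced point dipole `(APT_a - q_a I) dR_a`, keeping the
#' source multipoles consistent with the dipole function.
#'
#' @param positions numeric n x 3 matrix (Angstrom).
#' @param masses atomic masses (amu).
#' @param charges partial charges (au); must sum to `total_charge` to 1e-12.
#' @param apt list of n real 3 x 3 atomic polar tensors (au).
#' @param mode_freq mode frequencies in cm^-1, positive and ascending.
#' @param mode_vectors 3n x m matrix of mass-weighted displacement vectors,
#'   orthonormal columns (atom-major ordering x1 y1 z1 x2 ...).
#' @param alpha_deriv list of m real 3 x 3 polarizability derivatives (au).
#' @param dipoles optional n x 3 fixed point dipoles (au).
#' @param total_charge declared molecular charge (au).
#' @return an object of class `molecular_surrogate`; cartesian mode vectors
#'   (`mode_cart`, units amu^-1/2) are derived from the mass-weighted ones.
#' @export
molecular_surrogate <- function(positions, masses, charges, apt, mode_freq,
                                mode_vectors, alpha_deriv, dipoles = NULL,
                                total_charge = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(masses) == n, length(charges) == n,
            length(apt) == n)
  m <- length(mode_freq)
  mode_vectors <- as.matrix(mode_vectors)
  stopifnot(nrow(mode_vectors) == 3L * n, ncol(mode_vectors) == m,
            length(alpha_deriv) == m)
  if (abs(sum(charges) - total_charge) > 1e-12) {
    stop("partial charges do not sum to the declared molecular charge")
  }
  if (any(mode_freq <= 0)) stop("mode frequencies must be positive")
  if (is.unsorted(mode_freq)) stop("mode frequencies must be sorted ascending")
  gram <- crossprod(mode_vectors)
  if (max(abs(gram - diag(m))) > 1e-8) {
    stop("mass-weighted mode vectors are not orthonormal to 1e-8")
  }
  minv <- rep(1 / sqrt(masses), each = 3L)
  mode_cart <- mode_vectors * minv
  if (!is.null(dipoles)) dipoles <- matrix(dipoles, ncol = 3L)
  structure(list(positions = positions, masses = masses, charges = charges,
                 apt = apt, mode_freq = mode_freq,
                 mode_vectors = mode_vectors, mode_cart = mode_cart,
                 alpha_deriv = alpha_deriv, dipoles = dipoles,
                 total_charge = total_charge),
            class = "molecular_surrogate")
}

#' @export
print.molecular_surrogate <- function(x, ...) {
  cat(sprintf("<molecular_surrogate> %d atoms, %d modes (%.0f-%.0f cm^-1)\n",
              nrow(x$positions), length(x$mode_freq),
              min(x$mode_freq), max(x$mode_freq)))
  d <- drop(crossprod(ang_to_au(x$positions), x$charges))
  cat(sprintf("  total charge %.3g au, |d| = %.3g au\n", x$total_charge,
              sqrt(sum(d^2))))
  invisible(x)
}

# gas-phase dipole derivative along each normal coordinate:
# d mu / d Q_i = sum_a APT_a . Lcart_(a,i)   (e / sqrt(amu))
.dipole_gradients <- function(mol) {
  n <- nrow(mol$positions)
  m <- length(mol$mode_freq)
  out <- matrix(0, 3L, m)
  for (i in seq_len(m)) {
    L <- matrix(mol$mode_cart[, i], ncol = 3L, byrow = TRUE)
    acc <- c(0, 0, 0)
    for (a in seq_len(n)) acc <- acc + drop(mol$apt[[a]] %*% L[a, ])
    out[, i] <- acc
  }
  out
}

#' Gas-phase IR intensities
#'
#' `I_i = C |d mu / d Q_i|^2` with `d mu / d Q_i = sum_a APT_a L_(a,i)`
#' (cartesian mode vector `L`), reported in km/mol through the standard
#' conversion factor (974.88 km/mol per e^2/amu).
#'
#' @param mol a [molecular_surrogate()] with APTs present.
#' @return numeric vector of per-mode intensities (km/mol).
#' @export
gas_ir_intensities <- function(mol) {
  stopifnot(inherits(mol, "molecular_surrogate"))
  if (is.null(mol$apt)) stop("configuration error: APTs missing")
  g <- .dipole_gradients(mol)
  plasmovib_constants()$kmmol_per_e2amu * colSums(g^2)
}

# Raman rotational invariants of a (possibly complex) symmetric 3x3 tensor:
# S = 45 |a|^2 + 7 gamma^2 with a = tr/3 and the anisotropy gamma^2.
.raman_activity <- function(t3) {
  a <- (t3[1, 1] + t3[2, 2] + t3[3, 3]) / 3
  g2 <- 0.5 * (Mod(t3[1, 1] - t3[2, 2])^2 + Mod(t3[2, 2] - t3[3, 3])^2 +
                 Mod(t3[3, 3] - t3[1, 1])^2) +
    3 * (Mod((t3[1, 2] + t3[2, 1]) / 2)^2 +
           Mod((t3[2, 3] + t3[3, 2]) / 2)^2 +
           Mod((t3[1, 3] + t3[3, 1]) / 2)^2)
  45 * Mod(a)^2 + 7 * g2
}

#' Gas-phase Raman activities
#'
#' Standard rotational-invariant combination `45 a'^2 + 7 gamma'^2` of each
#' mode's polarizability derivative; non-negative by construction.
#'
#' @param mol a [molecular_surrogate()] with polarizability derivatives.
#' @return numeric vector of per-mode activities (au^4/amu).
#' @export
gas_raman_activities <- function(mol) {
  stopifnot(inherits(mol, "molecular_surrogate"))
  if (is.null(mol$alpha_deriv)) {
    stop("configuration error: polarizability derivatives missing")
  }
  vapply(mol$alpha_deriv, .raman_activity, numeric(1))
}

#' Seeded synthetic molecular surrogate
#'
#' Deterministic generator of a planar purine-like surrogate: a fused
#' five/six ring skeleton with outward substituents, bounded random partial
#' charges (|q| <= 0.5, exactly neutral), random APTs built around the
#' point-charge values, `3n - 6` orthonormal mass-weighted modes with
#' frequencies in 400-1800 cm^-1, and random symmetric polarizability
#' derivatives.  The same seed reproduces the surrogate bit for bit; the RNG
#' state of the session is left untouched.
#'
#' @param seed integer seed.
#' @param n_atoms number of atoms (>= 3).
#' @param planar keep all atoms in the z = 0 plane (default); otherwise a
#'   +-0.1 Angstrom out-of-plane jitter is applied.
#' @return a [molecular_surrogate()].
#' @examples
#' mol <- make_fixture(7)
#' length(mol$mode_freq)    # 3*15 - 6
#' @export
make_fixture <- function(seed, n_atoms = 15L, planar = TRUE) {
  if (n_atoms < 3L) stop("`n_atoms` must be at least 3")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  # purine-like fused 6+5 ring template (Angstrom, z = 0)
  hex <- t(vapply(0:5, function(k) {
    1.39 * c(cos(pi / 6 + k * pi / 3), sin(pi / 6 + k * pi / 3), 0)
  }, numeric(3)))
  pent_c <- c(2 * 1.39 * cos(pi / 6), 0, 0)
  pent <- t(vapply(c(-0.55, 0.55, 1.55) * pi / 2.5, function(a) {
    pent_c + 1.35 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  ring <- rbind(hex, pent)
  n_ring <- min(n_atoms, nrow(ring))
  pos <- ring[seq_len(n_ring), , drop = FALSE]
  extra <- n_atoms - n_ring
  if (extra > 0L) {
    host <- rep(seq_len(n_ring), length.out = extra)
    for (k in seq_len(extra)) {
      dir <- pos[host[k], ] - colMeans(pos[seq_len(n_ring), , drop = FALSE])
      dir[3] <- 0
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm > 1e-8) dir / nrm else c(1, 0, 0)
      bump <- 1.02 + 0.25 * stats::runif(1)
      pos <- rbind(pos, pos[host[k], ] + bump * dir +
                     c(stats::runif(2, -0.08, 0.08), 0))
    }
  }
  if (!planar) pos[, 3] <- pos[, 3] + stats::runif(n_atoms, -0.1, 0.1)
  masses <- c(sample(c(12.011, 14.007), n_ring, replace = TRUE),
              rep(1.008, max(extra, 0)))
  q <- stats::runif(n_atoms, -0.5, 0.5)
  q <- q - mean(q)
  q[n_atoms] <- -sum(q[-n_atoms])           # exact neutrality
  q <- pmax(pmin(q, 0.5), -0.5)
  q[n_atoms] <- -sum(q[-n_atoms])
  apt <- lapply(seq_len(n_atoms), function(a) {
    q[a] * diag(3) + matrix(stats::runif(9, -0.3, 0.3), 3L, 3L)
  })
  nm <- 3L * n_atoms - 6L
  # rigid-body space in mass-weighted coordinates
  sqm <- sqrt(masses)
  com <- colSums(pos * masses) / sum(masses)
  rel <- sweep(pos, 2L, com)
  rigid <- matrix(0, 3L * n_atoms, 6L)
  for (k in 1:3) rigid[seq(k, 3L * n_atoms, by = 3L), k] <- sqm
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(n_atoms), function(a) {
      sqm[a] * pracma_cross(axes[k, ], rel[a, ])
    }, numeric(3)))
    rigid[, 3L + k] <- as.vector(t(rot))
  }
  keep <- sqrt(colSums(rigid^2)) > 1e-10
  rigid <- rigid[, keep, drop = FALSE]
  qr_r <- qr(rigid)
  rigid_on <- qr.Q(qr_r)[, seq_len(qr_r$rank), drop = FALSE]
  raw <- matrix(stats::rnorm(3L * n_atoms * nm), 3L * n_atoms, nm)
  raw <- raw - rigid_on %*% crossprod(rigid_on, raw)
  modes <- qr.Q(qr(raw))[, seq_len(nm), drop = FALSE]
  freq <- sort(stats::runif(nm, 400, 1800))
  adv <- lapply(seq_len(nm), function(i) {
    m0 <- matrix(stats::runif(9, -1, 1), 3L, 3L)
    (m0 + t(m0)) / 2
  })
  molecular_surrogate(pos, masses, q, apt, freq, modes, adv)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Placement of a molecule on a substrate
#'
#' `placement()` describes how the surrogate is put on the substrate: a
#' proper rotation applied about the anchor atom, the substrate surface point
#' (defaults to the substrate atom nearest the structure's "top"), and the
#' anchor-to-surface distance along the local outward normal.  `place()`
#' applies it: after rotation, the anchor is slid along the normal until its
#' distance to the nearest substrate atom equals `distance` (to 1e-6
#' Angstrom).  End-on (anchor pointing at the surface) and face-on (molecular
#' plane parallel to the surface) orientations are built automatically when
#' `mode` is given; `rotation` overrides them.
#'
#' @param anchor_atom index of the molecular anchor atom.
#' @param distance anchor-to-substrate distance (Angstrom).
#' @param rotation proper rotation matrix (3 x 3, det +1) or `NULL` to derive
#'   it from `mode`.
#' @param surface_point 3-vector on the substrate (Angstrom) or `NULL` for
#'   the default site.
#' @param mode `"end_on"` or `"face_on"`.
#' @return `placement()` returns a `placement` object; `place()` returns the
#'   transformed [molecular_surrogate()].
#' @export
placement <- function(anchor_atom = 1L, distance = 3.0, rotation = NULL,
                      surface_point = NULL, mode = c("end_on", "face_on")) {
  mode <- match.arg(mode)
  if (!is.null(rotation)) {
    rotation <- as.matrix(rotation)
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
        abs(det(rotation) - 1) > 1e-10) {
      stop("`rotation` must be a proper rotation (orthogonal, det +1)")
    }
  }
  structure(list(anchor_atom = anchor_atom, distance = distance,
                 rotation = rotation, surface_point = surface_point,
                 mode = mode),
            class = "placement")
}

# rotation taking unit vector a onto unit vector b
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b)
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) pracma_cross(a, c(1, 0, 0)) else
      pracma_cross(a, c(0, 1, 0))
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
}

#' @rdname placement
#' @param mol a [molecular_surrogate()].
#' @param substrate a [nanostructure()].
#' @param plc a `placement` object.
#' @export
place <- function(mol, substrate, plc) {
  stopifnot(inherits(mol, "molecular_surrogate"),
            inherits(substrate, "nanostructure"),
            inherits(plc, "placement"))
  spos <- substrate$positions
  centroid <- colMeans(spos)
  flat <- diff(range(spos[, 3])) < 1e-6
  sp <- plc$surface_point
  if (is.null(sp)) {
    if (flat) {
      i0 <- which.min(rowSums(sweep(spos[, 1:2, drop = FALSE], 2L,
                                    centroid[1:2])^2))
    } else {
      i0 <- which.max(spos[, 3])
    }
    sp <- spos[i0, ]
  }
  normal <- if (flat) c(0, 0, 1) else {
    nv <- sp - centroid
    nv / sqrt(sum(nv^2))
  }
  pos <- mol$positions
  anchor <- plc$anchor_atom
  R <- plc$rotation
  if (is.null(R)) {
    mcen <- colMeans(pos)
    if (plc$mode == "end_on") {
      dirv <- pos[anchor, ] - mcen
      if (sqrt(sum(dirv^2)) < 1e-9) dirv <- c(0, 0, -1)
      R <- .rotation_between(dirv, -normal)
    } else {
      sv <- svd(sweep(pos, 2L, mcen))
      plane_normal <- sv$v[, 3L]
      R <- .rotation_between(plane_normal, normal)
    }
  }
  rel <- sweep(pos, 2L, pos[anchor, ])
  rot <- rel %*% t(R)
  fdist <- function(t) {
    a <- sp + t * normal
    sqrt(min(rowSums(sweep(spos, 2L, a)^2))) - plc$distance
  }
  tt <- stats::uniroot(fdist, c(0, plc$distance + 60), tol = 1e-9)$root
  newpos <- sweep(rot, 2L, sp + tt * normal, "+")
  mind <- sqrt(min(.cross_dist2(newpos, spos)))
  if (mind < 1.5) {
    stop(sprintf("placement error: steric clash (min distance %.3f Angstrom < 1.5)",
                 mind))
  }
  if (mind < 0.9 * plc$distance - 1e-9) {
    stop(sprintf(
      "placement error: minimum molecule-substrate distance %.3f < 0.9 * %.3f",
      mind, plc$distance))
  }
  out <- mol
  out$positions <- newpos
  # rotate tensorial quantities with the molecule
  out$apt <- lapply(mol$apt, function(a) R %*% a %*% t(R))
  out$alpha_deriv <- lapply(mol$alpha_deriv, function(a) R %*% a %*% t(R))
  if (!is.null(mol$dipoles)) out$dipoles <- mol$dipoles %*% t(R)
  rotm <- function(v) {
    m <- matrix(v, ncol = 3L, byrow = TRUE) %*% t(R)
    as.vector(t(m))
  }
  out$mode_vectors <- apply(mol$mode_vectors, 2L, rotm)
  out$mode_cart <- apply(mol$mode_cart, 2L, rotm)
  out
}

# squared distances between all rows of a and b (small sizes)
.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

#' Read and write the surrogate JSON schema
#'
#' Documented plain-text schema with explicit units: positions in Angstrom,
#' charges and APTs in au, mode frequencies in cm^-1 with dimensionless
#' mass-weighted vectors, polarizability derivatives in au.
#'
#' @param mol a [molecular_surrogate()].
#' @param path file path.
#' @return `read_surrogate()` returns a [molecular_surrogate()].
#' @export
write_surrogate <- function(mol, path) {
  stopifnot(inherits(mol, "molecular_surrogate"))
  obj <- list(
    units = list(positions = "angstrom", charges = "au", apt = "au",
                 mode_freq = "cm-1", alpha_deriv = "au"),
    positions = mol$positions, masses = mol$masses, charges = mol$charges,
    apt = mol$apt, mode_freq = mol$mode_freq,
    mode_vectors = mol$mode_vectors, alpha_deriv = mol$alpha_deriv,
    total_charge = mol$total_charge)
  if (!is.null(mol$dipoles)) obj$dipoles <- mol$dipoles
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  apt <- lapply(seq_len(dim(obj$apt)[1]), function(a) obj$apt[a, , ])
  adv <- lapply(seq_len(dim(obj$alpha_deriv)[1]),
                function(i) obj$alpha_deriv[i, , ])
  molecular_surrogate(obj$positions, obj$masses, obj$charges, apt,
                      obj$mode_freq, obj$mode_vectors, adv,
                      dipoles = obj$dipoles,
                      total_charge = obj$total_charge %||% 0)
}
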