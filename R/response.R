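# Frequency-domain response: the fluctuating-charge (wFQ) and
# fluctuating-charge-and-dipole (wFQFmu) linear systems, their dense and
# matrix-free iterative solutions, polarizabilities, absorption spectra and
# plasmon resonance frequencies, and scattered fields.

# sparse real matrix times complex vector (Matrix lacks complex support)
.spmv <- function(M, x) {
  if (is.complex(x)) {
    as.vector(M %*% Re(x)) + 1i * as.vector(M %*% Im(x))
  } else {
    as.vector(M %*% x)
  }
}

#' External source acting on the substrate
#'
#' A uniform-field source stores the potential `V_ext(r_p) = -e . r_p` and
#' the constant field `e` at every atom (atomic units).  Molecular sources
#' (potential and field of the oscillating molecular density) are produced by
#' [molecular_sources()].
#'
#' @param structure a [nanostructure()].
#' @param direction 3-vector; normalized to a unit probe field.
#' @return object of class `external_source` with fields `potential` (complex
#'   N-vector, au), `field` (complex N x 3, au) and `descriptor`.
#' @export
uniform_field_source <- function(structure, direction = c(0, 0, 1)) {
  stopifnot(inherits(structure, "nanostructure"), length(direction) == 3L)
  e <- direction / sqrt(sum(direction^2))
  pos <- ang_to_au(structure$positions)
  structure(list(potential = as.complex(-drop(pos %*% e)),
                 field = matrix(rep(as.complex(e), each = nrow(pos)),
                                ncol = 3L),
                 descriptor = "uniform"),
            class = "external_source")
}

#' @rdname uniform_field_source
#' @param potential complex per-atom potential (au).
#' @param field complex N x 3 per-atom field (au).
#' @param descriptor short label for the source.
#' @export
external_source <- function(potential, field, descriptor = "custom") {
  structure(list(potential = as.complex(potential),
                 field = matrix(as.complex(field), ncol = 3L),
                 descriptor = descriptor),
            class = "external_source")
}

#' Pre-assembled response system
#'
#' Assembles everything frequency-independent once (conduction matrix,
#' interaction kernels or their matrix-free application), so that frequency
#' scans and repeated solves amortize the assembly cost.  Below `dense_limit`
#' atoms the kernel blocks are formed as dense matrices and solves use LU
#' factorization; above it the kernels are applied on the fly and solves use
#' the iterative path.
#'
#' @param structure a [nanostructure()]; the neighbor graph is built at
#'   `1.2 * r0` if absent.
#' @param params a [material_params()] object.
#' @param model `"wfq"` (charges only) or `"wfqfmu"` (charges and dipoles;
#'   requires an interband model).
#' @param dense_limit atom count threshold for dense assembly.
#' @return an object of class `response_system`.
#' @export
response_system <- function(structure, params, model = c("wfq", "wfqfmu"),
                            dense_limit = 4000L) {
  model <- match.arg(model)
  stopifnot(inherits(structure, "nanostructure"),
            inherits(params, "material_params"))
  if (model == "wfqfmu" && is.null(params$interband)) {
    stop("configuration error: wfqfmu requires an interband model in `params`")
  }
  if (is.null(structure$neighbor_pairs)) {
    structure <- neighbor_graph(structure, 1.2 * params$r0)
  }
  n <- nrow(structure$positions)
  cm <- build_conduction_matrix(structure, params)
  pos <- ang_to_au(structure$positions)
  w <- rep_len(params$reg_width, n)
  dense <- if (model == "wfq") n <= dense_limit else n <= min(dense_limit, 1000L)
  sys <- list(model = model, n = n, kbar = cm$kbar, positions_au = pos,
              widths = w, params = params, dense = dense,
              structure = structure)
  if (dense) {
    kern <- build_interaction_kernels(structure, w)
    sys$kernels <- kern
    sys$KTqq <- as.matrix(cm$kbar %*% kern$Tqq)
    if (model == "wfqfmu") sys$KTqmu <- as.matrix(cm$kbar %*% kern$Tqmu)
  } else {
    selfT <- 2 / (sqrt(pi) * (sqrt(2) * w))
    sys$selfT <- selfT
  }
  class(sys) <- "response_system"
  sys
}

# kernel-matrix products for the matrix-free path:
# returns list(P = Tqq q + Tqmu mu, F = Tmuq q + Tmumu mu)
.kernel_apply <- function(sys, q, mu = NULL) {
  res <- .mp_eval(sys$positions_au, sys$widths, q, mu,
                  sys$positions_au, sys$widths,
                  self_index = seq_len(sys$n))
  P <- res$V + sys$selfT * q          # Gaussian self-interaction on diagonal
  list(P = P, F = -res$E)
}

# Dense or iterative solve of the frequency-dependent linear system for one
# or several right-hand sides.  `sources`: list of external_source objects.
.solve_system <- function(sys, omega_ev, sources, method = "auto",
                          tol = 1e-8, maxit = 2000L, x0 = NULL) {
  omega_au <- if (is.complex(omega_ev)) {
    ev_to_au(omega_ev)
  } else {
    ev_to_au(omega_ev + 0i)
  }
  zq <- z_q(omega_au, sys$params)
  if (Mod(zq) == 0) {
    stop(paste("solver error: the system is singular at omega = 0",
               "(the static limit is the constrained charge equilibration)"))
  }
  n <- sys$n
  rhs_list <- lapply(sources, function(s) {
    top <- -.spmv(sys$kbar, s$potential)
    if (sys$model == "wfq") top else c(top, as.vector(t(s$field)))
  })
  B <- do.call(cbind, rhs_list)
  if (sys$model == "wfqfmu") {
    zm <- z_mu(omega_ev, sys$params$interband)
  }
  use_dense <- (method == "dense") || (method == "auto" && sys$dense)
  if (use_dense && !sys$dense) stop("dense solve requested on a matrix-free system")
  if (use_dense) {
    if (sys$model == "wfq") {
      A <- sys$KTqq - diag(zq, n)
    } else {
      A <- rbind(cbind(sys$KTqq - diag(zq, n), sys$KTqmu),
                 cbind(sys$kernels$Tmuq,
                       sys$kernels$Tmumu - diag(zm, 3L * n)))
    }
    X <- tryCatch(solve(A, B), error = function(e) {
      kap <- tryCatch(kappa(abs(A), exact = FALSE), error = function(e2) Inf)
      stop(sprintf(
        "solver error: system singular or ill-conditioned (condition estimate %.3g) at omega = %.6g eV",
        kap, Re(omega_ev)), call. = FALSE)
    })
    X <- as.matrix(X)
    res_norm <- max(vapply(seq_len(ncol(B)), function(k) {
      r <- A %*% X[, k] - B[, k]
      sqrt(sum(Mod(r)^2)) / max(sqrt(sum(Mod(B[, k])^2)), 1e-300)
    }, numeric(1)))
    return(list(X = X, residual = res_norm))
  }
  # matrix-free / iterative
  matvec <- if (sys$model == "wfq") {
    if (!is.null(sys$KTqq)) {
      function(x) drop(sys$KTqq %*% x) - zq * x
    } else {
      function(x) {
        ka <- .kernel_apply(sys, x, NULL)
        .spmv(sys$kbar, ka$P) - zq * x
      }
    }
  } else {
    if (!is.null(sys$KTqq)) {
      function(x) {
        q <- x[seq_len(n)]
        m <- x[-seq_len(n)]
        top <- drop(sys$KTqq %*% q) + drop(sys$KTqmu %*% m) - zq * q
        bot <- drop(sys$kernels$Tmuq %*% q) + drop(sys$kernels$Tmumu %*% m) -
          zm * m
        c(top, bot)
      }
    } else {
      function(x) {
        q <- x[seq_len(n)]
        m <- matrix(x[-seq_len(n)], ncol = 3L, byrow = TRUE)
        ka <- .kernel_apply(sys, q, m)
        top <- .spmv(sys$kbar, ka$P) - zq * q
        bot <- as.vector(t(matrix(ka$F, ncol = 3L))) - zm * x[-seq_len(n)]
        c(top, bot)
      }
    }
  }
  X <- matrix(complex(1), nrow(B), ncol(B))
  res_norm <- 0
  for (k in seq_len(ncol(B))) {
    guess <- if (!is.null(x0)) x0[, k] else NULL
    g <- .gmres(matvec, B[, k], x0 = guess, tol = tol, maxit = maxit)
    if (!g$converged) {
      stop(sprintf(
        "solver error: GMRES did not converge in %d iterations (residual %.3g)",
        g$iterations, g$residual))
    }
    X[, k] <- g$x
    res_norm <- max(res_norm, g$residual)
  }
  list(X = X, residual = res_norm)
}

# Restarted complex GMRES with modified Gram-Schmidt and Givens rotations.
.gmres <- function(matvec, b, x0 = NULL, tol = 1e-8, maxit = 2000L,
                   restart = 200L) {
  n <- length(b)
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(list(x = complex(n), converged = TRUE,
                              residual = 0, iterations = 0L))
  x <- if (is.null(x0)) complex(n) else as.complex(x0)
  total_it <- 0L
  repeat {
    r <- b - matvec(x)
    beta <- sqrt(sum(Mod(r)^2))
    if (beta / bnorm <= tol) {
      return(list(x = x, converged = TRUE, residual = beta / bnorm,
                  iterations = total_it))
    }
    m <- min(restart, maxit - total_it)
    if (m <= 0L) {
      return(list(x = x, converged = FALSE, residual = beta / bnorm,
                  iterations = total_it))
    }
    V <- matrix(complex(1), n, m + 1L)
    H <- matrix(complex(1), m + 1L, m)
    cs <- complex(m); sn <- complex(m)
    g <- complex(m + 1L); g[1L] <- beta
    V[, 1L] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      wv <- matvec(V[, k])
      for (i in seq_len(k)) {
        H[i, k] <- sum(Conj(V[, i]) * wv)
        wv <- wv - H[i, k] * V[, i]
      }
      H[k + 1L, k] <- sqrt(sum(Mod(wv)^2))
      if (Mod(H[k + 1L, k]) > 1e-300) V[, k + 1L] <- wv / H[k + 1L, k]
      for (i in seq_len(k - 1L)) {
        tmp <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
        H[i + 1L, k] <- -Conj(sn[i]) * H[i, k] + cs[i] * H[i + 1L, k]
        H[i, k] <- tmp
      }
      denom <- sqrt(Mod(H[k, k])^2 + Mod(H[k + 1L, k])^2)
      if (denom == 0) { cs[k] <- 1; sn[k] <- 0 } else {
        cs[k] <- Mod(H[k, k]) / denom
        ph <- if (Mod(H[k, k]) > 0) H[k, k] / Mod(H[k, k]) else 1
        sn[k] <- ph * Conj(H[k + 1L, k]) / denom
      }
      tmp <- cs[k] * H[k, k] + sn[k] * H[k + 1L, k]
      H[k + 1L, k] <- 0
      H[k, k] <- tmp
      g[k + 1L] <- -Conj(sn[k]) * g[k]
      g[k] <- cs[k] * g[k]
      k_used <- k
      total_it <- total_it + 1L
      if (Mod(g[k + 1L]) / bnorm <= tol) break
    }
    y <- solve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
               g[seq_len(k_used)])
    x <- x + V[, seq_len(k_used), drop = FALSE] %*% y
    x <- as.vector(x)
    if (Mod(g[k_used + 1L]) / bnorm <= tol || total_it >= maxit) {
      r <- b - matvec(x)
      res <- sqrt(sum(Mod(r)^2)) / bnorm
      return(list(x = x, converged = res <= tol * 10, residual = res,
                  iterations = total_it))
    }
  }
}

.make_solution <- function(sys, omega_ev, X, residual, source_desc) {
  n <- sys$n
  q <- X[seq_len(n), 1L]
  mu <- NULL
  if (sys$model == "wfqfmu") {
    mu <- matrix(X[-seq_len(n), 1L], ncol = 3L, byrow = TRUE)
  }
  ind <- drop(crossprod(sys$positions_au, q))
  if (!is.null(mu)) ind <- ind + colSums(mu)
  structure(list(omega = omega_ev, model = sys$model, charges = q,
                 dipoles = mu, induced_dipole = ind,
                 residual_norm = residual, positions_au = sys$positions_au,
                 widths = sys$widths, source = source_desc),
            class = "response_solution")
}

#' Solve the fluctuating-charge response systems
#'
#' `solve_wfq()` solves the charge-only system
#' `[Kbar Tqq - z_q(w) I] q = -Kbar V_ext` and `solve_wfqfmu()` the coupled
#' charge-dipole block system (conduction-projected potential row, field row
#' shifted by `z_mu = -1/alpha_IB`).  Row and column sums of `Kbar` vanish,
#' so the induced charges always sum to zero on a neutral substrate.
#'
#' @param structure a [nanostructure()] (neighbor graph built automatically if
#'   missing).
#' @param params a [material_params()] object.
#' @param omega frequency in eV (> 0; the static system is singular by
#'   construction - charge equilibration is its limit).
#' @param source an [external_source()] / [uniform_field_source()].
#' @param system optional pre-assembled [response_system()] (must match
#'   `structure`/`params`).
#' @param method `"auto"`, `"dense"` (LU) or `"iterative"` (GMRES, relative
#'   residual `tol`, warm-startable).
#' @param tol iterative relative-residual tolerance.
#' @param maxit iterative iteration cap.
#' @return an object of class `response_solution` with complex per-atom
#'   `charges` (and `dipoles` for wfqfmu), the `induced_dipole` 3-vector
#'   `sum(q_p r_p + mu_p)` (au), and `residual_norm`.
#' @examples
#' s <- neighbor_graph(build_mackay_icosahedron(1), 1.2 * 2.885)
#' sol <- solve_wfq(s, gold_material(NULL), 2.5,
#'                  uniform_field_source(s, c(0, 0, 1)))
#' abs(sum(sol$charges))      # ~0: charge conservation
#' @export
solve_wfq <- function(structure, params, omega, source, system = NULL,
                      method = c("auto", "dense", "iterative"),
                      tol = 1e-8, maxit = 2000L) {
  method <- match.arg(method)
  sys <- system %||% response_system(structure, params, "wfq")
  out <- .solve_system(sys, omega, list(source), method = method, tol = tol,
                       maxit = maxit)
  .make_solution(sys, omega, out$X, out$residual, source$descriptor)
}

#' @rdname solve_wfq
#' @export
solve_wfqfmu <- function(structure, params, omega, source, system = NULL,
                         method = c("auto", "dense", "iterative"),
                         tol = 1e-8, maxit = 2000L) {
  method <- match.arg(method)
  sys <- system %||% response_system(structure, params, "wfqfmu")
  out <- .solve_system(sys, omega, list(source), method = method, tol = tol,
                       maxit = maxit)
  .make_solution(sys, omega, out$X, out$residual, source$descriptor)
}

#' @export
print.response_solution <- function(x, ...) {
  cat(sprintf("<response_solution> %s at %.4f eV\n", x$model, Re(x$omega)))
  cat(sprintf("  sum(q) = %.3g, residual = %.3g\n",
              Mod(sum(x$charges)), x$residual_norm))
  d <- x$induced_dipole
  cat(sprintf("  induced dipole (au): %.4g%+.4gi, %.4g%+.4gi, %.4g%+.4gi\n",
              Re(d[1]), Im(d[1]), Re(d[2]), Im(d[2]), Re(d[3]), Im(d[3])))
  invisible(x)
}

#' Quasi-static polarizability tensor
#'
#' Solves the response for unit uniform fields along x, y, z; column `b` of
#' the tensor is the induced dipole for the probe along axis `b`.  The tensor
#' is symmetric (reciprocity of the symmetric kernels) and its imaginary
#' trace is non-negative for positive frequencies (passivity).
#'
#' @inheritParams solve_wfq
#' @param model `"wfq"` or `"wfqfmu"`.
#' @return complex 3 x 3 matrix (au^3).
#' @export
polarizability <- function(structure, params, omega,
                           model = c("wfq", "wfqfmu"), system = NULL,
                           method = c("auto", "dense", "iterative"),
                           tol = 1e-8, maxit = 2000L) {
  model <- match.arg(model)
  method <- match.arg(method)
  sys <- system %||% response_system(structure, params, model)
  src <- lapply(1:3, function(b) {
    e <- c(0, 0, 0); e[b] <- 1
    uniform_field_source(sys$structure, e)
  })
  out <- .solve_system(sys, omega, src, method = method, tol = tol,
                       maxit = maxit)
  n <- sys$n
  alpha <- matrix(complex(1), 3L, 3L)
  for (b in 1:3) {
    q <- out$X[seq_len(n), b]
    ind <- drop(crossprod(sys$positions_au, q))
    if (sys$model == "wfqfmu") {
      mu <- matrix(out$X[-seq_len(n), b], ncol = 3L, byrow = TRUE)
      ind <- ind + colSums(mu)
    }
    alpha[, b] <- ind
  }
  alpha
}

#' Absorption cross-section spectrum and plasmon resonance frequency
#'
#' Scans the orientation-averaged quasi-static absorption cross-section
#' `sigma(w) = (4 pi w / c) * Im(tr alpha(w)) / 3` over a frequency grid and
#' locates the plasmon resonance frequency (PRF) as the refined position of
#' its global maximum.  Per-axis cross-sections are also stored.
#'
#' @inheritParams polarizability
#' @param grid increasing, positive frequency grid in eV (at least 3 points).
#' @param verbose print per-frequency progress.
#' @return object of class `absorption_spectrum` with fields `grid` (eV),
#'   `sigma` (au^2), `sigma_axes` (per-axis), `prf` (eV) and `model`.
#' @export
absorption_spectrum <- function(structure, params, grid,
                                model = c("wfq", "wfqfmu"), system = NULL,
                                method = c("auto", "dense", "iterative"),
                                tol = 1e-8, verbose = FALSE) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (length(grid) < 3L) stop("grid must contain at least 3 points")
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0)) {
    stop("grid must be strictly increasing and positive")
  }
  sys <- system %||% response_system(structure, params, model)
  cst <- plasmovib_constants()
  sig <- numeric(length(grid))
  sig_axes <- matrix(0, length(grid), 3L)
  for (k in seq_along(grid)) {
    a <- polarizability(structure, params, grid[k], model = model,
                        system = sys, method = method, tol = tol)
    wau <- ev_to_au(grid[k])
    pre <- 4 * pi * wau / cst$c_au
    sig_axes[k, ] <- pre * Im(diag(a))
    sig[k] <- pre * Im(sum(diag(a))) / 3
    if (verbose) {
      message(sprintf("  omega = %.4f eV  sigma = %.6g au^2", grid[k], sig[k]))
    }
  }
  sp <- structure(list(grid = grid, sigma = sig, sigma_axes = sig_axes,
                       model = model), class = "absorption_spectrum")
  sp$prf <- find_prf(sp)
  sp
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf("<absorption_spectrum> %s, %d points on [%.3f, %.3f] eV\n",
              x$model, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  PRF = %.4f eV (%.1f cm^-1), peak sigma = %.4g au^2\n",
              x$prf, ev_to_cm1(x$prf), max(x$sigma)))
  invisible(x)
}

#' @export
plot.absorption_spectrum <- function(x, ...) {
  graphics::plot(x$grid, x$sigma, type = "l", xlab = "frequency (eV)",
                 ylab = expression(sigma ~ (au^2)), ...)
  graphics::abline(v = x$prf, lty = 2, col = "grey50")
  invisible(x)
}

#' Plasmon resonance frequency of a spectrum
#'
#' Position of the global maximum of the cross-section, refined by a 3-point
#' parabola through the maximum and its neighbors.  Ties are broken toward
#' lower frequency; a maximum on the grid boundary is returned as-is with a
#' warning (monotone spectrum), as is a degenerate (flat) maximum.
#'
#' @param spectrum an `absorption_spectrum`, or any list with numeric fields
#'   `grid` and `sigma`.
#' @return refined peak frequency, in the unit of `grid`.
#' @export
find_prf <- function(spectrum) {
  g <- spectrum$grid
  s <- spectrum$sigma
  if (length(g) < 3L) stop("spectrum must have at least 3 points")
  if (diff(range(s)) == 0) {
    warning("degenerate (flat) spectrum: returning the lowest maximizer")
    return(g[1L])
  }
  i <- which.max(s)          # first maximum: ties break toward lower frequency
  if (i == 1L || i == length(g)) {
    warning("spectrum is monotone on the grid: returning the boundary maximum")
    return(g[i])
  }
  x1 <- g[i - 1L]; x2 <- g[i]; x3 <- g[i + 1L]
  y1 <- s[i - 1L]; y2 <- s[i]; y3 <- s[i + 1L]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  A <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  B <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (abs(A) < 1e-300) {
    warning("degenerate (flat) maximum: returning the lowest maximizer")
    return(g[i])
  }
  -B / (2 * A)
}

#' Scattered potential and field of a response solution
#'
#' Superposition of the regularized fields of the solution's charges and
#' dipoles at arbitrary points (finite everywhere thanks to the Gaussian
#' regularization, and linear in the solution).
#'
#' @param solution a `response_solution`.
#' @param points numeric M x 3 matrix of evaluation points (Angstrom).
#' @return list with complex `potential` (length M, au) and `field`
#'   (M x 3, au).
#' @export
scattered_field_at <- function(solution, points) {
  stopifnot(inherits(solution, "response_solution"))
  pts <- ang_to_au(matrix(points, ncol = 3L))
  res <- .mp_eval(solution$positions_au, solution$widths,
                  solution$charges, solution$dipoles, pts, 0)
  list(potential = res$V, field = res$E)
}
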