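test_that("solutions vanish for zero sources and always conserve charge", {
  s <- small_icosahedron(1)
  p <- gold_drude()
  zero <- external_source(complex(13), matrix(0i, 13, 3))
  sol <- solve_wfq(s, p, 2.0, zero)
  expect_equal(max(Mod(sol$charges)), 0)

  pg <- gold_material()
  for (seed in 1:3) {
    st <- random_cluster(15, seed = seed)
    set.seed(seed)
    src <- uniform_field_source(st, rnorm(3))
    sol <- solve_wfq(st, gold_drude(), runif(1, 0.5, 4), src)
    expect_lt(Mod(sum(sol$charges)), 1e-8 * sum(Mod(sol$charges)))
    sol2 <- solve_wfqfmu(st, pg, runif(1, 0.5, 4), src)
    expect_lt(Mod(sum(sol2$charges)), 1e-8 * max(sum(Mod(sol2$charges)), 1e-30))
  }
  expect_error(solve_wfq(s, p, 0, uniform_field_source(s)), "singular")
})

test_that("iterative and matrix-free solutions match the dense factorization", {
  pg <- gold_material()
  for (cfg in list(list(n = 20, seed = 1), list(n = 40, seed = 2))) {
    st <- random_cluster(cfg$n, seed = cfg$seed)
    src <- uniform_field_source(st, c(1, -2, 0.5))
    for (model in c("wfq", "wfqfmu")) {
      sys <- response_system(st, pg, model)
      a <- plasmovib:::.solve_system(sys, 2.3, list(src), method = "dense")
      b <- plasmovib:::.solve_system(sys, 2.3, list(src),
                                     method = "iterative", tol = 1e-10)
      expect_rel_equal(b$X, a$X, 1e-8)
      # matrix-free kernel application
      sysf <- response_system(st, pg, model, dense_limit = 1L)
      cc <- plasmovib:::.solve_system(sysf, 2.3, list(src),
                                      method = "iterative", tol = 1e-10)
      expect_rel_equal(cc$X, a$X, 1e-8)
    }
  }
})

test_that("the coupled charge-dipole solve equals a monolithic 4N x 4N oracle", {
  pg <- gold_material()
  st <- random_cluster(18, seed = 9)
  src <- uniform_field_source(st, c(0.3, 1, -0.7))
  sys <- response_system(st, pg, "wfqfmu")
  n <- sys$n
  kb <- as.matrix(sys$kbar)
  K <- sys$kernels
  zq <- z_q(ev_to_au(1.9 + 0i), pg)
  zm <- z_mu(1.9, pg$interband)
  D <- rbind(cbind(kb, matrix(0, n, 3 * n)),
             cbind(matrix(0, 3 * n, n), diag(3 * n)))
  Tfull <- rbind(cbind(K$Tqq, K$Tqmu), cbind(K$Tmuq, K$Tmumu))
  A <- D %*% Tfull - diag(c(rep(zq, n), rep(zm, 3 * n)))
  rhs <- D %*% c(-src$potential, as.vector(t(src$field)))
  w_oracle <- solve(A, rhs)
  got <- plasmovib:::.solve_system(sys, 1.9, list(src), method = "dense")
  expect_rel_equal(got$X[, 1], w_oracle, 1e-10)
})

test_that("an isolated atom decouples to mu = alpha_IB * E and q = 0", {
  pg <- gold_material()
  s1 <- nanostructure(matrix(0, 1, 3), "Au")
  s1$neighbor_pairs <- data.frame(i = integer(0), j = integer(0),
                                  r = numeric(0))
  sol <- suppressWarnings(
    solve_wfqfmu(s1, pg, 2.0, uniform_field_source(s1, c(0, 0, 1))))
  aib <- interband_alpha(pg$interband, 2.0)
  expect_equal(Mod(sol$charges), 0)
  expect_rel_equal(sol$dipoles[1, ], c(0, 0, aib), 1e-12)
})

test_that("polarizability is symmetric, isotropic for icosahedra, and decays", {
  p <- gold_drude()
  st <- random_cluster(20, seed = 4)
  a <- polarizability(st, p, 2.2, "wfq")
  expect_lt(max(Mod(a - t(a))) / max(Mod(a)), 1e-10)

  ico <- small_icosahedron(2)
  ai <- polarizability(ico, p, 2.5, "wfq")
  d <- Re(diag(ai))
  expect_lt(max(abs(d - mean(d))) / abs(mean(d)), 1e-4)
  expect_lt(max(Mod(ai - t(ai))) / max(Mod(ai)), 1e-6)

  # inertial limit: far above every resonance the response vanishes
  a_hi <- polarizability(ico, p, 60, "wfq")
  expect_lt(Mod(sum(diag(a_hi))), 1e-2 * Mod(sum(diag(ai))))

  # passivity across a scan
  for (w in seq(0.5, 8, by = 1.5)) {
    aw <- polarizability(ico, p, w, "wfq")
    expect_gte(Im(sum(diag(aw))), 0)
  }
})

test_that("the low-frequency solution approaches static charge equilibration", {
  p <- gold_drude()
  chain <- neighbor_graph(
    nanostructure(cbind(2.885 * (0:9), 0, 0)), 1.2 * 2.885)
  src <- uniform_field_source(chain, c(1, 0, 0))
  sol <- solve_wfq(chain, p, 1e-5, src)
  # independent constrained equilibration: Tqq q + V = lambda, sum q = 0
  kern <- build_interaction_kernels(chain, p$reg_width)
  n <- 10
  A <- rbind(cbind(kern$Tqq, rep(1, n)), c(rep(1, n), 0))
  rhs <- c(-Re(src$potential), 0)
  q_static <- solve(A, rhs)[1:n]
  expect_lt(max(Mod(sol$charges - q_static)) / max(abs(q_static)), 1e-4)
})

test_that("find_prf refines peaks, breaks ties low, and warns on edge cases", {
  # exact parabola: vertex recovered to 1e-9
  x0 <- 2.3456789
  g <- seq(2, 3, by = 0.05)
  sp <- list(grid = g, sigma = 5 - (g - x0)^2)
  expect_lt(abs(find_prf(sp) - x0), 1e-9)

  expect_warning(prf <- find_prf(list(grid = g, sigma = g)), "monotone")
  expect_equal(prf, max(g))

  # two equal maxima: the lower one wins
  g2 <- seq(1, 5, by = 0.5)
  s2 <- exp(-(g2 - 2)^2 / 0.1) + exp(-(g2 - 4)^2 / 0.1)
  expect_lt(find_prf(list(grid = g2, sigma = s2)), 3)

  expect_warning(find_prf(list(grid = g, sigma = rep(1, length(g)))),
                 "degenerate|flat")
  expect_error(find_prf(list(grid = c(1, 2), sigma = c(1, 2))), "3 points")
})

test_that("absorption spectra are non-negative and broaden with damping", {
  p <- gold_drude()
  ico <- small_icosahedron(2)
  sys <- response_system(ico, p, "wfq")
  grid <- seq(3.0, 7.5, by = 0.125)
  sp <- absorption_spectrum(ico, p, grid, "wfq", system = sys)
  expect_true(all(sp$sigma >= 0))
  expect_gt(sp$prf, min(grid))

  fwhm_of <- function(spec) {
    half <- max(spec$sigma) / 2
    above <- spec$grid[spec$sigma >= half]
    max(above) - min(above)
  }
  p_fast <- p
  p_fast$tau <- p$tau / 2          # doubled scattering rate
  sp2 <- absorption_spectrum(ico, p_fast, grid, "wfq")
  expect_gt(fwhm_of(sp2), fwhm_of(sp))

  expect_error(absorption_spectrum(ico, p, c(1, 2), "wfq"), "3 points")
  expect_error(absorption_spectrum(ico, p, c(2, 1, 3), "wfq"), "increasing")
})

test_that("scattered fields superpose linearly and match the dipole closed form", {
  sol0 <- structure(list(charges = c(0i), dipoles = NULL,
                         positions_au = matrix(0, 1, 3), widths = 0.5),
                    class = "response_solution")
  z <- scattered_field_at(sol0, matrix(c(5, 5, 5), 1, 3))
  expect_equal(Mod(z$potential), 0)
  expect_equal(max(Mod(z$field)), 0)

  dip <- structure(list(charges = c(0i), dipoles = matrix(c(0, 0, 1), 1, 3),
                        positions_au = matrix(0, 1, 3), widths = 0.5),
                   class = "response_solution")
  pt_au <- c(60, 0, 80)
  r <- sqrt(sum(pt_au^2)); u <- pt_au / r
  fld <- scattered_field_at(dip, matrix(au_to_ang(pt_au), 1, 3))
  mu <- c(0, 0, 1)
  expect_rel_equal(drop(fld$field),
                   (3 * sum(u * mu) * u - mu) / r^3, 1e-6)
  expect_rel_equal(fld$potential, sum(mu * u) / r^2, 1e-6)

  ch <- structure(list(charges = c(2 + 1i), dipoles = NULL,
                       positions_au = matrix(0, 1, 3), widths = 0.5),
                  class = "response_solution")
  both <- structure(list(charges = c(2 + 1i), dipoles = matrix(c(0, 0, 1), 1, 3),
                         positions_au = matrix(0, 1, 3), widths = 0.5),
                    class = "response_solution")
  pts <- matrix(au_to_ang(c(30, -10, 20)), 1, 3)
  fb <- scattered_field_at(both, pts)
  fc <- scattered_field_at(ch, pts)
  fd <- scattered_field_at(dip, pts)
  expect_rel_equal(fb$field, fc$field + fd$field, 1e-12)
  expect_rel_equal(fb$potential, fc$potential + fd$potential, 1e-12)
})

test_that("a compact Drude cluster resonates near the classical sphere limit", {
  p <- gold_drude()
  ico <- neighbor_graph(build_mackay_icosahedron(4), 1.2 * 2.885)
  wp <- sqrt(4 * pi * p$n_density)
  target <- au_to_ev(wp / sqrt(3))
  grid <- seq(0.5 * target, 1.5 * target, length.out = 45)
  sp <- absorption_spectrum(ico, p, grid, "wfq")
  expect_lt(abs(sp$prf - target) / target, 0.10)
})
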