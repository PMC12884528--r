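test_that("molecular sources reproduce bare multipole fields on the substrate", {
  pg <- gold_drude()
  sub1 <- nanostructure(matrix(0, 1, 3), "Au")
  mol <- make_fixture(1, 3)
  mol$charges <- c(0, 0, 0); mol$total_charge <- 0
  src0 <- molecular_sources(
    within_mol(mol, positions = mol$positions + 50), sub1, pg)
  expect_equal(max(Mod(src0$potential)), 0)
  expect_equal(max(Mod(src0$field)), 0)

  # single unit charge at 50 au: V = 1/50, |E| = 1/2500
  mq <- mol
  mq$positions <- rbind(au_to_ang(c(50, 0, 0)), au_to_ang(c(90, 0, 0)),
                        au_to_ang(c(50, 40, 0)))
  mq$charges <- c(1, 0, 0); mq$total_charge <- 1
  src <- molecular_sources(mq, sub1, pg)
  expect_lt(abs(Re(src$potential[1]) - 1 / 50), 1e-8)
  expect_lt(abs(sqrt(sum(Mod(src$field)^2)) - 1 / 2500), 1e-8)

  # neutral charge pair: far-field potential decays as r^-2
  md <- mol
  md$charges <- c(0.5, -0.5, 0); md$total_charge <- 0
  md$positions <- rbind(c(0, 0, 0.4), c(0, 0, -0.4), c(3, 0, 0))
  dists <- seq(50, 200, length.out = 8)
  v <- vapply(dists, function(r) {
    s1 <- nanostructure(matrix(au_to_ang(c(0, 0, r)), 1, 3), "Au")
    Mod(molecular_sources(md, s1, pg)$potential[1])
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(dists)))[2]
  expect_lt(abs(slope + 2) / 2, 0.02)
})

test_that("the induced external dipole obeys the uniform-probe identity and linearity", {
  pg <- gold_drude()
  st <- random_cluster(20, seed = 6)
  mol <- make_fixture(3, 6)
  mol$positions <- sweep(mol$positions, 2, c(0, 0, max(st$positions[, 3]) + 6), "+")
  sys <- response_system(st, pg, "wfq")

  ied <- induced_external_dipole(mol, st, pg, 1.8, "wfq", system = sys)
  sol <- ied$solution
  # projection of the defining identity on three uniform probes
  pos_au <- ang_to_au(st$positions)
  for (b in 1:3) {
    e <- c(0, 0, 0); e[b] <- 1
    proj <- sum(sol$charges * drop(pos_au %*% e))
    expect_lt(Mod(proj - ied$value[b]), 1e-10 * max(Mod(ied$value), 1))
  }

  mol2 <- mol
  mol2$charges <- 2 * mol$charges
  ied2 <- induced_external_dipole(mol2, st, pg, 1.8, "wfq", system = sys)
  expect_rel_equal(ied2$value, 2 * ied$value, 1e-10)

  none <- induced_external_dipole(mol, empty_substrate(), pg, 1.8, "wfq")
  expect_equal(max(Mod(none$value)), 0)
})

test_that("induced-dipole and transposed local-field routes are reciprocal", {
  pg <- gold_material()
  st <- random_cluster(24, seed = 3)
  x0 <- c(0, 0, max(st$positions[, 3]) + 5)
  dp <- c(0.3, -0.2, 0.5)
  mol <- point_dipole_molecule(x0, dp)
  for (model in c("wfq", "wfqfmu")) {
    sys <- response_system(st, pg, model)
    ied <- induced_external_dipole(mol, st, pg, 2.3, model, system = sys)
    lam <- local_field_tensor(st, pg, x0, 2.3, model, system = sys)
    pred <- drop(t(lam - diag(3)) %*% dp)
    expect_rel_equal(ied$value, pred, 1e-6)
  }
})

test_that("the local field tensor is the identity without (or far from) a substrate", {
  pg <- gold_drude()
  expect_equal(local_field_tensor(empty_substrate(), pg, c(0, 0, 0), 2),
               diag(3) + 0i)
  st <- small_icosahedron(1)
  lam_far <- local_field_tensor(st, pg, c(0, 0, au_to_ang(1e4)), 2.0)
  expect_lt(max(Mod(lam_far - diag(3))), 1e-6)

  # gradient consistency: scattered-field columns match finite differences
  # of the total potential (V_ext + V_scat)
  pt <- c(0, 0, max(st$positions[, 3]) + 4)
  sys <- response_system(st, pg, "wfq")
  lam <- local_field_tensor(st, pg, pt, 2.0, system = sys)
  h <- 1e-4
  for (b in 1:3) {
    e <- c(0, 0, 0); e[b] <- 1
    sol <- solve_wfq(st, pg, 2.0, uniform_field_source(st, e), system = sys)
    num <- vapply(1:3, function(a) {
      da <- c(0, 0, 0); da[a] <- au_to_ang(h)
      vp <- scattered_field_at(sol, matrix(pt + da, 1, 3))$potential -
        sum(ang_to_au(pt + da) * e)
      vm <- scattered_field_at(sol, matrix(pt - da, 1, 3))$potential -
        sum(ang_to_au(pt - da) * e)
      -(vp - vm) / (2 * h)
    }, complex(1))
    expect_rel_equal(num, lam[, b], 1e-6)
  }
})

test_that("SEIRA reduces to gas-phase IR without a substrate, analytically and numerically", {
  mol <- make_fixture(17, 8)
  rep0 <- seira_intensities(mol, empty_substrate(), gold_drude())
  expect_equal(rep0$ef, rep(1, length(mol$mode_freq)), tolerance = 1e-8)
  expect_equal(rep0$aef, 1, tolerance = 1e-10)
  expect_equal(rep0$mef, 1, tolerance = 1e-10)
  # the 3-point numerical derivative of the linearized dipole is exact:
  # enhanced intensities equal the analytic APT route to 1e-8
  expect_rel_equal(rep0$intensities, gas_ir_intensities(mol), 1e-8)
})

test_that("SEIRA enhancement responds to the substrate and half-step is stable", {
  pg <- gold_drude()
  st <- small_icosahedron(2)
  mol <- place(make_fixture(7, 8), st,
               placement(anchor_atom = 3, distance = 3.0, mode = "end_on"))
  sys <- response_system(st, pg, "wfq")
  rep1 <- seira_intensities(mol, st, pg, "wfq", system = sys)
  expect_gt(rep1$mef, 1)
  expect_gte(rep1$mef, rep1$aef)
  # numerical stability: halving the step changes intensities marginally
  rep_half <- seira_intensities(mol, st, pg, "wfq", step = 0.0005,
                                system = sys)
  expect_rel_equal(rep_half$intensities, rep1$intensities, 1e-4)
})

test_that("SERS equals gas-phase activities without a substrate and scales quartically", {
  mol <- make_fixture(5, 8)
  rep0 <- sers_intensities(mol, empty_substrate(), gold_drude(), 2.2)
  expect_equal(rep0$ef, rep(1, length(mol$mode_freq)), tolerance = 1e-12)

  # scalar-isotropy limit: EF_SERS = |lambda|^4 = EF_SEIRA^2
  lambda <- (1.7 - 0.6i) * diag(3)
  adv <- 0.8 * diag(3)
  g <- c(0.2, 0.2, 0.2)
  ef_sers <- raman_activity(dress_raman_tensor(lambda, adv)) /
    raman_activity(adv)
  ef_seira <- sum(Mod(dress_ir_gradient(lambda, g))^2) / sum(g^2)
  expect_lt(abs(ef_sers - ef_seira^2) / ef_sers, 1e-6)
  expect_lt(abs(ef_sers - Mod(1.7 - 0.6i)^4) / ef_sers, 1e-12)
})

test_that("enhancement factors are covariant under a global rotation", {
  pg <- gold_material()
  st <- random_cluster(16, seed = 8)
  mol <- make_fixture(9, 6)
  mol$positions <- sweep(mol$positions, 2,
                         c(0, 0, max(st$positions[, 3]) + 5), "+")
  r1 <- sers_intensities(mol, st, pg, 2.2, "wfqfmu")
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  st2 <- nanostructure(st$positions %*% t(R), st$labels,
                       st$material_id)
  st2 <- neighbor_graph(st2, 4.5)
  mol2 <- mol
  mol2$positions <- mol$positions %*% t(R)
  mol2$alpha_deriv <- lapply(mol$alpha_deriv, function(a) R %*% a %*% t(R))
  r2 <- sers_intensities(mol2, st2, pg, 2.2, "wfqfmu")
  expect_rel_equal(r2$ef, r1$ef, 1e-6)
})

test_that("enhancement reports implement the EF/AEF/MEF definitions", {
  r <- enhancement_report(c(2, 4), c(1, 1))
  expect_equal(r$ef, c(2, 4))
  expect_equal(r$aef, 3)
  expect_equal(r$mef, 4)
  expect_equal(r$i_mef, 2L)

  same <- enhancement_report(c(3, 5, 1), c(3, 5, 1))
  expect_equal(same$ef, rep(1, 3))
  expect_equal(same$aef, 1)
  expect_equal(same$mef, 1)

  # zero-vacuum modes excluded from EF and MEF but kept in the AEF sums
  z <- enhancement_report(c(2, 6), c(1, 0))
  expect_true(is.na(z$ef[2]))
  expect_equal(z$mef, 2)
  expect_equal(z$aef, 8)
  expect_error(enhancement_report(c(1, 1), c(0, 0)), "undefined AEF")
  expect_error(enhancement_report(c(1, 2, 3), c(1, 2)), "equal length")

  # MEF >= AEF for random positive spectra (weighted-mean convexity)
  set.seed(31)
  for (k in 1:30) {
    m <- sample(3:12, 1)
    iv <- runif(m, 0.1, 5); ie <- runif(m, 0.1, 50)
    rr <- enhancement_report(ie, iv)
    expect_gte(rr$mef, rr$aef)
  }

  # i-MEF tie-breaking toward the lowest frequency
  tie <- enhancement_report(c(4, 4, 1), c(1, 1, 1),
                            frequencies = c(900, 700, 500))
  expect_equal(tie$i_mef, 2L)
})

test_that("averaging reports is the arithmetic mean of intensities", {
  f <- c(500, 1000)
  a <- enhancement_report(c(0, 2), c(1, 1), frequencies = f)
  b <- enhancement_report(c(2, 0), c(1, 1), frequencies = f)
  expect_equal(average_spectra(list(a))$intensities, a$intensities)
  expect_equal(average_spectra(list(a, a))$intensities, a$intensities)
  m <- average_spectra(list(a, b))
  expect_equal(m$intensities, c(1, 1))
  expect_equal(m$aef, 1)
  cmix <- enhancement_report(c(1, 1, 1), c(1, 1, 1),
                             frequencies = c(1, 2, 3))
  expect_error(average_spectra(list(a, cmix)), "mismatch")
})

test_that("the most enhanced mode tracks the plasmon resonance on a graphene disk", {
  gd <- neighbor_graph(build_graphene_disk(4), 1.1 * 1.42)
  mol <- make_fixture(11, 8)
  sysg <- NULL
  grid <- seq(cm1_to_ev(500), cm1_to_ev(2200), length.out = 30)
  for (ef in c(0.015, 0.022, 0.030)) {
    p <- graphene_material(ef)
    sys <- response_system(gd, p, "wfq")
    sp <- suppressWarnings(absorption_spectrum(gd, p, grid, "wfq",
                                               system = sys))
    prf_cm1 <- ev_to_cm1(sp$prf)
    # the Fermi energies are chosen so the PRF falls inside the mode range
    expect_gt(prf_cm1, min(mol$mode_freq))
    expect_lt(prf_cm1, max(mol$mode_freq))
    pm <- place(mol, gd, placement(anchor_atom = 1, distance = 3.5,
                                   mode = "face_on"))
    rep <- seira_intensities(pm, gd, p, "wfq", system = sys)
    expect_lt(abs(rep$frequencies[rep$i_mef] - prf_cm1), 150)
  }
})
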