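test_that("the synthetic surrogate is deterministic and invariant-complete", {
  a <- make_fixture(7)
  b <- make_fixture(7)
  expect_identical(a, b)
  cdiff <- make_fixture(8)
  expect_false(identical(a$positions, cdiff$positions))

  expect_equal(sum(a$charges), 0)
  expect_true(all(abs(a$charges) <= 0.5))
  nm <- length(a$mode_freq)
  expect_equal(nm, 3 * 15 - 6)
  expect_lt(max(abs(crossprod(a$mode_vectors) - diag(nm))), 1e-8)
  expect_true(all(a$mode_freq > 0))
  expect_false(is.unsorted(a$mode_freq))
  expect_true(all(a$mode_freq >= 400 & a$mode_freq <= 1800))
  expect_true(all(a$positions[, 3] == 0))

  np <- make_fixture(3, 10, planar = FALSE)
  expect_gt(diff(range(np$positions[, 3])), 0)
  expect_error(make_fixture(1, 2), "at least 3")

  # generator leaves the session RNG untouched
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(make_fixture(5)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("IR intensities reproduce the diatomic closed form and zero APT limit", {
  m1 <- 12.011; m2 <- 15.999; q <- 0.31
  M <- m1 + m2
  lz <- c(sqrt(m2 / M), -sqrt(m1 / M))       # mass-weighted stretch
  modes <- matrix(0, 6, 1)
  modes[3, 1] <- lz[1]; modes[6, 1] <- lz[2]
  mol <- molecular_surrogate(
    positions = rbind(c(0, 0, 0), c(0, 0, 1.2)),
    masses = c(m1, m2), charges = c(q, -q),
    apt = list(q * diag(3), -q * diag(3)),
    mode_freq = 1500, mode_vectors = modes,
    alpha_deriv = list(diag(3)))
  got <- gas_ir_intensities(mol)
  mu_red <- m1 * m2 / M
  want <- plasmovib_constants()$kmmol_per_e2amu * q^2 / mu_red
  expect_equal(got, want, tolerance = 1e-12)

  zero <- mol
  zero$apt <- list(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(gas_ir_intensities(zero), 0)
})

test_that("Raman activities follow the rotational invariants", {
  mol <- make_fixture(2, 6)
  mol$alpha_deriv <- lapply(seq_along(mol$mode_freq), function(i) 0 * diag(3))
  expect_equal(gas_raman_activities(mol), rep(0, length(mol$mode_freq)))
  # isotropic derivative a*I: activity 45 a^2
  mol$alpha_deriv[[1]] <- 0.7 * diag(3)
  expect_equal(gas_raman_activities(mol)[1], 45 * 0.7^2, tolerance = 1e-12)

  mol2 <- make_fixture(4)
  expect_true(all(gas_raman_activities(mol2) >= 0))
})

test_that("gas-phase observables are invariant under rigid motions", {
  mol <- make_fixture(13)
  ir0 <- gas_ir_intensities(mol)
  ra0 <- gas_raman_activities(mol)
  set.seed(99)
  for (k in 1:3) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                   sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
    R <- Rz %*% Rx
    shift <- runif(3, -5, 5)
    rot <- mol
    rot$positions <- sweep(mol$positions %*% t(R), 2, shift, "+")
    rot$apt <- lapply(mol$apt, function(a) R %*% a %*% t(R))
    rot$alpha_deriv <- lapply(mol$alpha_deriv, function(a) R %*% a %*% t(R))
    rotv <- function(v) as.vector(t(matrix(v, ncol = 3, byrow = TRUE) %*% t(R)))
    rot$mode_vectors <- apply(mol$mode_vectors, 2, rotv)
    rot$mode_cart <- apply(mol$mode_cart, 2, rotv)
    expect_equal(gas_ir_intensities(rot), ir0, tolerance = 1e-10)
    expect_equal(gas_raman_activities(rot), ra0, tolerance = 1e-10)
  }
})

test_that("placement honors adsorption distances and detects clashes", {
  s <- small_icosahedron(2)
  mol <- make_fixture(7)
  for (d in c(3.0, 3.4)) {
    pm <- place(mol, s, placement(anchor_atom = 7, distance = d,
                                  mode = "end_on"))
    mind <- sqrt(min(plasmovib:::.cross_dist2(
      pm$positions[7, , drop = FALSE], s$positions)))
    expect_lt(abs(mind - d), 1e-6)
    allmin <- sqrt(min(plasmovib:::.cross_dist2(pm$positions, s$positions)))
    expect_gte(allmin, 0.9 * d - 1e-9)
  }

  gd <- neighbor_graph(build_graphene_disk(4), 1.1 * 1.42)
  ring_mol <- make_fixture(5, 9)       # pure ring, no substituents
  pm <- place(ring_mol, gd, placement(anchor_atom = 1, distance = 3.5,
                                      mode = "face_on"))
  expect_true(all(abs(pm$positions[, 3] - 3.5) <= 0.05))

  expect_error(place(mol, s, placement(anchor_atom = 7, distance = 1.2,
                                       mode = "end_on")),
               "steric|clash")
  expect_error(placement(rotation = diag(c(1, 1, -1))), "proper rotation")
})

test_that("the surrogate JSON schema round-trips", {
  mol <- make_fixture(21, 8)
  f <- tempfile(fileext = ".json")
  write_surrogate(mol, f)
  m2 <- read_surrogate(f)
  expect_equal(m2$positions, mol$positions, tolerance = 1e-12)
  expect_equal(m2$charges, mol$charges, tolerance = 1e-14)
  expect_equal(m2$mode_freq, mol$mode_freq, tolerance = 1e-12)
  expect_equal(m2$mode_vectors, mol$mode_vectors, tolerance = 1e-12)
  for (a in seq_along(mol$apt)) {
    expect_equal(m2$apt[[a]], mol$apt[[a]], tolerance = 1e-12)
  }
  expect_equal(gas_ir_intensities(m2), gas_ir_intensities(mol),
               tolerance = 1e-10)
})
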