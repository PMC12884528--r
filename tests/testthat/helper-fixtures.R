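# Shared fixtures: small structures, materials and random geometries used
# across the test files.  Everything is generated in code at test time.

gold_drude <- function() gold_material(interband = NULL)

small_icosahedron <- function(shells = 2) {
  neighbor_graph(build_mackay_icosahedron(shells), 1.2 * 2.885)
}

# random well-separated cluster with a connected neighbor graph
random_cluster <- function(n, seed, spread = 3, cutoff = 4.5) {
  set.seed(seed)
  pos <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
  repeat {
    close <- plasmovib:::.pair_list(pos, 2.0)
    if (nrow(close) == 0) break
    pos[close$i[1], ] <- pos[close$i[1], ] + stats::rnorm(3)
  }
  neighbor_graph(nanostructure(pos), cutoff)
}

empty_substrate <- function() {
  nanostructure(matrix(numeric(0), 0, 3), character(0))
}

# surrogate that is a single point transition dipole (dummy far atoms carry
# no charge); used by the reciprocity checks
point_dipole_molecule <- function(at, dp) {
  mol <- make_fixture(1, 3)
  mol$positions <- rbind(at, at + c(40, 0, 0), at + c(0, 40, 0))
  mol$charges <- c(0, 0, 0)
  mol$total_charge <- 0
  mol$dipoles <- rbind(dp, c(0, 0, 0), c(0, 0, 0))
  mol
}

within_mol <- function(mol, positions) {
  mol$positions <- positions
  mol
}

expect_rel_equal <- function(got, want, tol) {
  scale <- max(Mod(want))
  expect_lt(max(Mod(got - want)) / max(scale, 1e-300), tol)
}
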