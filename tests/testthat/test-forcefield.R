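# Analytic pair potentials, electrostatics solvers, and force consistency.

test_that("truncated LJ hits its textbook landmarks", {
  expect_equal(lj_pair_energy(1, eps = 1, shift = FALSE), 0)
  expect_equal(lj_pair_energy(2^(1 / 6), eps = 1, shift = FALSE), -1)
  expect_equal(lj_pair_energy(2^(1 / 6), eps = 0.37, shift = FALSE), -0.37)
  expect_equal(lj_pair_energy(2.6, eps = 1, rcut = 2.5), 0)
  expect_equal(lj_pair_energy(5, eps = 1, rcut = 2.5, shift = FALSE), 0)
  # energy-shifted form is continuous at the cutoff, unshifted is not
  expect_equal(lj_pair_energy(2.5 - 1e-9, eps = 1, rcut = 2.5), 0, tolerance = 1e-6)
  expect_lt(lj_pair_energy(2.5 - 1e-9, eps = 1, rcut = 2.5, shift = FALSE), -0.01)
})

test_that("FENE energy matches direct evaluation and diverges at R0", {
  expect_equal(fene_bond_energy(0), 0)
  # independent hand evaluation of -(k/2) R0^2 ln(1 - (r/R0)^2)
  expect_equal(fene_bond_energy(1.0, k = 30, R0 = 1.5),
               -0.5 * 30 * 1.5^2 * log(1 - (1 / 1.5)^2))
  expect_equal(fene_bond_energy(1.0), 19.8378, tolerance = 1e-4)
  r <- seq(0.1, 1.49, by = 0.01)
  expect_true(all(diff(fene_bond_energy(r)) > 0))
  expect_gt(fene_bond_energy(1.4999), 100)
  expect_error(fene_bond_energy(1.5), "broken")
})

test_that("Coulomb pair energies define the Bjerrum length", {
  two <- function(q2, r) tibble::tibble(x = c(0, r), y = 0, z = 0, charge = c(1, q2))
  expect_equal(coulomb_energy(two(-1, 1), "direct"), -1)
  expect_equal(coulomb_energy(two(1, 2), "direct"), 0.5)
  expect_equal(coulomb_energy(two(-1, 2), "direct", lB = 3), -1.5)
})

test_that("Ewald reproduces the rock-salt Madelung energy", {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  q <- ifelse(rowSums(g) %% 2 == 0, 1, -1)
  e_ion <- cpp_coulomb_ewald(g * 1.0, q, c(2, 2, 2), 1, 1e-6) / 8
  expect_equal(e_ion, -1.7475646 / 2, tolerance = 1e-5)
})

test_that("Ewald agrees with the direct-sum oracle within the accuracy target", {
  # zero-charge, zero-dipole cluster: the image-shell lattice sum is
  # absolutely convergent and boundary-condition independent
  cfg <- mirrored_neutral_charges(n_half = 20, seed = 3)
  e_dir <- cpp_coulomb_direct(cfg$pos, cfg$q, c(40, 40, 40), 1, 6L)
  e_ew <- cpp_coulomb_ewald(cfg$pos, cfg$q, c(40, 40, 40), 1, 1e-6)
  expect_lt(abs(e_ew - e_dir) / abs(e_dir), 1e-4)
  # and through the R interface on a second configuration
  cfg2 <- mirrored_neutral_charges(n_half = 30, seed = 8)
  fr <- tibble::tibble(x = cfg2$pos[, 1], y = cfg2$pos[, 2], z = cfg2$pos[, 3],
                       charge = cfg2$q)
  e_dir2 <- coulomb_energy(fr, "direct", box = c(40, 40, 40), nshells = 6)
  e_ew2 <- coulomb_energy(fr, "ewald", box = c(40, 40, 40))
  expect_lt(abs(e_ew2 - e_dir2) / abs(e_dir2), 1e-4)
})

test_that("Ewald refuses non-neutral systems", {
  fr <- tibble::tibble(x = c(1, 3), y = 1, z = 1, charge = c(1, 1))
  expect_error(coulomb_energy(fr, "ewald", box = c(6, 6, 6)), "neutral")
})

test_that("DSF forces approximate bare Coulomb at short range and damp beyond", {
  # isolated +/- pair beyond the WCA core: force on bead 1 points toward
  # bead 2 (+x) with magnitude ~ lB/r^2 at contact range
  pair_force <- function(r) {
    st <- structure(list(
      pos = rbind(c(20, 20, 20), c(20 + r, 20, 20)), vel = matrix(0, 2, 3),
      species = c(1L, 1L), charge = c(1, -1),
      bonds = matrix(integer(0), 0, 2), box = c(40, 40, 40), step = 0L
    ), class = "md_state")
    system_forces(st, force_field(coulomb_method = "dsf"))$force[1, 1]
  }
  expect_equal(pair_force(1.2), 1 / 1.2^2, tolerance = 0.03)
  expect_equal(pair_force(1.5), 1 / 1.5^2, tolerance = 0.04)
  # the damping is an explicit approximation: increasingly below bare
  rel <- vapply(c(2, 4, 6), function(r) pair_force(r) * r^2, 0)
  expect_true(all(diff(rel) < 0))
  expect_true(all(rel < 1 & rel > 0))
})

test_that("forces are the exact gradient of the potential", {
  st <- random_cluster_state()
  h <- 1e-6
  for (cm in c("ewald", "dsf", "none")) {
    ff <- force_field(eps_poly = 0.8, coulomb_method = cm,
                      coulomb_cutoff = if (cm == "ewald") 0 else 5.9)
    f0 <- system_forces(st, ff)
    for (probe in list(c(1, 1), c(4, 2), c(9, 3), c(17, 2))) {
      i <- probe[1]; d <- probe[2]
      stp <- st; stp$pos[i, d] <- stp$pos[i, d] + h
      stm <- st; stm$pos[i, d] <- stm$pos[i, d] - h
      fd <- -(system_forces(stp, ff)$e_pot - system_forces(stm, ff)$e_pot) / (2 * h)
      expect_equal(f0$force[i, d], fd, tolerance = 1e-4)
    }
    # Newton's third law: no net force without an external field
    expect_lt(max(abs(colSums(f0$force))), 1e-7)
  }
})

test_that("neighbor-list forces equal the all-pairs reference to machine precision", {
  sys <- tiny_gel_system(f = 0.1)
  st <- as_md_state(sys, seed = 2)
  for (cm in c("dsf", "none")) {
    ff <- force_field(eps_poly = 0.5, coulomb_method = cm)
    fn <- system_forces(st, ff, use_neighbor_lists = TRUE)
    fa <- system_forces(st, ff, use_neighbor_lists = FALSE)
    # identical pair sets, summed in a different order
    expect_lt(max(abs(fn$force - fa$force)), 1e-9)
    expect_equal(fn$e_pot, fa$e_pot, tolerance = 1e-12)
  }
})

test_that("species-resolved LJ applies the counterion parameters only to counterions", {
  # two network beads at r = 2: attractive well active (rcut 2.5)
  mk <- function(sp) structure(list(
    pos = rbind(c(10, 10, 10), c(12, 10, 10)), vel = matrix(0, 2, 3),
    species = sp, charge = c(0, 0), bonds = matrix(integer(0), 0, 2),
    box = c(20, 20, 20), step = 0L), class = "md_state")
  ff <- force_field(eps_poly = 1, lj_shift = FALSE, coulomb_method = "none")
  e_net <- system_forces(mk(c(0L, 0L)), ff)$e_lj
  expect_equal(e_net, lj_pair_energy(2, eps = 1, rcut = 2.5, shift = FALSE))
  # any pair involving a counterion is WCA-truncated: zero beyond 2^(1/6)
  expect_equal(system_forces(mk(c(0L, 1L)), ff)$e_lj, 0)
  expect_equal(system_forces(mk(c(1L, 1L)), ff)$e_lj, 0)
})

test_that("overlapping beads are an error unless capped relaxation is enabled", {
  st <- random_cluster_state()
  st$pos[2, ] <- st$pos[1, ]
  ff <- force_field(coulomb_method = "none")
  expect_error(system_forces(st, ff), "overlap")
  stc <- run_md(st, ff, nsteps = 5, seed = 1, cap = 100)
  expect_true(all(is.finite(stc$pos)))
})
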