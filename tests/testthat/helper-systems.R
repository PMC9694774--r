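# Shared fixtures built in code.

# a free-particle (ideal-gas) state: no bonds, no charges, negligible LJ
ideal_gas_state <- function(n = 200, box = c(50, 50, 50), seed = 1) {
  pos <- withr::with_seed(seed, matrix(runif(3 * n, 0, box[1]), n, 3))
  structure(list(pos = pos, vel = matrix(0, n, 3),
                 species = rep(1L, n), charge = rep(0, n),
                 bonds = matrix(integer(0), 0, 2), box = box, step = 0L),
            class = "md_state")
}

ideal_gas_ff <- function(...) {
  force_field(eps_ci = 1e-9, rcut_ci = 0.01, coulomb_method = "none", ...)
}

# a small random cluster with two FENE bonds and +-1 charges, for force checks
random_cluster_state <- function(n = 24, box = c(12, 12, 12), seed = 7) {
  pos <- withr::with_seed(seed, matrix(runif(3 * n, 2, box[1] - 2), n, 3))
  pos[2, ] <- pos[1, ] + c(0.9, 0, 0)
  pos[4, ] <- pos[3, ] + c(0, 0.8, 0.3)
  structure(list(
    pos = pos, vel = matrix(0, n, 3),
    species = rep(c(0L, 1L), length.out = n),
    charge = rep(c(1, -1), length.out = n),
    bonds = matrix(c(1L, 2L, 3L, 4L), 2, 2, byrow = TRUE),
    box = box, step = 0L
  ), class = "md_state")
}

# compact neutral cluster plus a shifted anti-copy: net charge and dipole
# are both exactly zero, so the periodic lattice sum is absolutely
# convergent and boundary-condition independent (tinfoil == vacuum)
mirrored_neutral_charges <- function(n_half = 10, box = c(40, 40, 40), seed = 3) {
  stopifnot(n_half %% 2 == 0)
  withr::with_seed(seed, {
    p1 <- matrix(rnorm(3 * n_half, sd = 1.3), n_half, 3) +
      matrix(box / 2, n_half, 3, byrow = TRUE)
    q1 <- rep(c(1, -1), n_half / 2)
    list(pos = rbind(p1, sweep(p1, 2, c(2.7, 1.9, 2.3), "+")), q = c(q1, -q1))
  })
}

# small built microgel system shared across io / simulator tests
tiny_gel_system <- function(f = 0.1, M = 2, nz = 6, seed = 5) {
  topo <- build_diamond_template(2, 2, nz, M = M)
  topo <- inscribe_cylinder(topo)
  if (f > 0) topo <- assign_charges(topo, f, seed = seed)
  make_system(topo, seed = seed + 1L)
}

rotation_matrix <- function(axis = c(1, 2, 1), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c) * (K %*% K)
}
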