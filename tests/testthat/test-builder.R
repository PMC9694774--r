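# Diamond-lattice template construction, cylinder inscription, charge
# assignment and system assembly.

test_that("diamond cell bookkeeping matches an independent enumeration", {
  # brute-force oracle: place the 8 conventional-cell basis points, count
  # nearest-neighbour pairs under periodic wrapping of one cell
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0),
                 c(.25, .25, .25), c(.25, .75, .75), c(.75, .25, .75), c(.75, .75, .25))
  nn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    d <- basis[i, ] - basis[j, ]
    d <- d - round(d)                     # periodic cell
    # each A-B nearest-neighbour pair sits at sqrt(3)/4 cell edges
    if (abs(sqrt(sum(d^2)) - sqrt(3) / 4) < 1e-9) nn <- nn + 1
  }
  n_bonds_oracle <- nn / 2
  expect_equal(n_bonds_oracle, 16)
  for (M in c(1, 10, 20)) {
    expect_equal(crosslink_fraction_limit(M), 8 / (8 + n_bonds_oracle * M))
    expect_equal(crosslink_fraction_limit(M), 1 / (2 * M + 1))
  }
})

test_that("every subchain carries exactly M beads and M+1 bonds", {
  M <- 4
  topo <- build_diamond_template(2, 2, 3, M = M)
  n_cross <- sum(topo$beads$role == "crosslink")
  n_chain <- sum(topo$beads$role == "chain")
  expect_equal(n_chain %% M, 0)
  n_sub <- n_chain / M
  expect_equal(nrow(topo$bonds), (M + 1) * n_sub)
  # bond lengths all equal the configured spacing
  d <- with(topo, cbind(beads$x[bonds$i] - beads$x[bonds$j],
                        beads$y[bonds$i] - beads$y[bonds$j],
                        beads$z[bonds$i] - beads$z[bonds$j]))
  expect_equal(sqrt(rowSums(d^2)), rep(0.97, nrow(d)), tolerance = 1e-10)
  # degree invariants: cross-links at most tetrafunctional, chain beads <= 2
  deg <- tabulate(c(topo$bonds$i, topo$bonds$j), nrow(topo$beads))
  expect_true(all(deg[topo$beads$role == "crosslink"] <= 4))
  expect_true(all(deg[topo$beads$role == "chain"] <= 2))
  expect_true(any(deg == 4))
})

test_that("cross-link fraction exceeds the bulk limit and converges to it", {
  M <- 3
  lim <- crosslink_fraction_limit(M)
  f1 <- crosslink_fraction(build_diamond_template(1, 1, 2, M = M))
  f2 <- crosslink_fraction(build_diamond_template(2, 2, 4, M = M))
  f3 <- crosslink_fraction(build_diamond_template(4, 4, 8, M = M))
  expect_true(f1 > f2 && f2 > f3)
  expect_true(f3 > lim)
  expect_lt(f3 - lim, f1 - lim)
  # boundary correction scales like the surface-to-volume ratio
  expect_lt((f3 - lim) / (f1 - lim), 0.45)
})

test_that("builder rejects degenerate inputs", {
  expect_error(build_diamond_template(1, 1, 1, M = 0), "M")
  expect_error(build_diamond_template(1, 1, 1, M = 3, bond_spacing = 1.5), "FENE")
  expect_error(build_diamond_template(1, 1, 1, M = 3, bond_spacing = 0), "FENE")
})

test_that("template is elongated along z in proportion to the cell counts", {
  topo <- build_diamond_template(2, 2, 20, M = 2)
  ext <- vapply(topo$beads[, c("x", "y", "z")], function(v) diff(range(v)), 0)
  expect_gt(ext[[3]] / ext[[1]], 8)       # 20 vs 2 cells, boundary-corrected
  expect_equal(ext[[1]], ext[[2]], tolerance = 1e-12)
})

test_that("inscribing with a generous radius keeps every bead", {
  topo <- build_diamond_template(2, 2, 4, M = 2)
  big <- inscribe_cylinder(topo, radius = 100)
  expect_equal(nrow(big$beads), nrow(topo$beads))
  expect_equal(big$beads[, c("x", "y", "z")], topo$beads[, c("x", "y", "z")])
})

test_that("max-fit inscription realizes the configured aspect ratio", {
  # L0 = (nz-1) a and the max-fit radius is (nx/2) a, so A0 = (nz-1)/nx
  topo <- inscribe_cylinder(build_diamond_template(2, 2, 21, M = 2))
  expect_equal(topo$A0, 10, tolerance = 1e-10)
  expect_equal(topo$L0 / (2 * topo$R0_cyl), 10, tolerance = 1e-10)
  # the axis chain survives in axial order
  expect_true(all(diff(topo$beads$z[topo$axis_chain]) > 0))
  az <- topo$beads[topo$axis_chain, ]
  expect_true(all(abs(az$x - az$x[1]) < 1e-9))
  expect_true(all(abs(az$y - az$y[1]) < 1e-9))
})

test_that("retained bead fraction tracks the cylinder cross-section area", {
  topo <- build_diamond_template(4, 4, 6, M = 2)
  r <- topo$cell_edge            # half of the max-fit radius
  cut <- inscribe_cylinder(topo, radius = r)
  retained <- nrow(cut$beads) / nrow(topo$beads)
  # Monte-Carlo area integration oracle over the square cross-section
  a <- topo$cell_edge
  pts <- withr::with_seed(1, matrix(runif(2 * 20000, 0, 4 * a), ncol = 2))
  area_frac <- mean((pts[, 1] - 2 * a)^2 + (pts[, 2] - 2 * a)^2 <= r^2)
  expect_equal(retained, area_frac, tolerance = 0.12)
})

test_that("inscription drops disconnected fragments", {
  topo <- inscribe_cylinder(build_diamond_template(2, 2, 8, M = 3))
  g <- igraph::graph_from_edgelist(as.matrix(topo$bonds), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("charge assignment is exact, seeded, and validated", {
  topo <- inscribe_cylinder(build_diamond_template(2, 2, 4, M = 2))
  n <- nrow(topo$beads)
  expect_equal(sum(assign_charges(topo, 0, seed = 1)$beads$charge), 0)
  t1 <- assign_charges(topo, 0.1, seed = 1)
  expect_equal(sum(t1$beads$charge), round(0.1 * n))
  expect_true(all(t1$beads$charge %in% c(0, 1)))
  t1b <- assign_charges(topo, 0.1, seed = 1)
  t2 <- assign_charges(topo, 0.1, seed = 2)
  expect_identical(t1$beads$charge, t1b$beads$charge)
  expect_equal(sum(t2$beads$charge), sum(t1$beads$charge))
  expect_false(identical(which(t1$beads$charge > 0), which(t2$beads$charge > 0)))
  expect_error(assign_charges(topo, 1.2), "fraction")
})

test_that("assembled systems are exactly neutral and reproducible", {
  sys <- tiny_gel_system(f = 0.1)
  expect_equal(sum(sys$topology$beads$charge) + sum(sys$counterions$charge), 0)
  expect_equal(nrow(sys$counterions), sum(sys$topology$beads$charge > 0))
  sys2 <- tiny_gel_system(f = 0.1)
  expect_identical(sys$counterions, sys2$counterions)
  # counterions avoid the network core
  d <- cpp_min_dist_to_set(as.matrix(sys$counterions[, c("x", "y", "z")]),
                           as.matrix(sys$topology$beads[, c("x", "y", "z")]),
                           sys$box)
  expect_true(all(d >= 0.9))
  # neutral gel gets no counterions
  sys0 <- tiny_gel_system(f = 0)
  expect_equal(nrow(sys0$counterions), 0)
})

test_that("a box smaller than the network is rejected", {
  topo <- inscribe_cylinder(build_diamond_template(2, 2, 4, M = 2))
  expect_error(make_system(topo, box = c(5, 5, 5)), "bounding box")
})
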