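# Shape and charge measurements against closed forms and invariances.

test_that("contour length sums consecutive cross-link distances", {
  z <- seq(0, 20, by = 2)
  fr <- tibble::tibble(x = 0, y = 0, z = z)
  expect_equal(contour_length(fr, seq_along(z)), 20)
  # a kinked chain is never shorter than its end-to-end distance
  set.seed(1)
  kink <- tibble::tibble(x = rnorm(11), y = rnorm(11), z = z)
  ee <- sqrt(sum((kink[11, ] - kink[1, ])^2))
  expect_gte(contour_length(kink, 1:11), ee)
})

test_that("slab thickness recovers a uniform cylinder diameter", {
  cyl <- uniform_cylinder_cloud(1e5, L = 60, R = 5, seed = 11)
  expect_equal(gel_thickness(cyl, L = 60), 10, tolerance = 0.02)
  expect_equal(gel_thickness(cyl), 10, tolerance = 0.02)  # moment-equivalent L
  # percentile estimator close for a sharp-edged cylinder
  expect_equal(gel_thickness(cyl, L = 60, method = "percentile"), 10,
               tolerance = 0.05)
  # beads on the axis have zero thickness
  rod <- tibble::tibble(x = 0, y = 0, z = seq(0, 30, 0.1))
  expect_equal(gel_thickness(rod, L = 30), 0, tolerance = 1e-9)
})

test_that("gyration eigenvalues match closed forms and are rigid-motion invariant", {
  sph <- uniform_sphere_cloud(1e5, R = 4, seed = 12)
  expect_equal(gyration_eigenvalues(sph), rep(16 / 5, 3), tolerance = 0.02)
  cyl <- uniform_cylinder_cloud(5e4, L = 40, R = 4, seed = 13)
  ev <- gyration_eigenvalues(cyl)
  shifted <- dplyr::mutate(cyl, x = x + 17, y = y - 4, z = z + 100)
  expect_equal(gyration_eigenvalues(shifted), ev, tolerance = 1e-12)
  expect_error(gyration_eigenvalues(cyl[1:2, ]), "at least 3")
})

test_that("eigenvalue aspect estimator is calibrated to uniform cylinders", {
  cyl <- uniform_cylinder_cloud(1e5, L = 80, R = 4, seed = 14)
  est <- aspect_from_eigenvalues(cyl)
  expect_equal(est$aspect_eigen, 10, tolerance = 0.02)
  # agrees with the exact closed form when fed exact moments
  exact <- aspect_from_eigenvalues(80^2 / 12, 4^2 / 4)
  expect_equal(exact$aspect_eigen, 10)
  expect_equal(exact$eigen_ratio, (80^2 / 12) / 4)
  # sphere: A-hat = sqrt(3)/2, raw ratio 1
  sph_est <- aspect_from_eigenvalues(2, 2)
  expect_equal(sph_est$aspect_eigen, sqrt(12) / 4)
  expect_equal(sph_est$eigen_ratio, 1)
  # dimensionless: invariant under coordinate scaling
  expect_equal(aspect_from_eigenvalues(3.7 * 80^2 / 12, 3.7 * 4)$aspect_eigen, 10)
})

test_that("asphericity spans sphere to rod with the documented thresholds", {
  expect_equal(asphericity(c(2, 2, 2)), 0)
  expect_equal(asphericity(c(5, 0, 0)), 1)
  # uniform cylinder at A = 4: delta ~ 0.759, above the 0.6 threshold
  l <- c(16 / 3, 1 / 4, 1 / 4)
  expect_equal(asphericity(l), 0.75938776, tolerance = 1e-6)
  expect_gt(asphericity(l), 0.6)
  expect_lt(asphericity(c(1.01, 1, 0.99)), 0.1)
  expect_error(asphericity(c(0, 0, 0)), "eigenvalues")
})

test_that("counterion localization counts contact fractions", {
  topo <- inscribe_cylinder(build_diamond_template(2, 2, 4, M = 2))
  net <- ideal_microgel_frame(topo)
  make_ci <- function(xyz) {
    tibble::tibble(id = nrow(net) + seq_len(nrow(xyz)), species = "counterion",
                   charge = -1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  on_beads <- make_ci(as.matrix(net[1:20, c("x", "y", "z")]) + 0.1)
  far <- make_ci(as.matrix(net[1:20, c("x", "y", "z")]) + 500)
  fr1 <- new_gel_frame(dplyr::bind_rows(net, on_beads))
  expect_equal(counterion_localization(fr1), 1)
  fr0 <- new_gel_frame(dplyr::bind_rows(net, far))
  expect_equal(counterion_localization(fr0), 0)
  frh <- new_gel_frame(dplyr::bind_rows(net, on_beads[1:10, ], far[1:10, ]))
  expect_equal(counterion_localization(frh), 0.5)
  expect_equal(counterion_localization(frh, criterion = "envelope"), 0.5,
               tolerance = 0.101)
  expect_error(counterion_localization(net), "no counterions")
})

test_that("net charge fraction is f(1 - beta)", {
  expect_equal(net_charge_fraction(0.10, 0.82), 0.018)
  expect_equal(net_charge_fraction(0, 0.5), 0)
  expect_equal(net_charge_fraction(0.4, 1), 0)
  expect_error(net_charge_fraction(0.2, 1.4))
})

test_that("radial profiles recover a uniform cylinder's volume fraction", {
  n <- 2e5; L <- 60; R <- 6
  cyl <- uniform_cylinder_cloud(n, L = L, R = R, seed = 15)
  phi0 <- n * (pi / 6) / (pi * R^2 * L)
  prof <- radial_profiles(cyl, L = L, bin_width = 1)
  interior <- prof$r < R - 1
  expect_equal(prof$phi_polymer[interior], rep(phi0, sum(interior)),
               tolerance = 0.05)
  expect_true(all(prof$phi_polymer[prof$r > R + 1] == 0))
  # no charged beads / counterions: identically zero profiles
  expect_true(all(prof$phi_charged == 0))
  expect_true(all(prof$phi_counterion == 0))
})

test_that("profiles conserve mass and are idempotent under frame duplication", {
  cyl <- uniform_cylinder_cloud(3e4, L = 50, R = 5, seed = 16)
  prof <- radial_profiles(cyl, L = 50, bin_width = 0.5)
  # integrate phi * bin volume back to a bead count over inner segments
  edges <- seq(0, max(prof$r) + 0.25, by = 0.5)
  annvol <- pi * (edges[-1]^2 - edges[-length(edges)]^2) * attr(prof, "slab_fraction") *
    50 * attr(prof, "n_segments")
  mass <- sum(prof$phi_polymer * annvol) / (pi / 6)
  inner <- sum(cyl$z >= -15 & cyl$z < 15)  # 3 inner segments of 10 each
  expect_equal(mass, inner, tolerance = 0.001)
  prof2 <- radial_profiles(list(cyl, cyl), L = 50, bin_width = 0.5)
  expect_equal(prof2$phi_polymer, prof$phi_polymer, tolerance = 1e-12)
  expect_error(radial_profiles(cyl, L = 50, slab_fraction = 0.5), "inner segment")
})

test_that("unwrapping restores bonded distances across periodic images", {
  sys <- tiny_gel_system(f = 0)
  fr <- ideal_microgel_frame(sys)
  box <- sys$box
  wrapped <- dplyr::mutate(fr,
    x = x - box[1] * floor(x / box[1] + 0.3),
    z = z - box[3] * floor(z / box[3] + 0.45))
  uw <- unwrap_frame(wrapped, sys$topology$bonds, box)
  b <- sys$topology$bonds
  d <- cbind(uw$x[b$i] - uw$x[b$j], uw$y[b$i] - uw$y[b$j], uw$z[b$i] - uw$z[b$j])
  expect_true(all(sqrt(rowSums(d^2)) < 1.5))
  expect_equal(sqrt(rowSums(d^2)), rep(0.97, nrow(d)), tolerance = 1e-9)
})
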