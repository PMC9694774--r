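# Langevin/Brownian integration: thermostat targets, determinism, and the
# staged solvent-quality protocol.

test_that("free particles equilibrate to the Maxwell-Boltzmann velocity variance", {
  st <- ideal_gas_state(n = 300)
  r <- run_md(st, ideal_gas_ff(), nsteps = 3000, seed = 3)
  v <- as.vector(r$vel)
  # var(v) -> kT/m = 1; SE of the sample variance of 900 quasi-independent
  # components is sqrt(2/n)
  se <- sqrt(2 / length(v))
  expect_lt(abs(var(v) - 1), 3 * se)
  expect_lt(abs(kinetic_temperature(r) - 1), 3 * se)
})

test_that("a harmonically tethered bead samples the Boltzmann position variance", {
  st <- ideal_gas_state(n = 150)
  k_trap <- 2
  r <- run_md(st, ideal_gas_ff(), nsteps = 6000, seed = 4,
              tether_k = k_trap, frame_every = 50)
  late <- r$frames[60:120]
  dev <- vapply(late, function(fr) as.vector(fr - st$pos), numeric(3 * 150))
  v <- var(as.vector(dev))
  expect_equal(v, 1 / k_trap, tolerance = 0.05)
})

test_that("dynamics are a pure function of the seed", {
  st <- ideal_gas_state(n = 50)
  a <- run_md(st, ideal_gas_ff(), nsteps = 200, seed = 11)
  b <- run_md(st, ideal_gas_ff(), nsteps = 200, seed = 11)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  c <- run_md(st, ideal_gas_ff(), nsteps = 200, seed = 12)
  expect_false(identical(a$pos, c$pos))
})

test_that("zero-temperature overdamped dynamics never raise the potential energy", {
  sys <- tiny_gel_system(f = 0)
  # overdamped stability requires a small step against the bond curvature,
  # which grows as the network densifies during the descent
  ff <- force_field(eps_poly = 0.3, kT = 1e-12, dt = 5e-4, coulomb_method = "none")
  st <- as_md_state(sys, ff, seed = 6)
  st$vel[] <- 0
  r <- run_md(st, ff, nsteps = 1500, seed = 6, integrator = "brownian",
              log_every = 75)
  epot <- r$log$e_lj + r$log$e_fene
  expect_true(all(diff(epot) <= 1e-6))
  expect_lt(epot[length(epot)], epot[1])
})

test_that("an overstretched FENE bond aborts with a diagnostic", {
  st <- random_cluster_state()
  st$pos[2, ] <- st$pos[1, ] + c(1.62, 0, 0)
  expect_error(run_md(st, force_field(coulomb_method = "none"), nsteps = 1, seed = 1),
               "FENE bond .* broken")
})

test_that("langevin_step advances exactly one step", {
  st <- ideal_gas_state(n = 20)
  r <- langevin_step(st, ideal_gas_ff(), seed = 2)
  expect_equal(r$step, 1L)
  expect_false(identical(r$pos, st$pos))
})

test_that("the protocol tags one frame set per scheduled solvent quality", {
  sys <- tiny_gel_system(f = 0)
  sch <- default_schedule(eps = c(0.01, 0.3, 0.6, 1.0, 1.4),
                          equil_steps = 200, stats_steps = 200)
  traj <- run_protocol(sys, force_field(), sch, seed = 1, frame_every = 100)
  expect_length(traj$stages, 5)
  expect_true(all(lengths(traj$stages) == 2))
  fr <- stage_frames(traj, 3)
  expect_equal(attr(fr[[1]], "eps"), 0.6)
  expect_s3_class(fr[[1]], "gel_frame")
})

test_that("protocol reruns are bit-identical and schedule contracts are enforced", {
  sys <- tiny_gel_system(f = 0)
  sch <- default_schedule(eps = c(0.01, 0.7), equil_steps = 150, stats_steps = 150)
  t1 <- run_protocol(sys, force_field(), sch, seed = 9, frame_every = 50)
  t2 <- run_protocol(sys, force_field(), sch, seed = 9, frame_every = 50)
  expect_identical(t1$stages, t2$stages)
  bad <- default_schedule(eps = c(0.5, 0.01), equil_steps = 150, stats_steps = 150)
  expect_error(run_protocol(sys, force_field(), bad, seed = 1), "non-decreasing")
  uneq <- tibble::tibble(eps = c(0.01, 0.5), equil_steps = c(100L, 300L),
                         stats_steps = c(100L, 100L))
  expect_error(run_protocol(sys, force_field(), uneq, seed = 1), "duration")
  hot <- default_schedule(eps = c(0.01, 1.6), equil_steps = 150, stats_steps = 150)
  expect_warning(run_protocol(sys, force_field(), hot, seed = 1, frame_every = 100),
                 "1.4")
})

test_that("bead-bead cohesion deepens as the solvent quality declines", {
  sys <- tiny_gel_system(f = 0, M = 3, nz = 5)
  sch <- default_schedule(eps = c(0.01, 0.7, 1.4),
                          equil_steps = 1500, stats_steps = 500)
  traj <- run_protocol(sys, force_field(), sch, seed = 4, frame_every = 250)
  elj <- tapply(traj$log$e_lj, traj$log$eps, mean)
  expect_true(all(diff(elj[order(as.numeric(names(elj)))]) < 0))
})
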