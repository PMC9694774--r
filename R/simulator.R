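# NVT Langevin dynamics driver and the solvent-quality sweep protocol.

#' Create an integrable dynamics state from a system
#'
#' Packs positions, Maxwell-Boltzmann velocities, charges, species tags and
#' bonds of a [make_system()] result into an `md_state` ready for
#' [run_md()].
#'
#' @param system A `gel_system`.
#' @param ff A [force_field()] (sets kT and mass for the velocity draw).
#' @param seed Integer seed for the initial velocities.
#' @return An `md_state` object.
#' @export
as_md_state <- function(system, ff = force_field(), seed = 1L) {
  stopifnot(inherits(system, "gel_system"))
  b <- system$topology$beads
  ci <- system$counterions
  n <- nrow(b) + nrow(ci)
  pos <- rbind(cbind(b$x, b$y, b$z), cbind(ci$x, ci$y, ci$z))
  vel <- withr::with_seed(seed,
    matrix(rnorm(3 * n, sd = sqrt(ff$kT / ff$mass)), n, 3))
  structure(list(
    pos = pos, vel = vel,
    species = c(rep(0L, nrow(b)), rep(1L, nrow(ci))),
    charge = c(b$charge, ci$charge),
    bonds = as.matrix(system$topology$bonds),
    box = system$box,
    topology = system$topology,
    step = 0L
  ), class = "md_state")
}

#' @export
print.md_state <- function(x, ...) {
  cat("<md_state> ", nrow(x$pos), " beads (",
      sum(x$species == 1L), " counterions), step ", x$step, "\n", sep = "")
  invisible(x)
}

#' Run NVT Langevin (or overdamped Brownian) dynamics
#'
#' Integrates the equations of motion with the BAOAB splitting of Langevin
#' dynamics (velocity Verlet with friction and thermal noise at
#' temperature kT), or with the inertialess overdamped Brownian scheme.
#' The trajectory is a pure function of `(state, ff, nsteps, seed, ...)`.
#'
#' @param state An `md_state`.
#' @param ff A [force_field()]; `ff$eps_poly` may be overridden per call
#'   with `eps`.
#' @param nsteps Number of time steps.
#' @param seed Integer seed for the thermal noise.
#' @param eps Optional solvent-quality parameter overriding
#'   `ff$eps_poly`.
#' @param frame_every Record a coordinate frame every this many steps
#'   (0 = none).
#' @param log_every Record energies every this many steps (0 = none).
#' @param integrator `"langevin"` (BAOAB, with inertia; default) or
#'   `"brownian"` (overdamped, no inertia). The explicit overdamped step is
#'   only stable for `dt < 2 gamma / U''`; with the stiff FENE + LJ bond
#'   curvature this means a time step several times smaller than the
#'   Langevin default (0.001 tau is safe at eps up to 1.4).
#' @param tether_k Optional harmonic tether (kBT/sigma^2) anchoring every
#'   bead to its position at entry — used for constrained relaxation and
#'   thermostat validation.
#' @param cap Optional pair-force cap enabling the overlap-tolerant
#'   relaxation mode.
#' @return The advanced `md_state`, with recorded `frames` (list of
#'   coordinate matrices), `frame_steps`, and an energy `log` tibble.
#' @export
run_md <- function(state, ff = force_field(), nsteps, seed = 1L, eps = NULL,
                   frame_every = 0L, log_every = 0L,
                   integrator = c("langevin", "brownian"),
                   tether_k = 0, cap = NULL) {
  stopifnot(inherits(state, "md_state"), nsteps >= 0)
  integrator <- match.arg(integrator)
  ffl <- .ff_cpp(ff, eps_poly = eps, cap = cap)
  res <- cpp_run_langevin(state$pos, state$vel, state$species, state$charge,
                          state$bonds, state$box, ffl,
                          as.integer(nsteps), ff$dt, ff$gamma, ff$kT, ff$mass,
                          as.integer(seed), as.integer(frame_every),
                          as.integer(log_every), tether_k,
                          if (integrator == "langevin") 0L else 1L)
  state$pos <- res$pos
  state$vel <- res$vel
  state$step <- state$step + as.integer(nsteps)
  state$frames <- res$frames
  state$frame_steps <- res$frame_steps
  state$log <- as_tibble(res$log)
  state
}

#' @rdname run_md
#' @export
langevin_step <- function(state, ff = force_field(), seed = 1L, ...) {
  run_md(state, ff, nsteps = 1L, seed = seed, ...)
}

#' Instantaneous kinetic temperature
#'
#' `T = sum(m v^2) / (3 N)` in reduced units (kB = 1).
#'
#' @param state An `md_state`.
#' @param mass Bead mass.
#' @return Temperature in kBT units.
#' @export
kinetic_temperature <- function(state, mass = 1) {
  sum(mass * state$vel^2) / (3 * nrow(state$vel))
}

#' Net force and potential energy of a state
#'
#' Evaluates the full force field (species-resolved LJ, FENE bonds,
#' Coulomb) on the current coordinates. `use_neighbor_lists = FALSE`
#' switches to the all-pairs reference evaluation, which must agree to
#' machine precision.
#'
#' @param state An `md_state`.
#' @param ff A [force_field()].
#' @param eps Optional override of `ff$eps_poly`.
#' @param use_neighbor_lists Use cell/Verlet neighbor lists?
#' @return List with `force` (n x 3), `e_lj`, `e_fene`, `e_coul`, `e_pot`.
#' @export
system_forces <- function(state, ff = force_field(), eps = NULL,
                          use_neighbor_lists = TRUE) {
  cpp_forces(state$pos, state$species, state$charge, state$bonds, state$box,
             .ff_cpp(ff, eps_poly = eps), use_neighbor_lists)
}

#' Solvent-quality sweep protocol
#'
#' Runs the staged annealing protocol: the system is first equilibrated at
#' the initial (good-solvent) attraction strength, then the solvent
#' quality is worsened step by step; at every stage the system is
#' equilibrated for `equil_steps` and statistics frames are then recorded
#' over `stats_steps`. By default every stage must have the same total
#' duration (equilibration + statistics), mirroring the constant
#' time-per-state convention of the annealing experiment.
#'
#' @param system A `gel_system`.
#' @param ff A [force_field()].
#' @param schedule A data frame with columns `eps`, `equil_steps`,
#'   `stats_steps`; `eps` must be non-decreasing and start in the
#'   good-solvent regime. See [default_schedule()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param frame_every Statistics-frame cadence in steps.
#' @param integrator Passed to [run_md()].
#' @param equal_duration Enforce identical per-stage duration?
#' @param ramp_frac Fraction of each stage's equilibration spent ramping
#'   the attraction smoothly (geometrically) from the previous stage's
#'   value. At good-solvent conditions the monomer repulsive core is weak
#'   (it scales with the same eps as the attraction) and beads
#'   interpenetrate, so an instantaneous quench multiplies overlap forces
#'   by the eps ratio and can snap FENE bonds; a gradual quench lets
#'   overlaps relax. 0 disables ramping.
#' @return A `gel_trajectory`: per-stage frame sets (each frame an
#'   unwrapped coordinate matrix), the energy log, and the metadata needed
#'   to turn frames into measurable [new_gel_frame()] tibbles.
#' @export
run_protocol <- function(system, ff = force_field(), schedule = default_schedule(),
                         seed = 1L, frame_every = 500L,
                         integrator = c("langevin", "brownian"),
                         equal_duration = TRUE, ramp_frac = 0.5) {
  stopifnot(inherits(system, "gel_system"))
  integrator <- match.arg(integrator)
  schedule <- as_tibble(schedule)
  stopifnot(all(c("eps", "equil_steps", "stats_steps") %in% names(schedule)))
  if (is.unsorted(schedule$eps)) abort("`schedule$eps` must be non-decreasing")
  if (any(schedule$eps > 1.4)) {
    warn("schedule exceeds eps = 1.4 kBT, outside the studied solvent-quality range")
  }
  if (equal_duration) {
    tot <- schedule$equil_steps + schedule$stats_steps
    if (length(unique(tot)) > 1) {
      abort(paste0("stages have unequal total duration (equil + stats); ",
                   "set `equal_duration = FALSE` to allow this"))
    }
  }
  state <- as_md_state(system, ff, seed = seed)
  stages <- vector("list", nrow(schedule))
  logs <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    e <- schedule$eps[k]
    equil <- schedule$equil_steps[k]
    if (k > 1L && ramp_frac > 0 && e > schedule$eps[k - 1L]) {
      e_prev <- schedule$eps[k - 1L]
      n_chunk <- 20L
      ramp_steps <- max(round(ramp_frac * equil / n_chunk), 1L)
      e_seq <- exp(seq(log(e_prev), log(e), length.out = n_chunk + 1L))[-1L]
      for (m in seq_len(n_chunk)) {
        state <- run_md(state, ff, nsteps = ramp_steps,
                        seed = seed + 100000L * k + m, eps = e_seq[m],
                        log_every = 0L, integrator = integrator)
      }
      equil <- max(equil - n_chunk * ramp_steps, 0L)
    }
    state <- run_md(state, ff, nsteps = equil,
                    seed = seed + 1000L * (2L * k - 1L), eps = e,
                    log_every = 0L, integrator = integrator)
    state <- run_md(state, ff, nsteps = schedule$stats_steps[k],
                    seed = seed + 1000L * (2L * k), eps = e,
                    frame_every = frame_every,
                    log_every = max(frame_every %/% 2L, 1L),
                    integrator = integrator)
    stages[[k]] <- state$frames
    logs[[k]] <- dplyr::mutate(state$log, eps = e, .before = 1)
  }
  structure(list(
    schedule = schedule,
    stages = stages,
    log = dplyr::bind_rows(logs),
    species = state$species,
    charge = state$charge,
    bonds = state$bonds,
    box = state$box,
    topology = system$topology,
    seed = as.integer(seed),
    frame_every = as.integer(frame_every)
  ), class = "gel_trajectory")
}

#' Default solvent-quality schedule
#'
#' The attraction parameter ramps from the good-solvent value 0.01 kBT to
#' the poor-solvent value 1.4 kBT. Desk-scale step counts (5e4
#' equilibration + 2e4 statistics per stage) stand in for the cluster-scale
#' protocol; both are configurable.
#'
#' @param eps Vector of non-decreasing attraction strengths (kBT).
#' @param equil_steps,stats_steps Steps per stage.
#' @return A tibble usable as a [run_protocol()] schedule.
#' @export
default_schedule <- function(eps = c(0.01, seq(0.1, 1.4, by = 0.1)),
                             equil_steps = 50000L, stats_steps = 20000L) {
  tibble(eps = eps, equil_steps = as.integer(equil_steps),
         stats_steps = as.integer(stats_steps))
}

#' @export
print.gel_trajectory <- function(x, ...) {
  cat("<gel_trajectory> ", nrow(x$schedule), " solvent-quality stages, ",
      sum(lengths(x$stages)), " frames of ", length(x$species), " beads\n", sep = "")
  invisible(x)
}

#' Extract measurable frames from a trajectory stage
#'
#' @param traj A `gel_trajectory`.
#' @param stage Stage index (1-based) into the schedule.
#' @return List of `gel_frame` tibbles for that stage's statistics window.
#' @export
stage_frames <- function(traj, stage) {
  stopifnot(inherits(traj, "gel_trajectory"),
            stage >= 1, stage <= length(traj$stages))
  role <- c(traj$topology$beads$role,
            rep("counterion", sum(traj$species == 1L)))
  purrr::map(traj$stages[[stage]], function(m) {
    new_gel_frame(tibble(
      id = seq_len(nrow(m)),
      species = ifelse(traj$species == 0L, "network", "counterion"),
      charge = traj$charge,
      x = m[, 1], y = m[, 2], z = m[, 3],
      role = role
    ), box = traj$box, eps = traj$schedule$eps[stage])
  })
}
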