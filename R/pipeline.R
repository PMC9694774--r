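# End-to-end experiment: build -> anneal -> solvent-quality sweep ->
# measure -> tabulate.

#' Configure a solvent-quality sweep
#'
#' Bundles every parameter of a sweep experiment — builder geometry,
#' charge fraction, force field, annealing schedule, seeds — into a single
#' serializable object. A sweep is a pure function of its configuration:
#' rerunning the same config reproduces the same tables bit for bit.
#'
#' The default is the desk-scale demonstration system: a 4 x 4 x 16-cell
#' template with subchain length `M = 5`, a cylinder radius of one cell
#' edge (realized aspect ratio about 7.5, roughly 4,200 network beads),
#' and an 8-point attraction ramp of about 1e5 total steps, which runs in
#' minutes on one CPU. The cluster-scale geometry of the headline
#' experiments (10 x 10 x 100 cells, M = 10/20, millions of steps) is
#' expressed with the same parameters but is not a desk workload.
#'
#' @param nx,ny,nz Template cells per axis.
#' @param M Subchain length.
#' @param bond_spacing As-built bond length (sigma).
#' @param radius Cylinder radius in sigma or `"max-fit"`.
#' @param f Charged-group fraction in `[0, 1]`.
#' @param box Simulation box (3 lengths, sigma) or `NULL` for automatic.
#' @param eps Non-decreasing attraction schedule (kBT).
#' @param equil_steps,stats_steps Steps per stage.
#' @param frame_every Statistics-frame cadence (steps).
#' @param seed Master seed; charge assignment, counterion placement and
#'   dynamics use seeds derived from it.
#' @param integrator `"langevin"` or `"brownian"`.
#' @param ramp_frac See [run_protocol()].
#' @param profile_bin Radial profile bin width (sigma).
#' @param ff Named list of [force_field()] overrides (e.g.
#'   `list(coulomb_cutoff = 10)`); `eps_poly` is driven by the schedule.
#' @return A `sweep_config`.
#' @export
sweep_config <- function(nx = 4, ny = 4, nz = 16, M = 5, bond_spacing = 0.97,
                         radius = "auto", f = 0, box = NULL,
                         eps = c(0.01, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4),
                         equil_steps = 8000, stats_steps = 4000,
                         frame_every = 500, seed = 1L,
                         integrator = "langevin", ramp_frac = 0.5,
                         profile_bin = 1.0, ff = list()) {
  cfg <- list(nx = nx, ny = ny, nz = nz, M = M, bond_spacing = bond_spacing,
              radius = radius, f = f, box = box, eps = eps,
              equil_steps = equil_steps, stats_steps = stats_steps,
              frame_every = frame_every, seed = as.integer(seed),
              integrator = integrator, ramp_frac = ramp_frac,
              profile_bin = profile_bin, ff = ff)
  structure(cfg, class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("<sweep_config> cells ", x$nx, "x", x$ny, "x", x$nz, ", M = ", x$M,
      ", radius = ", format(x$radius), ", f = ", x$f, "\n", sep = "")
  cat("  eps:", paste(x$eps, collapse = ", "), "\n")
  cat("  steps/stage:", x$equil_steps, "+", x$stats_steps,
      "| seed:", x$seed, "\n")
  invisible(x)
}

.build_from_config <- function(config) {
  topo <- build_diamond_template(config$nx, config$ny, config$nz, config$M,
                                 config$bond_spacing)
  radius <- config$radius
  if (identical(radius, "auto")) radius <- topo$cell_edge
  topo <- inscribe_cylinder(topo, radius)
  if (config$f > 0) topo <- assign_charges(topo, config$f, seed = config$seed + 1L)
  make_system(topo, box = config$box, seed = config$seed + 2L)
}

#' Measure all observables on one frame
#'
#' One row of shape/charge observables for a single (unwrapped) frame:
#' contour length L, thickness 2R from the central slab, contour aspect
#' ratio A = L/2R, the eigenvalue-based aspect estimate and raw ratio,
#' asphericity, the localized counterion fraction beta (when counterions
#' are present), and the net charge fraction f(1 - beta).
#'
#' @param frame A `gel_frame` with network (and optionally counterion)
#'   beads.
#' @param topology The `gel_topology` the frame belongs to (provides the
#'   axis chain and f).
#' @return One-row tibble.
#' @export
measure_frame <- function(frame, topology) {
  net <- frame[frame$species == "network", , drop = FALSE]
  L <- contour_length(net, topology$axis_chain)
  D <- gel_thickness(net, L = L)
  ev <- gyration_eigenvalues(net)
  asp <- aspect_from_eigenvalues(ev[1], ev[3])
  has_ci <- any(frame$species == "counterion")
  beta <- if (has_ci) counterion_localization(frame) else NA_real_
  tibble(
    L = L, D = D, aspect_contour = L / D,
    aspect_eigen = asp$aspect_eigen, eigen_ratio = asp$eigen_ratio,
    asphericity = asphericity(ev),
    beta = beta,
    net_charge = if (has_ci) net_charge_fraction(topology$f, beta) else 0
  )
}

.se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# stage frames are >= frame_every steps apart; treating each as one block
# gives the block-averaged standard error of the stats window
.summarise_stage <- function(per_frame, eps) {
  means <- dplyr::summarise(per_frame, dplyr::across(dplyr::everything(), ~ mean(.x)))
  ses <- dplyr::summarise(per_frame,
                          dplyr::across(c("L", "D", "aspect_contour",
                                          "aspect_eigen", "asphericity", "beta"),
                                        .se, .names = "se_{.col}"))
  dplyr::bind_cols(tibble(eps = eps), means, ses)
}

#' Run a configured solvent-quality sweep
#'
#' Executes the full experiment: builds the cylindrical microgel, places
#' counterions, anneals at the initial good-solvent attraction, steps
#' through the solvent-quality schedule, measures every observable on each
#' stage's statistics frames, and attaches per-stage radial profiles and a
#' reproducibility manifest.
#'
#' @param config A [sweep_config()].
#' @param profiles Compute radial profiles per stage? (Slightly slower.)
#' @return A `gel_sweep`: `observables` (one row per eps, means and
#'   block-averaged standard errors), `profiles` (list of
#'   [radial_profiles()] tibbles), `per_frame` (frame-resolved records),
#'   `topology`, `config`, and `manifest`.
#' @export
run_sweep <- function(config = sweep_config(), profiles = TRUE) {
  stopifnot(inherits(config, "sweep_config"))
  system <- .build_from_config(config)
  ff <- do.call(force_field, config$ff[setdiff(names(config$ff), "eps_poly")])
  schedule <- default_schedule(config$eps, config$equil_steps, config$stats_steps)
  traj <- run_protocol(system, ff, schedule, seed = config$seed + 3L,
                       frame_every = config$frame_every,
                       integrator = config$integrator,
                       ramp_frac = config$ramp_frac)
  topo <- system$topology
  obs <- vector("list", nrow(schedule))
  prof <- vector("list", nrow(schedule))
  per_frame <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    frames <- stage_frames(traj, k)
    pf <- dplyr::bind_rows(lapply(frames, measure_frame, topology = topo))
    per_frame[[k]] <- dplyr::mutate(pf, eps = schedule$eps[k], .before = 1)
    obs[[k]] <- .summarise_stage(pf, schedule$eps[k])
    if (profiles) {
      prof[[k]] <- radial_profiles(frames, L = pf$L, bin_width = config$profile_bin)
    }
  }
  structure(list(
    observables = dplyr::bind_rows(obs),
    profiles = prof,
    per_frame = dplyr::bind_rows(per_frame),
    log = traj$log,
    topology = topo,
    config = config,
    manifest = list(
      seed = config$seed,
      version = as.character(utils::packageVersion("cylgel")),
      n_network = nrow(topo$beads),
      n_counterions = sum(topo$beads$charge > 0),
      L0 = topo$L0, R0 = topo$R0_cyl, A0 = topo$A0,
      crosslink_fraction = crosslink_fraction(topo)
    )
  ), class = "gel_sweep")
}

#' @export
print.gel_sweep <- function(x, ...) {
  m <- x$manifest
  cat("<gel_sweep> N = ", m$n_network, " beads (f = ", x$config$f,
      "), A0 = ", signif(m$A0, 3), ", ", nrow(x$observables),
      " solvent qualities\n", sep = "")
  print(x$observables, n = 6)
  invisible(x)
}

#' @describeIn run_sweep `tidy()` returns the per-eps observable table.
#' @param x A `gel_sweep`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gel_sweep <- function(x, ...) x$observables

#' @describeIn run_sweep `glance()` returns a one-row sweep summary.
#' @exportS3Method generics::glance
glance.gel_sweep <- function(x, ...) {
  m <- x$manifest
  o <- x$observables
  tibble(
    n_network = m$n_network, n_counterions = m$n_counterions,
    f = x$config$f, M = x$config$M,
    crosslink_fraction = m$crosslink_fraction,
    L0 = m$L0, A0 = m$A0,
    n_eps = nrow(o), eps_min = min(o$eps), eps_max = max(o$eps),
    L_swollen = o$L[1], L_collapsed = o$L[nrow(o)],
    final_asphericity = o$asphericity[nrow(o)]
  )
}

#' Compare sweeps across charge fractions
#'
#' Aligns the L, 2R and A curves of several sweeps on their shared
#' attraction grid and flags interior extrema: a maximum of the aspect
#' ratio (the electrostatic signature) and an interior minimum of the
#' thickness (the surface-tension signature). An interior maximum is
#' flagged when the curve shows a statistically significant rise followed
#' by a significant fall (and vice versa for a minimum), each difference
#' exceeding twice its propagated block-averaged standard error — a
#' local-extremum definition that is robust to plateaus and to the
#' contour-path inflation of the swollen endpoint on small gels.
#'
#' @param sweeps List of `gel_sweep` objects (at least 2) on one eps grid.
#' @param labels Optional names; defaults to `f = <value>`.
#' @return A `gel_comparison`: long tibble `table` (label, eps, L, D, A)
#'   and a `flags` tibble (one row per sweep).
#' @export
compare_sweeps <- function(sweeps, labels = NULL) {
  stopifnot(is.list(sweeps), length(sweeps) >= 2,
            all(vapply(sweeps, inherits, TRUE, "gel_sweep")))
  grids <- lapply(sweeps, function(s) s$observables$eps)
  if (!all(vapply(grids, identical, TRUE, grids[[1]]))) {
    abort("sweeps must share the same eps schedule")
  }
  if (is.null(labels)) {
    labels <- vapply(sweeps, function(s) paste0("f = ", s$config$f), "")
  }
  tab <- dplyr::bind_rows(lapply(seq_along(sweeps), function(i) {
    o <- sweeps[[i]]$observables
    tibble(label = labels[i], eps = o$eps, L = o$L, D = o$D,
           A = o$aspect_contour, asphericity = o$asphericity)
  }))
  interior_extremum <- function(v, se, maximum = TRUE) {
    if (!maximum) v <- -v
    if (all(is.na(se))) se <- rep(0, length(v))
    se[is.na(se)] <- mean(se, na.rm = TRUE)
    n <- length(v)
    # a difference of two stage means is significant when it exceeds twice
    # its propagated standard error
    sig <- function(j, i) (v[j] - v[i]) > 2 * sqrt(se[j]^2 + se[i]^2)
    for (j in 2:(n - 1L)) {
      rose <- any(vapply(seq_len(j - 1L), function(i) sig(j, i), TRUE))
      fell <- any(vapply((j + 1L):n, function(i) sig(j, i), TRUE))
      if (rose && fell) return(TRUE)
    }
    FALSE
  }
  flags <- dplyr::bind_rows(lapply(seq_along(sweeps), function(i) {
    o <- sweeps[[i]]$observables
    tibble(
      label = labels[i], f = sweeps[[i]]$config$f,
      A_interior_max = interior_extremum(o$aspect_contour, o$se_aspect_contour, TRUE),
      D_interior_min = interior_extremum(o$D, o$se_D, FALSE),
      final_asphericity = o$asphericity[nrow(o)]
    )
  }))
  structure(list(table = tab, flags = flags), class = "gel_comparison")
}

#' @export
print.gel_comparison <- function(x, ...) {
  cat("<gel_comparison> of", length(unique(x$table$label)), "sweeps\n")
  print(x$flags)
  invisible(x)
}

# ---------------------------------------------------------------------------
# plots

#' Plot a sweep's observables against solvent quality
#'
#' Panels of contour length L, thickness 2R, aspect ratio A = L/2R, and
#' asphericity versus the attraction parameter, with block-averaged error
#' bars.
#'
#' @param object A `gel_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gel_sweep <- function(object, ...) {
  o <- object$observables
  long <- dplyr::bind_rows(
    tibble(eps = o$eps, value = o$L, se = o$se_L, what = "contour length L"),
    tibble(eps = o$eps, value = o$D, se = o$se_D, what = "thickness 2R"),
    tibble(eps = o$eps, value = o$aspect_contour, se = o$se_aspect_contour,
           what = "aspect ratio A"),
    tibble(eps = o$eps, value = o$asphericity, se = o$se_asphericity,
           what = "asphericity")
  )
  long$what <- factor(long$what, levels = unique(long$what))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eps, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                          ymax = .data$value + .data$se),
                             size = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = expression(epsilon ~ "(" * k[B] * T * ")"), y = NULL) +
    ggplot2::theme_bw()
}

#' Plot radial volume-fraction profiles
#'
#' Polymer, charged-group and counterion volume fractions against the
#' radial coordinate.
#'
#' @param object A `gel_profile` from [radial_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gel_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::starts_with("phi_"),
                              names_to = "species", names_prefix = "phi_",
                              values_to = "phi")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$phi,
                                     colour = .data$species,
                                     linetype = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (sigma)", y = "volume fraction") +
    ggplot2::theme_bw()
}

#' Overlay the aspect-ratio curves of compared sweeps
#'
#' @param object A `gel_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gel_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("L", "D", "A"),
                              names_to = "what", values_to = "value")
  long$what <- factor(long$what, levels = c("L", "D", "A"),
                      labels = c("contour length L", "thickness 2R", "aspect ratio A"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eps, y = .data$value,
                                     colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = expression(epsilon ~ "(" * k[B] * T * ")"), y = NULL,
                  colour = NULL) +
    ggplot2::theme_bw()
}
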