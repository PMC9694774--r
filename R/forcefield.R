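# Force-field parameter container and the analytic pair potentials.

#' Force-field parameters
#'
#' Collects all interaction constants of the coarse-grained model in
#' reduced units (lengths in sigma, energies in kBT, mass m = 1, time in
#' tau). All beads interact through a truncated Lennard-Jones potential:
#' monomer-monomer pairs with well depth `eps_poly` (the solvent-quality
#' parameter, 0.01 = good solvent to 1.4 = poor solvent) and cutoff
#' `rcut_poly = 2.5`, while any pair involving a counterion uses
#' `eps_ci = 1` truncated at the potential minimum `rcut_ci = 2^(1/6)`
#' (purely repulsive excluded volume). Bonded beads are connected by FENE
#' springs with `fene_k = 30` and maximum extension `fene_R0 = 1.5`.
#' Charges interact via the Coulomb potential with Bjerrum length `lB = 1`
#' (aqueous conditions).
#'
#' The long-range solver is selected by `coulomb_method`: `"ewald"`
#' (classical Ewald summation meeting `coulomb_accuracy` relative accuracy,
#' tinfoil boundaries), `"dsf"` (damped shifted-force truncation at
#' `coulomb_cutoff` — a fast, explicitly approximate mode used for
#' desk-scale dynamics in large dilute boxes), or `"none"`.
#'
#' By default the LJ energy is shifted to zero at the cutoff; forces (and
#' hence all structural observables) are identical to the unshifted form,
#' which can be selected with `lj_shift = FALSE`.
#'
#' @param eps_poly Monomer-monomer attraction strength in kBT (solvent
#'   quality; larger = poorer solvent).
#' @param eps_ci LJ parameter for pairs involving counterions (kBT).
#' @param rcut_poly,rcut_ci LJ cutoffs in sigma.
#' @param lB Bjerrum length in sigma.
#' @param fene_k FENE spring constant (kBT/sigma^2).
#' @param fene_R0 FENE maximum extension (sigma).
#' @param dt Integration time step (tau).
#' @param gamma Langevin friction (1/tau).
#' @param kT Thermostat temperature (kBT units).
#' @param mass Bead mass (m units).
#' @param coulomb_method `"dsf"`, `"ewald"`, or `"none"`.
#' @param coulomb_cutoff Real-space Coulomb cutoff in sigma (DSF and the
#'   Ewald real-space part; for Ewald, 0 means auto: just under half the
#'   shortest box edge).
#' @param dsf_alpha Damping parameter of the DSF mode (1/sigma). The
#'   default 0 gives the undamped shifted-force (Wolf-type) truncation,
#'   which stays within `(r/rcut)^2` of the bare Coulomb force inside the
#'   cutoff — appropriate for a single gel in a dilute box, where strong
#'   damping would artificially suppress counterion condensation. Finite
#'   values reproduce the conventional damped form used for dense ionic
#'   systems.
#' @param coulomb_accuracy Target relative accuracy of the Ewald solver.
#' @param lj_shift Shift the LJ energy to zero at the cutoff?
#' @param cap Pair-force magnitude cap (kBT/sigma) for relaxation
#'   pre-passes; 0 (default) disables capping and overlapping beads are an
#'   error.
#' @return A `force_field` object (validated list).
#' @export
force_field <- function(eps_poly = 1.0, eps_ci = 1.0,
                        rcut_poly = 2.5, rcut_ci = 2^(1 / 6),
                        lB = 1.0, fene_k = 30, fene_R0 = 1.5,
                        dt = 0.005, gamma = 1.0, kT = 1.0, mass = 1.0,
                        coulomb_method = c("dsf", "ewald", "none"),
                        coulomb_cutoff = 10, dsf_alpha = 0,
                        coulomb_accuracy = 1e-5,
                        lj_shift = TRUE, cap = 0) {
  coulomb_method <- match.arg(coulomb_method)
  stopifnot(eps_poly > 0, eps_ci > 0, rcut_poly > 0, rcut_ci > 0,
            fene_k > 0, fene_R0 > 0, dt > 0, gamma > 0, kT > 0, mass > 0,
            lB >= 0, coulomb_accuracy > 0)
  if (dt > 0.05) abort("`dt` is far above the stable range for this model (<= 0.05 tau).")
  structure(list(
    eps_poly = eps_poly, eps_ci = eps_ci,
    rcut_poly = rcut_poly, rcut_ci = rcut_ci,
    lB = lB, fene_k = fene_k, fene_R0 = fene_R0,
    dt = dt, gamma = gamma, kT = kT, mass = mass,
    coulomb_method = coulomb_method, coulomb_cutoff = coulomb_cutoff,
    dsf_alpha = dsf_alpha, coulomb_accuracy = coulomb_accuracy,
    lj_shift = lj_shift, cap = cap
  ), class = "force_field")
}

# internal: list the C++ side expects
.ff_cpp <- function(ff, eps_poly = NULL, cap = NULL) {
  list(
    eps_poly = eps_poly %||% ff$eps_poly, eps_ci = ff$eps_ci,
    rcut_poly = ff$rcut_poly, rcut_ci = ff$rcut_ci,
    lj_shift = ff$lj_shift, fene_k = ff$fene_k, fene_R0 = ff$fene_R0,
    lB = ff$lB,
    coul_method = match(ff$coulomb_method, c("none", "dsf", "ewald")) - 1L,
    coul_rcut = ff$coulomb_cutoff, dsf_alpha = ff$dsf_alpha,
    ewald_accuracy = ff$coulomb_accuracy,
    cap = cap %||% ff$cap
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.force_field <- function(x, ...) {
  cat("<force_field> eps_poly =", x$eps_poly, "kBT, eps_ci =", x$eps_ci,
      "| rcut", x$rcut_poly, "/", signif(x$rcut_ci, 4), "sigma\n")
  cat("  FENE k =", x$fene_k, "R0 =", x$fene_R0,
      "| lB =", x$lB, "| coulomb:", x$coulomb_method, "\n")
  cat("  dt =", x$dt, "tau, gamma =", x$gamma, ", kT =", x$kT, "\n")
  invisible(x)
}

#' Truncated Lennard-Jones pair energy
#'
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)` for distances up to `rcut`, zero
#' beyond. With `shift = TRUE` (the default used in dynamics) the energy is
#' shifted so `U(rcut) = 0`; the force is unaffected.
#'
#' @param r Distance(s) in sigma.
#' @param eps Well depth in kBT.
#' @param rcut Cutoff in sigma.
#' @param shift Shift the energy to zero at the cutoff?
#' @return Energy (kBT), vectorized over `r`.
#' @export
lj_pair_energy <- function(r, eps = 1, rcut = 2.5, shift = TRUE) {
  stopifnot(all(r > 0))
  u <- function(rr) 4 * eps * (rr^-12 - rr^-6)
  out <- ifelse(r <= rcut, u(r) - if (shift) u(rcut) else 0, 0)
  as.numeric(out)
}

#' FENE bond energy
#'
#' `U(r) = -(k/2) R0^2 log(1 - (r/R0)^2)`, the finitely extensible
#' nonlinear elastic spring, diverging at the maximum extension `R0`.
#'
#' @param r Bond length(s) in sigma; must be below `R0`.
#' @param k Spring constant (kBT/sigma^2).
#' @param R0 Maximum extension (sigma).
#' @return Energy (kBT), vectorized over `r`.
#' @export
fene_bond_energy <- function(r, k = 30, R0 = 1.5) {
  stopifnot(all(r >= 0))
  if (any(r >= R0)) {
    abort(sprintf("FENE bond broken: r = %.4f sigma >= R0 = %.2f sigma",
                  max(r), R0))
  }
  -k / 2 * R0^2 * log(1 - (r / R0)^2)
}

#' Coulomb energy of a charge configuration
#'
#' Total electrostatic energy `sum_{i<j} lB kT qi qj / rij` under the
#' chosen long-range treatment. `"ewald"` is the accurate periodic solver
#' (requires a neutral system) meeting `accuracy` relative error;
#' `"direct"` is the brute-force oracle — a plain pair sum for open
#' boundaries (`box = NULL`) or a lattice sum over `nshells` cubic image
#' shells for periodic systems; `"dsf"` is the approximate damped
#' shifted-force truncation used in fast dynamics.
#'
#' @param frame A frame (or data frame / matrix of coordinates) with
#'   charges in a `charge` column, or supply `charges`.
#' @param method `"ewald"`, `"direct"`, or `"dsf"`.
#' @param box Periodic box lengths (defaults to the frame attribute);
#'   `NULL` means open boundaries (direct method only).
#' @param charges Charge vector in e, overriding the frame column.
#' @param lB Bjerrum length (sigma).
#' @param accuracy Ewald relative accuracy target.
#' @param nshells Image shells for the periodic direct sum.
#' @param cutoff,alpha DSF cutoff and damping.
#' @return Energy in kBT.
#' @export
coulomb_energy <- function(frame, method = c("ewald", "direct", "dsf"),
                           box = NULL, charges = NULL, lB = 1,
                           accuracy = 1e-5, nshells = 8,
                           cutoff = 8, alpha = 0.3) {
  method <- match.arg(method)
  p <- .xyz_matrix(frame)
  q <- charges %||% frame[["charge"]]
  if (is.null(q)) abort("no charges: supply a `charge` column or `charges`")
  if (is.null(box) && !is.matrix(frame)) box <- attr(frame, "box")
  if (method == "ewald") {
    if (is.null(box)) abort("Ewald summation needs a periodic `box`")
    return(cpp_coulomb_ewald(p, q, box, lB, accuracy))
  }
  if (method == "direct") {
    if (is.null(box)) {
      return(cpp_coulomb_direct(p, q, c(Inf, Inf, Inf), lB, 0L))
    }
    return(cpp_coulomb_direct(p, q, box, lB, as.integer(nshells)))
  }
  # dsf: reuse the engine with only electrostatics switched on
  ffl <- list(eps_poly = 1e-12, eps_ci = 1e-12, rcut_poly = 0.1, rcut_ci = 0.1,
              lj_shift = FALSE, fene_k = 1, fene_R0 = 1e6, lB = lB,
              coul_method = 1L, coul_rcut = cutoff, dsf_alpha = alpha,
              ewald_accuracy = accuracy, cap = 0)
  if (is.null(box)) box <- c(Inf, Inf, Inf)
  res <- cpp_forces(p, integer(nrow(p)), q,
                    matrix(integer(0), 0, 2), box, ffl, TRUE)
  res$e_coul
}
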