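# Synthetic idealized conformations with closed-form shape observables.
# These are first-class generators used to validate every measurement
# without running dynamics: a uniform solid cylinder of length L and radius
# R has gyration eigenvalues L^2/12 (axial) and R^2/4 (transverse); a
# uniform ball of radius R has all three equal to R^2/5.

#' Uniform random cloud filling a solid cylinder
#'
#' Samples `n` points uniformly inside a solid cylinder of length `L` and
#' radius `R`, axis along z, centred at the origin. Transverse coordinates
#' are drawn by rejection from the bounding square, so the distribution is
#' exactly uniform.
#'
#' @param n Number of points (at least 100 for meaningful moments).
#' @param L,R Cylinder length and radius in sigma.
#' @param seed Integer seed; the cloud is a pure function of
#'   `(n, L, R, seed)`.
#' @return A `gel_frame` tibble with columns `id, species, charge, x, y, z`
#'   (all points tagged `"network"`, uncharged).
#' @examples
#' cyl <- uniform_cylinder_cloud(5000, L = 32, R = 4, seed = 1)
#' gyration_eigenvalues(cyl)  # ~ c(32^2/12, 4^2/4, 4^2/4)
#' @export
uniform_cylinder_cloud <- function(n, L, R, seed = 1L) {
  stopifnot(n >= 100, L > 0, R > 0)
  xy <- withr::with_seed(seed, {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      m <- max(ceiling(1.31 * (n - nrow(out))), 64L)
      cand <- matrix(runif(2 * m, -R, R), ncol = 2)
      out <- rbind(out, cand[rowSums(cand^2) <= R^2, , drop = FALSE])
    }
    cbind(out[seq_len(n), , drop = FALSE], runif(n, -L / 2, L / 2))
  })
  new_gel_frame(tibble(
    id = seq_len(n), species = "network", charge = 0,
    x = xy[, 1], y = xy[, 2], z = xy[, 3]
  ))
}

#' Uniform random cloud filling a ball
#'
#' Samples `n` points uniformly inside a ball of radius `R` centred at the
#' origin, by rejection from the bounding cube.
#'
#' @inheritParams uniform_cylinder_cloud
#' @return A `gel_frame` tibble (see [uniform_cylinder_cloud()]).
#' @export
uniform_sphere_cloud <- function(n, R, seed = 1L) {
  stopifnot(n >= 100, R > 0)
  xyz <- withr::with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      m <- max(ceiling(1.95 * (n - nrow(out))), 64L)
      cand <- matrix(runif(3 * m, -R, R), ncol = 3)
      out <- rbind(out, cand[rowSums(cand^2) <= R^2, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
  new_gel_frame(tibble(
    id = seq_len(n), species = "network", charge = 0,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

#' Preparation-state conformation of a built microgel
#'
#' Returns the as-built (fully stretched subchains) coordinates of a
#' topology or system as a measurable frame: the reference state in which
#' the aspect ratio equals the configured `L0 / 2 R0`.
#'
#' @param x A `gel_topology` or `gel_system`.
#' @return A `gel_frame` tibble; for systems, counterions are included and
#'   tagged `species = "counterion"`.
#' @export
ideal_microgel_frame <- function(x) {
  if (inherits(x, "gel_system")) {
    b <- x$topology$beads
    ci <- x$counterions
    fr <- dplyr::bind_rows(
      tibble(id = b$id, species = "network", charge = b$charge,
             x = b$x, y = b$y, z = b$z, role = b$role),
      tibble(id = ci$id, species = rep("counterion", nrow(ci)),
             charge = ci$charge, x = ci$x, y = ci$y, z = ci$z,
             role = rep("counterion", nrow(ci)))
    )
    return(new_gel_frame(fr, box = x$box))
  }
  stopifnot(inherits(x, "gel_topology"))
  b <- x$beads
  new_gel_frame(tibble(id = b$id, species = "network", charge = b$charge,
                       x = b$x, y = b$y, z = b$z, role = b$role))
}

#' Construct a measurable frame
#'
#' Tags a tibble of bead records (`id, species, charge, x, y, z`) as a
#' `gel_frame`, optionally attaching the periodic box and the solvent
#' quality it was recorded at.
#'
#' @param df Data frame of bead records.
#' @param box Periodic box lengths (sigma) or `NULL` for open boundaries.
#' @param eps Solvent-quality parameter the frame belongs to.
#' @return A `gel_frame` tibble.
#' @export
new_gel_frame <- function(df, box = NULL, eps = NULL) {
  df <- as_tibble(df)
  attr(df, "box") <- box
  attr(df, "eps") <- eps
  class(df) <- c("gel_frame", class(df))
  df
}
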