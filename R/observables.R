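# Shape and charge observables: contour length, slab thickness,
# gyration-tensor metrics, counterion localization, radial profiles.

.xyz_matrix <- function(frame) {
  if (is.matrix(frame)) {
    stopifnot(ncol(frame) == 3)
    return(frame)
  }
  stopifnot(all(c("x", "y", "z") %in% names(frame)))
  cbind(frame$x, frame$y, frame$z)
}

.network_xyz <- function(frame) {
  if (!is.matrix(frame) && "species" %in% names(frame)) {
    frame <- frame[frame$species == "network", , drop = FALSE]
  }
  .xyz_matrix(frame)
}

#' Contour length along the axis cross-link chain
#'
#' The contour length L of a cylindrical microgel is the sum of distances
#' between neighbouring cross-links of the chain that the cylinder axis
#' passes through under preparation conditions. It is nearly equal to the
#' apparent length of the cylinder.
#'
#' @param frame A `gel_frame` (or data frame with `x, y, z`) whose network
#'   beads are ordered as in the topology; coordinates must be unwrapped
#'   across periodic boundaries (see [unwrap_frame()]).
#' @param axis_chain Integer bead ids of the axis cross-links in axial
#'   order, as recorded by [inscribe_cylinder()] (`topology$axis_chain`).
#' @return Length in sigma.
#' @export
contour_length <- function(frame, axis_chain) {
  stopifnot(length(axis_chain) >= 2)
  p <- .network_xyz(frame)[axis_chain, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Cylinder thickness from a central slab
#'
#' The thickness 2R (cylinder diameter) is determined from a slab cut from
#' the central part of the network (located from the centre of mass) with a
#' length equal to `slab_fraction` of the contour length L. The default
#' estimator is the uniform-cylinder moment relation `R = sqrt(2 <r_perp^2>)`
#' about the slab axis, which is exact for a uniformly filled cylinder; a
#' 95th-percentile radial-extent estimator is available as a robustness
#' check.
#'
#' @param frame A frame (unwrapped); only `species == "network"` rows are
#'   used when a species column is present.
#' @param L Contour length in sigma (from [contour_length()]); if `NULL`,
#'   the moment-equivalent length `sqrt(12 lambda_max)` is used.
#' @param slab_fraction Slab length as a fraction of L (default 0.2).
#' @param method `"moment"` (default) or `"percentile"`.
#' @return Thickness 2R in sigma.
#' @export
gel_thickness <- function(frame, L = NULL, slab_fraction = 0.2,
                          method = c("moment", "percentile")) {
  method <- match.arg(method)
  p <- .network_xyz(frame)
  com <- colMeans(p)
  e <- .principal_axis(p)
  s <- drop((p - matrix(com, nrow(p), 3, byrow = TRUE)) %*% e)
  if (is.null(L)) L <- sqrt(12 * gyration_eigenvalues(p)[1])
  half <- slab_fraction * L / 2
  slab <- abs(s) <= half
  if (!any(slab)) abort("central slab contains no beads")
  q <- p[slab, , drop = FALSE]
  cq <- colMeans(q)
  d <- q - matrix(cq, nrow(q), 3, byrow = TRUE)
  rperp2 <- rowSums(d^2) - drop(d %*% e)^2
  rperp2[rperp2 < 0] <- 0
  if (method == "moment") {
    2 * sqrt(2 * mean(rperp2))
  } else {
    2 * stats::quantile(sqrt(rperp2), 0.95, names = FALSE)
  }
}

#' Gyration-tensor eigenvalues
#'
#' Eigenvalues of the (equal-mass) gyration tensor about the centre of
#' mass, sorted in decreasing order. For a uniform solid cylinder of length
#' L and radius R the axial eigenvalue is L^2/12 and the two transverse
#' ones R^2/4; for a uniform ball of radius R all three equal R^2/5.
#'
#' @param frame A frame, data frame with `x, y, z`, or an n x 3 matrix.
#' @return Numeric vector `c(lambda1, lambda2, lambda3)`, decreasing.
#' @export
gyration_eigenvalues <- function(frame) {
  p <- .xyz_matrix(frame)
  if (nrow(p) < 3) abort("need at least 3 beads for a gyration tensor")
  d <- sweep(p, 2, colMeans(p))
  g <- crossprod(d) / nrow(d)
  sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

.principal_axis <- function(p) {
  d <- sweep(p, 2, colMeans(p))
  g <- crossprod(d) / nrow(d)
  ev <- eigen(g, symmetric = TRUE)
  ev$vectors[, which.max(ev$values)]
}

#' Aspect ratio from gyration eigenvalues
#'
#' Estimates the cylinder aspect ratio A = L/2R from the extreme gyration
#' eigenvalues by calibrating against the moment-equivalent uniform
#' cylinder: `A_hat = sqrt(12 lambda1) / (4 sqrt(lambda3))`. For long
#' cylinders this agrees with the contour-length-based L/2R; for a sphere
#' it evaluates to `sqrt(3)/2 ~ 0.866`. The raw eigenvalue ratio
#' `lambda1/lambda3` (the quantity sometimes plotted directly) is reported
#' alongside.
#'
#' @param lambda1,lambda3 Largest and smallest gyration eigenvalues
#'   (sigma^2), or a frame in `lambda1` with `lambda3` missing.
#' @return A tibble with columns `aspect_eigen` and `eigen_ratio`.
#' @export
aspect_from_eigenvalues <- function(lambda1, lambda3 = NULL) {
  if (is.null(lambda3)) {
    ev <- if (is.numeric(lambda1) && length(lambda1) == 3) lambda1
          else gyration_eigenvalues(lambda1)
    lambda3 <- ev[3]
    lambda1 <- ev[1]
  }
  stopifnot(all(lambda3 > 0))
  tibble(aspect_eigen = sqrt(12 * lambda1) / (4 * sqrt(lambda3)),
         eigen_ratio = lambda1 / lambda3)
}

#' Asphericity parameter
#'
#' The normalized gyration-tensor invariant
#' `delta = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2`,
#' which is 0 for any spherically symmetric mass distribution and 1 for an
#' ideal thin rod. Values above 0.6 are classified as cylindrical, below
#' 0.1 as spherical.
#'
#' @param lambda Either the three eigenvalues (numeric length 3) or a frame
#'   from which they are computed.
#' @return Asphericity in `[0, 1]`.
#' @export
asphericity <- function(lambda) {
  ev <- if (is.numeric(lambda) && length(lambda) == 3) lambda
        else gyration_eigenvalues(lambda)
  if (any(ev < -1e-12) || sum(ev) <= 0) abort("eigenvalues must be non-negative, not all zero")
  ev[ev < 0] <- 0
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / sum(ev)^2
}

#' Fraction of counterions localized within the microgel
#'
#' beta is the share of all counterions residing inside the microgel; the
#' remaining fraction `1 - beta` has escaped into the solution and sets the
#' uncompensated net charge of the gel. Two criteria are provided:
#' `"contact"` (default) counts a counterion as localized when its
#' minimum-image distance to the nearest network bead is at most `cutoff`
#' (default 2.5 sigma, the monomer attraction cutoff); `"envelope"` counts
#' counterions inside the moment-equivalent cylindrical envelope of the
#' network.
#'
#' @param frame A `gel_frame` containing both network beads and
#'   counterions.
#' @param cutoff Contact distance in sigma for the `"contact"` criterion.
#' @param criterion `"contact"` or `"envelope"`.
#' @param box Periodic box lengths; defaults to the frame's `box`
#'   attribute. `NULL` means open boundaries.
#' @return beta in `[0, 1]`.
#' @export
counterion_localization <- function(frame, cutoff = 2.5,
                                    criterion = c("contact", "envelope"),
                                    box = NULL) {
  criterion <- match.arg(criterion)
  stopifnot("species" %in% names(frame))
  if (is.null(box)) box <- attr(frame, "box")
  net <- .xyz_matrix(frame[frame$species == "network", ])
  ci <- .xyz_matrix(frame[frame$species == "counterion", ])
  if (nrow(ci) == 0) abort("frame contains no counterions")
  if (criterion == "contact") {
    b <- if (is.null(box)) c(Inf, Inf, Inf) else box
    dmin <- cpp_min_dist_to_set(ci, net, b)
    return(mean(dmin <= cutoff))
  }
  com <- colMeans(net)
  e <- .principal_axis(net)
  ev <- gyration_eigenvalues(net)
  half_l <- sqrt(12 * ev[1]) / 2
  r_env <- 2 * sqrt(ev[3])
  # minimum-image displacement of each counterion from the gel centre
  d <- sweep(ci, 2, com)
  if (!is.null(box)) {
    bm <- matrix(box, nrow(d), 3, byrow = TRUE)
    d <- d - bm * round(d / bm)
  }
  s <- drop(d %*% e)
  rp2 <- rowSums(d^2) - s^2
  mean(abs(s) <= half_l & rp2 <= r_env^2)
}

#' Net charge fraction of the microgel
#'
#' With a fraction `f` of charged network beads and a fraction `beta` of
#' counterions localized inside the gel, the uncompensated relative net
#' charge per network bead is `Q/(N e) = f (1 - beta)`.
#'
#' @param f Fraction of charged network beads in `[0, 1]`.
#' @param beta Localized counterion fraction in `[0, 1]`.
#' @return Net charge per bead in units of e.
#' @export
net_charge_fraction <- function(f, beta) {
  stopifnot(all(f >= 0 & f <= 1), all(beta >= 0 & beta <= 1))
  f * (1 - beta)
}

#' Cylindrical radial volume-fraction profiles
#'
#' Computes radial volume-fraction profiles of polymer beads, network
#' charged groups, and counterions about the microgel axis. Each frame's
#' gel is divided into consecutive cylindrical segments of length
#' `slab_fraction * L` along the principal axis; the two end segments are
#' excluded and bead counts of the inner segments are histogrammed in
#' annular bins (azimuthal averaging is implicit), converted to volume
#' fractions with the bead volume `pi sigma^3 / 6`, and averaged over
#' segments and frames.
#'
#' @param frames A `gel_frame` or list of them (same system, e.g. the
#'   statistics frames of one solvent quality).
#' @param L Contour length(s) in sigma: one value or one per frame; if
#'   `NULL`, the moment-equivalent length of the network is used per frame.
#' @param slab_fraction Segment length as a fraction of L (default 0.2).
#' @param bin_width Radial bin width in sigma.
#' @param r_max Outer radius of the binning in sigma; default covers the
#'   outermost network bead plus 5 sigma.
#' @return A `gel_profile` tibble: `r` (bin centre), `phi_polymer`,
#'   `phi_charged`, `phi_counterion`, with the segment length and count as
#'   attributes.
#' @export
radial_profiles <- function(frames, L = NULL, slab_fraction = 0.2,
                            bin_width = 0.5, r_max = NULL) {
  if (inherits(frames, "gel_frame") || is.data.frame(frames)) frames <- list(frames)
  n_fr <- length(frames)
  stopifnot(n_fr >= 1)
  n_seg <- floor(1 / slab_fraction)
  if (n_seg < 3) abort("slab_fraction leaves no inner segment (need at least 3 segments)")
  if (!is.null(L)) L <- rep_len(L, n_fr)

  # shared r grid across frames
  if (is.null(r_max)) {
    r_max <- 0
    for (fr in frames) {
      net <- .network_xyz(fr)
      com <- colMeans(net)
      e <- .principal_axis(net)
      d <- sweep(net, 2, com)
      rp2 <- rowSums(d^2) - drop(d %*% e)^2
      r_max <- max(r_max, sqrt(max(rp2, 0)))
    }
    r_max <- ceiling(r_max + 5)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0, nb, 3)
  seg_len_tot <- 0
  n_seg_tot <- 0L

  for (k in seq_len(n_fr)) {
    fr <- frames[[k]]
    stopifnot("species" %in% names(fr))
    box <- attr(fr, "box")
    net_rows <- fr$species == "network"
    net <- .xyz_matrix(fr[net_rows, ])
    com <- colMeans(net)
    e <- .principal_axis(net)
    Lk <- if (is.null(L)) sqrt(12 * gyration_eigenvalues(net)[1]) else L[k]
    l <- slab_fraction * Lk
    p <- .xyz_matrix(fr)
    d <- sweep(p, 2, com)
    if (!is.null(box)) {
      bm <- matrix(box, nrow(d), 3, byrow = TRUE)
      d <- d - bm * round(d / bm)
    }
    s <- drop(d %*% e)
    rp <- sqrt(pmax(rowSums(d^2) - s^2, 0))
    # segments tile [-L/2, L/2]; inner ones exclude the two ends
    seg <- floor((s + Lk / 2) / l)
    inner <- seg >= 1 & seg <= (n_seg - 2L) & rp < edges[nb + 1L]
    ibin <- findInterval(rp[inner], edges, rightmost.closed = TRUE)
    sp <- fr$species[inner]
    ch <- fr$charge[inner]
    pol <- sp == "network"
    counts[, 1] <- counts[, 1] + tabulate(ibin[pol], nb)
    counts[, 2] <- counts[, 2] + tabulate(ibin[pol & ch > 0], nb)
    counts[, 3] <- counts[, 3] + tabulate(ibin[sp == "counterion"], nb)
    seg_len_tot <- seg_len_tot + l * (n_seg - 2L)
    n_seg_tot <- n_seg_tot + (n_seg - 2L)
  }

  # annulus volume per bin uses the average total inner-segment length
  ann_area <- pi * (edges[-1]^2 - edges[-(nb + 1L)]^2)
  bead_vol <- pi / 6
  phi <- counts * bead_vol / (ann_area * seg_len_tot)
  out <- tibble(
    r = (edges[-1] + edges[-(nb + 1L)]) / 2,
    phi_polymer = phi[, 1], phi_charged = phi[, 2], phi_counterion = phi[, 3]
  )
  attr(out, "slab_fraction") <- slab_fraction
  attr(out, "n_segments") <- n_seg_tot
  attr(out, "n_frames") <- n_fr
  attr(out, "bin_width") <- bin_width
  class(out) <- c("gel_profile", class(out))
  out
}

#' Unwrap periodic-image coordinates using bond connectivity
#'
#' Reconstructs continuous (unwrapped) network coordinates from wrapped
#' ones by walking the bond graph breadth-first and placing each bead at
#' the minimum image relative to its already-placed neighbour. Counterions
#' (unbonded beads) are left as-is.
#'
#' @param frame A frame with wrapped coordinates.
#' @param bonds Bond tibble (`i, j`) of the network.
#' @param box Periodic box lengths; defaults to the frame's attribute.
#' @return The frame with network coordinates unwrapped.
#' @export
unwrap_frame <- function(frame, bonds, box = NULL) {
  if (is.null(box)) box <- attr(frame, "box")
  stopifnot(!is.null(box))
  p <- .xyz_matrix(frame)
  n_net <- if ("species" %in% names(frame)) sum(frame$species == "network") else nrow(p)
  p2 <- cpp_unwrap(p, as.matrix(bonds), as.numeric(box), n_net)
  frame$x <- p2[, 1]; frame$y <- p2[, 2]; frame$z <- p2[, 3]
  frame
}
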