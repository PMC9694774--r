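# Network builder: diamond-lattice templates, cylinder inscription, charge
# assignment and counterion placement.

# Diamond conventional-cell basis in quarter-cell integer coordinates.
# Sublattice A (fcc) sites have all-even coordinates, sublattice B sites
# (fcc + 1/4,1/4,1/4) all-odd; every bond connects a B site to 4 A sites.
.diamond_basis <- matrix(c(
  0L, 0L, 0L,
  0L, 2L, 2L,
  2L, 0L, 2L,
  2L, 2L, 0L,
  1L, 1L, 1L,
  1L, 3L, 3L,
  3L, 1L, 3L,
  3L, 3L, 1L), ncol = 3L, byrow = TRUE)

# Bond offsets (quarter-cell units) from a B site to its 4 A neighbours.
.diamond_bond_offsets <- matrix(c(
  -1L, -1L, -1L,
   1L,  1L, -1L,
   1L, -1L,  1L,
  -1L,  1L,  1L), ncol = 3L, byrow = TRUE)

# Enumerate cross-link nodes and node-node lattice bonds of an
# nx x ny x nz block of diamond conventional cells, in quarter-cell integer
# coordinates. With periodic = TRUE bonds wrap, giving the bulk (infinite
# lattice) bookkeeping: 8 nodes and 16 bonds per cell.
diamond_lattice_graph <- function(nx, ny, nz, periodic = FALSE) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  cells <- as.matrix(expand.grid(ix = seq_len(nx) - 1L,
                                 iy = seq_len(ny) - 1L,
                                 iz = seq_len(nz) - 1L))
  n_cells <- nrow(cells)
  # every basis point lies in [0,4) per axis, so nodes are generated once each
  nodes <- .diamond_basis[rep(seq_len(8L), n_cells), , drop = FALSE] +
    4L * cells[rep(seq_len(n_cells), each = 8L), , drop = FALSE]
  dims <- 4L * c(nx, ny, nz)
  key <- function(m) (m[, 1] * dims[2] + m[, 2]) * dims[3] + m[, 3]
  node_key <- key(nodes)
  idx <- seq_len(nrow(nodes))
  is_b <- nodes[, 1] %% 2L == 1L
  b_nodes <- nodes[is_b, , drop = FALSE]
  b_idx <- idx[is_b]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(4L)) {
    nb <- sweep(b_nodes, 2L, .diamond_bond_offsets[k, ], "+")
    if (periodic) nb <- sweep(nb %% matrix(dims, nrow(nb), 3, byrow = TRUE), 1L, 0L, "+")
    inside <- nb[, 1] >= 0L & nb[, 1] < dims[1] &
              nb[, 2] >= 0L & nb[, 2] < dims[2] &
              nb[, 3] >= 0L & nb[, 3] < dims[3]
    m <- match(key(nb[inside, , drop = FALSE]), node_key)
    from <- c(from, b_idx[inside])
    to <- c(to, m)
  }
  list(nodes = nodes, bonds = cbind(from, to), dims = dims)
}

#' Build a diamond-lattice microgel template
#'
#' Constructs a parallelepiped polymer-network template by tiling the diamond
#' conventional cell `nx * ny * nz` times and replacing every
#' nearest-neighbour lattice bond with a straight, fully stretched subchain of
#' `M` equally spaced beads, connected through tetrafunctional cross-links.
#' This is the preparation-state (ideal, fully stretched) conformation from
#' which cylindrical microgels are cut with [inscribe_cylinder()].
#'
#' The cell edge is derived from the subchain geometry: neighbouring
#' cross-links sit `(M + 1) * bond_spacing` apart, and the diamond
#' nearest-neighbour distance is `sqrt(3)/4` of the cell edge, so
#' `a = 4 (M + 1) bond_spacing / sqrt(3)` (all lengths in bead diameters,
#' sigma).
#'
#' @param nx,ny,nz Number of conventional diamond cells along x, y, z.
#' @param M Subchain length: beads strictly between two cross-links.
#'   The bulk cross-link fraction of such a network is `1/(2M + 1)`
#'   (about 5% for `M = 10`, 2.5% for `M = 20`).
#' @param bond_spacing Distance between consecutive bonded beads along a
#'   fully stretched subchain, in sigma. Must be positive and below the FENE
#'   maximum extension 1.5 sigma; the default 0.97 sits near the
#'   Lennard-Jones minimum so the as-built state is mechanically relaxed.
#' @return A `gel_topology` object: a list with tibbles `beads`
#'   (`id, x, y, z, role, charge`) and `bonds` (`i, j`), the ordered
#'   `axis_chain` of cross-link bead ids that the cylinder axis will pass
#'   through, and build provenance (`M`, `cell_counts`, `cell_edge`,
#'   `bond_spacing`, `L0`).
#' @seealso [inscribe_cylinder()], [assign_charges()], [make_system()],
#'   [crosslink_fraction()]
#' @examples
#' topo <- build_diamond_template(2, 2, 4, M = 3)
#' topo
#' crosslink_fraction(topo)
#' @export
build_diamond_template <- function(nx, ny, nz, M, bond_spacing = 0.97) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  if (M < 1) abort("`M` must be at least 1 (zero-length subchains are not a network).")
  if (bond_spacing <= 0 || bond_spacing >= 1.5) {
    abort("`bond_spacing` must lie in (0, 1.5) sigma: the FENE potential diverges at 1.5 sigma.")
  }
  M <- as.integer(M)
  a <- 4 * (M + 1) * bond_spacing / sqrt(3)
  g <- diamond_lattice_graph(nx, ny, nz, periodic = FALSE)
  n_nodes <- nrow(g$nodes)
  n_sub <- nrow(g$bonds)
  node_xyz <- g$nodes * (a / 4)

  # interior subchain beads: M per lattice bond, equally spaced
  tfrac <- seq_len(M) / (M + 1)
  p1 <- node_xyz[g$bonds[, 1], , drop = FALSE]
  p2 <- node_xyz[g$bonds[, 2], , drop = FALSE]
  rep1 <- rep(seq_len(n_sub), each = M)
  tt <- rep(tfrac, times = n_sub)
  chain_xyz <- p1[rep1, , drop = FALSE] + tt * (p2[rep1, , drop = FALSE] - p1[rep1, , drop = FALSE])

  xyz <- rbind(node_xyz, chain_xyz)
  n_beads <- n_nodes + M * n_sub
  role <- rep(c("crosslink", "chain"), c(n_nodes, M * n_sub))

  # bonds along each subchain: node - b1 - b2 - ... - bM - node
  first_bead <- n_nodes + (seq_len(n_sub) - 1L) * M + 1L
  bi <- bj <- matrix(0L, n_sub, M + 1L)
  bi[, 1] <- g$bonds[, 1]
  bj[, 1] <- first_bead
  if (M > 1) {
    for (k in seq_len(M - 1L)) {
      bi[, k + 1L] <- first_bead + k - 1L
      bj[, k + 1L] <- first_bead + k
    }
  }
  bi[, M + 1L] <- first_bead + M - 1L
  bj[, M + 1L] <- g$bonds[, 2]

  beads <- tibble(
    id = seq_len(n_beads),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    role = role, charge = 0
  )
  bonds <- tibble(i = as.integer(t(bi)), j = as.integer(t(bj)))

  axis <- .find_axis_chain(g$nodes, node_xyz, nx, ny, a)
  topo <- structure(list(
    beads = beads, bonds = bonds,
    axis_chain = axis$ids, axis_xy = axis$xy,
    M = M, cell_counts = c(nx = nx, ny = ny, nz = nz),
    bond_spacing = bond_spacing, cell_edge = a,
    L0 = diff(range(node_xyz[axis$ids, 3])),
    R0_cyl = NA_real_, radius = NA_real_, f = 0,
    charge_seed = NA_integer_
  ), class = "gel_topology")
  topo
}

# Pick the straight column of cross-links, parallel to z, that the cylinder
# axis passes through: among full-height node columns (one node per cell,
# spacing a), take the one closest to the transverse template centre.
.find_axis_chain <- function(nodes_q, node_xyz, nx, ny, a) {
  colkey <- paste(nodes_q[, 1], nodes_q[, 2])
  cnt <- table(colkey)
  full <- names(cnt)[cnt == max(cnt)]
  qxy <- do.call(rbind, strsplit(full, " "))
  storage.mode(qxy) <- "double"
  xy <- qxy * (a / 4)
  centre <- c(nx, ny) * a / 2
  d2 <- (xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2
  pick <- full[which.min(d2)]
  ids <- which(colkey == pick)
  ids <- ids[order(node_xyz[ids, 3])]
  list(ids = as.integer(ids), xy = xy[which.min(d2), ])
}

#' Cut a cylindrical microgel out of a template
#'
#' Inscribes a cylinder into a diamond-lattice template: the cylinder axis is
#' the template's long (z) axis passing through a straight column of
#' cross-links, and every bead strictly farther than `radius` from the axis
#' is cut off together with its bonds. Fragments left disconnected from the
#' main (axis-containing) network component are dropped; dangling subchain
#' stubs that remain bonded to the network are kept.
#'
#' @param template A `gel_topology` from [build_diamond_template()].
#' @param radius Cylinder radius in sigma, or `"max-fit"` (default) for the
#'   largest cylinder that fits inside the template cross-section.
#' @return A `gel_topology` with beads renumbered, the surviving
#'   `axis_chain` in axial order, and the preparation-state geometry
#'   recorded: length `L0` (axial extent of the axis chain), radius
#'   `R0_cyl`, and realized aspect ratio `A0 = L0 / (2 R0_cyl)`.
#' @examples
#' topo <- build_diamond_template(2, 2, 8, M = 3) |> inscribe_cylinder()
#' topo$A0
#' @export
inscribe_cylinder <- function(template, radius = "max-fit") {
  stopifnot(inherits(template, "gel_topology"))
  a <- template$cell_edge
  ax <- template$axis_xy
  nxy <- template$cell_counts[c("nx", "ny")]
  maxfit <- min(ax[1], nxy[1] * a - ax[1], ax[2], nxy[2] * a - ax[2])
  if (identical(radius, "max-fit")) radius <- maxfit
  if (!is.numeric(radius) || radius <= 0) {
    abort("`radius` must be a positive length in sigma or \"max-fit\".")
  }
  beads <- template$beads
  r2 <- (beads$x - ax[1])^2 + (beads$y - ax[2])^2
  keep <- r2 <= radius^2 + 1e-9
  if (!any(keep)) abort("cylinder of this radius contains no beads")
  if (!all(keep[template$axis_chain])) {
    abort("`radius` would cut beads of the axis cross-link chain; increase it.")
  }
  new_id <- cumsum(keep)
  bonds <- template$bonds
  bkeep <- keep[bonds$i] & keep[bonds$j]
  bonds <- tibble(i = new_id[bonds$i[bkeep]], j = new_id[bonds$j[bkeep]])
  beads <- beads[keep, ]
  beads$id <- seq_len(nrow(beads))
  axis_chain <- new_id[template$axis_chain]

  # keep only the connected component that contains the axis chain
  g <- igraph::graph_from_edgelist(as.matrix(bonds), directed = FALSE)
  if (igraph::vcount(g) < nrow(beads)) {
    g <- igraph::add_vertices(g, nrow(beads) - igraph::vcount(g))
  }
  comp <- igraph::components(g)$membership
  main <- comp[axis_chain[1]]
  if (!all(comp[axis_chain] == main)) {
    abort("axis chain fragmented after cutting; choose a larger radius.")
  }
  keep2 <- comp == main
  if (!all(keep2)) {
    new_id2 <- cumsum(keep2)
    bkeep2 <- keep2[bonds$i] & keep2[bonds$j]
    bonds <- tibble(i = new_id2[bonds$i[bkeep2]], j = new_id2[bonds$j[bkeep2]])
    beads <- beads[keep2, ]
    beads$id <- seq_len(nrow(beads))
    axis_chain <- new_id2[axis_chain]
  }

  out <- template
  out$beads <- beads
  out$bonds <- bonds
  out$axis_chain <- as.integer(axis_chain)
  out$radius <- radius
  out$R0_cyl <- radius
  out$L0 <- diff(range(beads$z[axis_chain]))
  out$A0 <- out$L0 / (2 * radius)
  out
}

#' Randomly assign charged groups to a network
#'
#' Marks `round(f * N)` network beads, chosen uniformly at random, as
#' monovalent cationic charged groups (+1 e). Any bead — cross-link or chain
#' monomer — is eligible. The selection is a pure function of
#' `(topology, f, seed)`.
#'
#' @param topology A `gel_topology`.
#' @param f Fraction of charged groups, between 0 and 1 (the studied range
#'   is 0 to 0.5).
#' @param seed Integer seed for the random selection.
#' @return The topology with `beads$charge` set (0 or +1) and `f` recorded.
#' @export
assign_charges <- function(topology, f, seed = 1L) {
  stopifnot(inherits(topology, "gel_topology"))
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1) {
    abort("`f` must be a single fraction in [0, 1].")
  }
  n <- nrow(topology$beads)
  n_charged <- round(f * n)
  topology$beads$charge <- 0
  if (n_charged > 0) {
    pick <- withr::with_seed(seed, sample.int(n, n_charged))
    topology$beads$charge[pick] <- 1
  }
  topology$f <- f
  topology$charge_seed <- as.integer(seed)
  topology
}

#' Assemble a charge-neutral periodic simulation system
#'
#' Centres the network in a periodic box and adds one monovalent counterion
#' (-1 e) per charged network bead, placed uniformly at random in the box
#' while avoiding core overlap (closer than 0.9 sigma) with network beads,
#' so that the total system charge is exactly zero.
#'
#' @param topology A (typically inscribed and charged) `gel_topology`.
#' @param box Numeric length-3 box edge lengths in sigma, or `NULL` for an
#'   automatic box: `Lx = Ly = 3 * 2 R0_cyl` transverse to the cylinder and
#'   `Lz = 1.5 L0 + 2 * 2 R0_cyl` along it — room to swell, a
#'   solution-to-gel volume ratio of the same order as the reference
#'   cluster-scale setup, and counterions close enough to exchange with the
#'   gel within desk-scale runs.
#' @param seed Integer seed for counterion placement.
#' @return A `gel_system`: the topology, a `counterions` tibble, the box,
#'   and the placement seed. Network beads are translated so the gel sits at
#'   the box centre.
#' @export
make_system <- function(topology, box = NULL, seed = 1L) {
  stopifnot(inherits(topology, "gel_topology"))
  beads <- topology$beads
  ext <- vapply(beads[, c("x", "y", "z")], function(v) diff(range(v)), 0)
  if (is.null(box)) {
    if (is.na(topology$R0_cyl)) {
      box <- pmax(2.5 * ext, ext + 20)
    } else {
      d0 <- 2 * topology$R0_cyl
      box <- c(3 * d0, 3 * d0, 1.5 * topology$L0 + 2 * d0)
    }
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) abort("`box` must be three positive lengths.")
  if (any(box < ext - 1e-9)) {
    abort("`box` is smaller than the template bounding box; the network does not fit.")
  }
  # centre the network in the box
  for (d in c("x", "y", "z")) {
    beads[[d]] <- beads[[d]] - mean(range(beads[[d]])) + box[match(d, c("x", "y", "z"))] / 2
  }
  n_ci <- sum(beads$charge > 0)
  ci <- withr::with_seed(seed, .place_counterions(n_ci, box,
                                                  as.matrix(beads[, c("x", "y", "z")])))
  topology$beads <- beads
  structure(list(
    topology = topology,
    counterions = tibble(id = seq_len(n_ci) + nrow(beads),
                         x = ci[, 1], y = ci[, 2], z = ci[, 3],
                         charge = rep(-1, n_ci)),
    box = box,
    placement_seed = as.integer(seed)
  ), class = "gel_system")
}

.place_counterions <- function(n, box, net_xyz, min_dist = 0.9) {
  if (n == 0) return(matrix(0, 0, 3))
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    cand <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]), runif(m, 0, box[3]))
    ok <- cpp_min_dist_to_set(cand, net_xyz, box) >= min_dist
    if (nrow(out) > 0) {
      ok <- ok & cpp_min_dist_to_set(cand, out, box) >= min_dist
    }
    cand <- cand[ok, , drop = FALSE]
    # core overlap must also be avoided within the accepted batch itself
    if (nrow(cand) > 1) {
      keep <- rep(TRUE, nrow(cand))
      for (i in seq_len(nrow(cand) - 1L)) {
        if (!keep[i]) next
        d <- cpp_min_dist_to_set(cand[(i + 1):nrow(cand), , drop = FALSE],
                                 cand[i, , drop = FALSE], box)
        keep[(i + 1):nrow(cand)] <- keep[(i + 1):nrow(cand)] & d >= min_dist
      }
      cand <- cand[keep, , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Cross-link fraction of a network
#'
#' Fraction of tetrafunctional cross-link beads among all network beads.
#' For an infinite diamond-lattice network with subchain length `M` this
#' converges to `1/(2M + 1)`; finite templates are slightly higher because
#' boundary nodes carry fewer attached subchains.
#'
#' @param topology A `gel_topology`.
#' @return A single fraction in (0, 1).
#' @seealso [crosslink_fraction_limit()]
#' @export
crosslink_fraction <- function(topology) {
  stopifnot(inherits(topology, "gel_topology"))
  mean(topology$beads$role == "crosslink")
}

#' Bulk (large-template limit) cross-link fraction
#'
#' Computes the infinite-lattice cross-link fraction for subchain length `M`
#' from the periodic bookkeeping of the same diamond-cell machinery used by
#' the builder: a periodic conventional cell carries 8 nodes and 16
#' node-node bonds, each bond contributing `M` chain beads, so the fraction
#' is `8 / (8 + 16 M) = 1/(2M + 1)`. Evaluated by enumeration, not by
#' formula.
#'
#' @param M Subchain length (beads between cross-links).
#' @return The limiting cross-link fraction.
#' @export
crosslink_fraction_limit <- function(M) {
  stopifnot(M >= 1)
  g <- diamond_lattice_graph(1, 1, 1, periodic = TRUE)
  n_nodes <- nrow(g$nodes)
  n_bonds <- nrow(g$bonds)
  n_nodes / (n_nodes + n_bonds * as.integer(M))
}

#' @export
print.gel_topology <- function(x, ...) {
  n <- nrow(x$beads)
  cat("<gel_topology> ", n, " beads, ", nrow(x$bonds), " bonds; M = ", x$M,
      ", cells ", paste(x$cell_counts, collapse = "x"), "\n", sep = "")
  if (!is.na(x$R0_cyl)) {
    cat("  cylinder: L0 = ", signif(x$L0, 4), " sigma, R0 = ",
        signif(x$R0_cyl, 4), " sigma, A0 = ", signif(x$A0, 4), "\n", sep = "")
  }
  if (x$f > 0) {
    cat("  charged groups: f = ", x$f, " (", sum(x$beads$charge > 0),
        " beads)\n", sep = "")
  }
  invisible(x)
}

#' @export
print.gel_system <- function(x, ...) {
  cat("<gel_system> ", nrow(x$topology$beads), " network beads + ",
      nrow(x$counterions), " counterions in box ",
      paste(signif(x$box, 4), collapse = " x "), " sigma\n", sep = "")
  invisible(x)
}
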