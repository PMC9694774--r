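# Interchange formats: LAMMPS data ("full" atom style) and dump, XYZ,
# CSV/JSON observable tables with a checksummed run manifest, YAML configs.
# Coordinates are kept unwrapped internally and wrapped only on export;
# LAMMPS files use 1-based atom ids.

.fmt <- function(x) formatC(x, format = "g", digits = 10)

.wrap_coords <- function(p, box) {
  p - sweep(floor(sweep(p, 2, box, "/")), 2, box, "*")
}

#' Write a system as a LAMMPS data file
#'
#' Emits a LAMMPS data file in the `full` atom style (atom-ID, molecule-ID,
#' type, charge, x y z) with a Bonds section for the FENE springs. Atom
#' type 1 is a network bead, type 2 a counterion; the network is molecule
#' 1, counterions molecule 2. Coordinates are wrapped into the box.
#'
#' @param system A `gel_system` (or the result of [read_lammps_data()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(system, path) {
  if (inherits(system, "gel_system")) {
    b <- system$topology$beads
    ci <- system$counterions
    atoms <- tibble(
      id = c(b$id, ci$id),
      mol = c(rep(1L, nrow(b)), rep(2L, nrow(ci))),
      type = c(rep(1L, nrow(b)), rep(2L, nrow(ci))),
      q = c(b$charge, ci$charge),
      x = c(b$x, ci$x), y = c(b$y, ci$y), z = c(b$z, ci$z)
    )
    bonds <- system$topology$bonds
    box <- system$box
  } else if (inherits(system, "lammps_data")) {
    atoms <- system$atoms
    bonds <- system$bonds
    box <- system$box
  } else {
    abort("`system` must be a gel_system or lammps_data object")
  }
  p <- .wrap_coords(cbind(atoms$x, atoms$y, atoms$z), box)
  lines <- c(
    "LAMMPS data file generated by cylgel",
    "",
    paste(nrow(atoms), "atoms"),
    paste(nrow(bonds), "bonds"),
    "2 atom types",
    "1 bond types",
    "",
    paste("0", .fmt(box[1]), "xlo xhi"),
    paste("0", .fmt(box[2]), "ylo yhi"),
    paste("0", .fmt(box[3]), "zlo zhi"),
    "",
    "Masses",
    "",
    "1 1",
    "2 1",
    "",
    "Atoms # full",
    "",
    paste(atoms$id, atoms$mol, atoms$type, .fmt(atoms$q),
          .fmt(p[, 1]), .fmt(p[, 2]), .fmt(p[, 3])),
    "",
    "Bonds",
    "",
    paste(seq_len(nrow(bonds)), 1L, bonds[[1]], bonds[[2]])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a LAMMPS data file (full atom style)
#'
#' @param path File written by [write_lammps_data()] (or stock LAMMPS,
#'   full style, orthogonal box).
#' @return A `lammps_data` object: tibbles `atoms` (`id, mol, type, q, x,
#'   y, z`, sorted by id) and `bonds` (`i, j`), plus `box`.
#' @export
read_lammps_data <- function(path) {
  ln <- readLines(path)
  grab_count <- function(what) {
    m <- grep(paste0("^\\s*\\d+\\s+", what, "\\s*$"), ln, value = TRUE)
    if (!length(m)) abort(sprintf("malformed data file: missing '%s' count", what))
    as.integer(sub("\\s*(\\d+).*", "\\1", m[1]))
  }
  na <- grab_count("atoms")
  nb <- grab_count("bonds")
  box <- vapply(c("xlo xhi", "ylo yhi", "zlo zhi"), function(tag) {
    m <- grep(tag, ln, fixed = TRUE, value = TRUE)
    if (!length(m)) abort(sprintf("malformed data file: missing '%s'", tag))
    v <- as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][1:2])
    v[2] - v[1]
  }, 0)
  section <- function(name, n) {
    i <- grep(paste0("^", name, "\\b"), ln)
    if (!length(i)) abort(sprintf("malformed data file: no '%s' section", name))
    block <- ln[(i[1] + 2):(i[1] + 1 + n)]
    if (anyNA(block) || any(block == "")) {
      abort(sprintf("truncated '%s' section: expected %d rows", name, n))
    }
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  }
  am <- section("Atoms", na)
  bm <- section("Bonds", nb)
  atoms <- tibble(id = as.integer(am[, 1]), mol = as.integer(am[, 2]),
                  type = as.integer(am[, 3]), q = am[, 4],
                  x = am[, 5], y = am[, 6], z = am[, 7])
  atoms <- atoms[order(atoms$id), ]
  structure(list(
    atoms = atoms,
    bonds = tibble(i = as.integer(bm[, 3]), j = as.integer(bm[, 4])),
    box = unname(box)
  ), class = "lammps_data")
}

#' Write trajectory frames as a LAMMPS dump file
#'
#' Custom dump with per-atom `id type q x y z`; one snapshot per recorded
#' frame. Coordinates are wrapped into the periodic box on export.
#'
#' @param traj A `gel_trajectory`, or a list of `gel_frame` tibbles.
#' @param path Output file path.
#' @param box Required when `traj` is a list of frames without box
#'   attributes.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, box = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(step, ids, types, q, p, box) {
    p <- .wrap_coords(p, box)
    writeLines(c(
      "ITEM: TIMESTEP", as.character(step),
      "ITEM: NUMBER OF ATOMS", as.character(nrow(p)),
      "ITEM: BOX BOUNDS pp pp pp",
      paste("0", .fmt(box[1])), paste("0", .fmt(box[2])), paste("0", .fmt(box[3])),
      "ITEM: ATOMS id type q x y z",
      paste(ids, types, .fmt(q), .fmt(p[, 1]), .fmt(p[, 2]), .fmt(p[, 3]))
    ), con)
  }
  if (inherits(traj, "gel_trajectory")) {
    ids <- seq_along(traj$species)
    types <- traj$species + 1L
    step0 <- 0L
    for (k in seq_along(traj$stages)) {
      for (m in seq_along(traj$stages[[k]])) {
        step0 <- step0 + traj$frame_every
        emit(step0, ids, types, traj$charge, traj$stages[[k]][[m]], traj$box)
      }
    }
  } else {
    if (inherits(traj, "gel_frame")) traj <- list(traj)
    for (m in seq_along(traj)) {
      fr <- traj[[m]]
      b <- box %||% attr(fr, "box")
      if (is.null(b)) abort("no box: supply `box` or use frames with a box attribute")
      emit(m, fr$id, ifelse(fr$species == "network", 1L, 2L), fr$charge,
           .xyz_matrix(fr), b)
    }
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Reads `id type q x y z` dump snapshots. Coordinates in a dump are
#' wrapped periodic images; the returned frames carry `wrapped = TRUE` so
#' shape measurements know to pass them through [unwrap_frame()] first.
#'
#' @param path Dump file path.
#' @return List of `gel_frame` tibbles (type 1 = network, 2 = counterion).
#' @export
read_lammps_dump <- function(path) {
  ln <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", ln)
  if (!length(starts)) abort("not a LAMMPS dump: no 'ITEM: TIMESTEP' found")
  frames <- vector("list", length(starts))
  bounds <- c(starts, length(ln) + 1L)
  for (k in seq_along(starts)) {
    blk <- ln[bounds[k]:(bounds[k + 1] - 1L)]
    fail <- function(why) abort(sprintf("truncated dump frame %d: %s", k, why))
    if (length(blk) < 10) fail("incomplete header")
    step <- as.integer(blk[2])
    n <- as.integer(blk[4])
    box <- vapply(6:8, function(i) {
      v <- as.numeric(strsplit(trimws(blk[i]), "\\s+")[[1]])
      v[2] - v[1]
    }, 0)
    hdr <- grep("^ITEM: ATOMS", blk)
    if (!length(hdr)) fail("no ATOMS section")
    rows <- blk[(hdr[1] + 1L):length(blk)]
    rows <- rows[nzchar(rows)]
    if (length(rows) < n) fail(sprintf("expected %d atoms, found %d", n, length(rows)))
    am <- do.call(rbind, lapply(strsplit(trimws(rows[seq_len(n)]), "\\s+"), as.numeric))
    if (anyNA(am)) fail("non-numeric atom record")
    ord <- order(am[, 1])
    am <- am[ord, , drop = FALSE]
    fr <- new_gel_frame(tibble(
      id = as.integer(am[, 1]),
      species = ifelse(am[, 2] == 1, "network", "counterion"),
      charge = am[, 3],
      x = am[, 4], y = am[, 5], z = am[, 6]
    ), box = box)
    attr(fr, "wrapped") <- TRUE
    attr(fr, "step") <- step
    frames[[k]] <- fr
  }
  frames
}

#' Write frames in XYZ format
#'
#' Plain XYZ (element symbol + coordinates): network beads are written as
#' `P`, counterions as `C`. XYZ carries no charges; observables that need
#' charges will refuse frames read back from XYZ.
#'
#' @param frames A `gel_frame` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "gel_frame") || is.data.frame(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    sym <- if ("species" %in% names(fr)) ifelse(fr$species == "network", "P", "C")
           else rep("P", nrow(fr))
    writeLines(c(
      as.character(nrow(fr)),
      "generated by cylgel",
      paste(sym, .fmt(fr$x), .fmt(fr$y), .fmt(fr$z))
    ), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file path.
#' @return List of `gel_frame` tibbles without charges (`charge` absent).
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n)) abort(sprintf("malformed XYZ frame %d: bad atom count '%s'", k, ln[i]))
    if (i + 1L + n > length(ln)) {
      abort(sprintf("truncated XYZ frame %d: expected %d atoms", k, n))
    }
    rows <- strsplit(trimws(ln[(i + 2L):(i + 1L + n)]), "\\s+")
    sym <- vapply(rows, `[`, "", 1L)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[2:4])))
    if (anyNA(m)) abort(sprintf("malformed XYZ frame %d: non-numeric coordinates", k))
    frames[[k]] <- new_gel_frame(tibble(
      id = seq_len(n),
      species = ifelse(sym == "C", "counterion", "network"),
      x = m[, 1], y = m[, 2], z = m[, 3]
    ))
    i <- i + 2L + n
  }
  frames
}

#' Write sweep results as CSV/JSON tables with a run manifest
#'
#' Writes `observables.csv` (one row per solvent quality), one radial
#' profile CSV per stage, `config.yaml`, `observables.json`, and
#' `manifest.json` holding the configuration snapshot, seeds, package
#' version, and an MD5 checksum inventory of every written file.
#'
#' @param sweep A `gel_sweep` from [run_sweep()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_tables <- function(sweep, dir) {
  stopifnot(inherits(sweep, "gel_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  obs_path <- file.path(dir, "observables.csv")
  utils::write.csv(sweep$observables, obs_path, row.names = FALSE)
  files <- c(files, "observables.csv")
  jsonlite::write_json(sweep$observables, file.path(dir, "observables.json"),
                       dataframe = "rows", digits = NA)
  files <- c(files, "observables.json")
  for (k in seq_along(sweep$profiles)) {
    if (is.null(sweep$profiles[[k]])) next
    fn <- sprintf("profile_eps_%s.csv", gsub("\\.", "p", format(sweep$observables$eps[k])))
    utils::write.csv(as.data.frame(sweep$profiles[[k]]), file.path(dir, fn),
                     row.names = FALSE)
    files <- c(files, fn)
  }
  yaml::write_yaml(unclass(sweep$config), file.path(dir, "config.yaml"))
  files <- c(files, "config.yaml")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "cylgel",
    version = as.character(utils::packageVersion("cylgel")),
    seed = sweep$config$seed,
    files = setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Reload sweep tables, verifying the manifest
#'
#' Recomputes the MD5 checksum of every file listed in `manifest.json` and
#' refuses to load if any differs (tamper/corruption guard).
#'
#' @param dir Directory written by [write_sweep_tables()].
#' @return List with `observables` (tibble), `profiles` (named list of
#'   tibbles), `config`, and `manifest`.
#' @export
read_sweep_tables <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) abort("no manifest.json in this directory")
  manifest <- jsonlite::read_json(man_path)
  for (fn in names(manifest$files)) {
    actual <- unname(tools::md5sum(file.path(dir, fn)))
    if (is.na(actual) || actual != manifest$files[[fn]]) {
      abort(sprintf("checksum mismatch for '%s': file missing or modified", fn))
    }
  }
  prof_files <- grep("^profile_", names(manifest$files), value = TRUE)
  profiles <- lapply(prof_files, function(fn) {
    as_tibble(utils::read.csv(file.path(dir, fn)))
  })
  names(profiles) <- prof_files
  list(
    observables = as_tibble(utils::read.csv(file.path(dir, "observables.csv"))),
    profiles = profiles,
    config = yaml::read_yaml(file.path(dir, "config.yaml")),
    manifest = manifest
  )
}

#' Save / load a sweep configuration as YAML
#'
#' @param config A [sweep_config()].
#' @param path YAML file path.
#' @return `path` (write) or the `sweep_config` (read).
#' @export
write_sweep_config <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sweep_config, x)
}
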