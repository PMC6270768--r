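# Trajectory container and I/O (multi-model PDB).

#' Build a trajectory object
#'
#' @param coords Numeric array frames x atoms x 3, Angstrom.
#' @param times Per-frame timestamps, ps (strictly increasing); default
#'   `1:frames`.
#' @param atoms Optional `pc_structure` (or atom tibble) labelling the
#'   atom dimension.
#' @return List of class `md_trajectory` with `coords`, `times`, `atoms`.
#' @export
as_trajectory <- function(coords, times = NULL, atoms = NULL) {
  coords <- unclass(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be a frames x atoms x 3 array")
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf)
  if (length(times) != nf) abort("times must have one entry per frame")
  if (nf > 1 && any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (!is.null(atoms)) {
    atoms <- as_structure(atoms)
    if (nrow(atoms) != dim(coords)[2]) {
      abort("atoms table does not match the trajectory's atom count")
    }
  }
  structure(list(coords = coords, times = as.numeric(times), atoms = atoms),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<md_trajectory> ", d[1], " frames x ", d[2], " atoms; t = ",
      format(x$times[1]), " .. ", format(x$times[d[1]]), " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) dim(t$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param t An `md_trajectory`.
#' @param frame Frame index.
#' @return Matrix (atoms x 3).
#' @export
frame_coords <- function(t, frame) {
  nf <- n_frames(t)
  if (frame < 1 || frame > nf) abort("frame index out of range")
  m <- t$coords[frame, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame (parsed via bio3d); atom labels come
#' from the first model.
#'
#' @param path Path to a multi-model PDB file.
#' @param dt_ps Time spacing assigned to successive frames, ps (default 1).
#' @return An `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, dt_ps = 1) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  arr <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  first <- as_structure(tibble(
    serial = as.integer(pdb$atom$eleno),
    name = trimws(pdb$atom$elety),
    element = .guess_element(pdb$atom$elety,
                             ifelse(is.na(pdb$atom$elesy), "", pdb$atom$elesy)),
    res_name = trimws(pdb$atom$resid),
    res_number = as.integer(pdb$atom$resno),
    chain = ifelse(is.na(pdb$atom$chain) | pdb$atom$chain == "", "A",
                   pdb$atom$chain),
    x = arr[1, , 1], y = arr[1, , 2], z = arr[1, , 3]
  ))
  as_trajectory(arr, times = seq_len(nf) * dt_ps, atoms = first)
}

.pdb_atom_line <- function(serial, name, res_name, chain, res_number,
                           x, y, z, element, hetatm = FALSE) {
  rec <- if (hetatm) "HETATM" else "ATOM  "
  name_fmt <- ifelse(nchar(name) < 4, sprintf(" %-3s", name),
                     sprintf("%-4s", name))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000, name_fmt, substr(res_name, 1, 3), chain,
          res_number %% 10000, x, y, z, 1.0, 0.0, element)
}

#' Write a trajectory as a multi-model PDB
#'
#' Emits standard MODEL/ENDMDL blocks of ATOM records, one per frame, with
#' a REMARK header recording frame times.
#'
#' @param t An `md_trajectory` with an `atoms` table.
#' @param path Output path.
#' @param header Optional extra REMARK comment lines.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(t, path, header = character(0)) {
  if (is.null(t$atoms)) abort("trajectory has no atom labels to write")
  a <- t$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("REMARK    ", h), con)
  writeLines(sprintf("REMARK     frames %d dt_ps %g", n_frames(t),
                     if (n_frames(t) > 1) t$times[2] - t$times[1] else 0), con)
  for (f in seq_len(n_frames(t))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(t, f)
    lines <- .pdb_atom_line(a$serial, a$name, a$res_name, a$chain,
                            a$res_number, xyz[, 1], xyz[, 2], xyz[, 3],
                            a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write the activated cast particles as a PDB file
#'
#' Active particles are emitted as HETATM records (element X, residue CST),
#' one MODEL per requested snapshot.
#'
#' @param cast An `asp_cast`.
#' @param path Output path.
#' @param events Which activation events to write (default: final only).
#' @param positions `"lattice"` (anchor sites, default) or
#'   `"instantaneous"` (saved dynamical coordinates).
#' @return `path`, invisibly.
#' @export
write_cast_pdb <- function(cast, path, events = NULL,
                           positions = c("lattice", "instantaneous")) {
  positions <- match.arg(positions)
  n_ev <- nrow(cast$activation_log)
  if (is.null(events)) events <- n_ev
  if (any(events < 1 | events > n_ev)) abort("event index out of range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK     cast snapshots; seed %d", cast$seed), con)
  for (ev in events) {
    xyz <- if (positions == "lattice") {
      cast_lattice_positions(cast, n_active = ev + 1L)
    } else {
      cast$active_positions[[ev]]
    }
    writeLines(sprintf("MODEL     %4d", ev), con)
    n <- nrow(xyz)
    writeLines(.pdb_atom_line(seq_len(n), rep("X", n), rep("CST", n),
                              rep("P", n), seq_len(n),
                              xyz[, 1], xyz[, 2], xyz[, 3],
                              rep("X", n), hetatm = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
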