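# Structure I/O: PDB reading/writing behind a tibble-of-atoms surface.

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, X = 10.0
)

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))

.guess_element <- function(name, elem) {
  elem <- toupper(trimws(elem))
  out <- ifelse(nzchar(elem), elem, toupper(substr(trimws(name), 1, 1)))
  out[!nzchar(out)] <- "C"
  out
}

.mass_from_element <- function(element) {
  m <- .element_masses[element]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Build a structure from an atom table
#'
#' A structure is a tibble of atom records with columns `serial`, `name`,
#' `element`, `res_name`, `res_number`, `chain`, `insert`, `x`, `y`, `z`,
#' `mass`, `occupancy`, `altloc`. Coordinates are in Angstrom, masses in Da.
#'
#' @param atoms Data frame with at least `name`, `res_name`, `res_number`,
#'   `x`, `y`, `z`; missing bookkeeping columns are filled with defaults.
#' @return A tibble of class `pc_structure`.
#' @export
as_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (n == 0L) abort("structure must contain at least one atom")
  has <- function(col) col %in% names(atoms)
  if (!has("serial")) atoms$serial <- seq_len(n)
  if (!has("chain")) atoms$chain <- "A"
  if (!has("insert")) atoms$insert <- ""
  if (!has("altloc")) atoms$altloc <- ""
  if (!has("occupancy")) atoms$occupancy <- 1
  if (!has("element")) atoms$element <- .guess_element(atoms$name, "")
  if (!has("mass")) atoms$mass <- .mass_from_element(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("all coordinates must be finite")
  if (any(atoms$mass <= 0)) abort("all masses must be positive")
  key <- paste(atoms$chain, atoms$res_number, atoms$insert, atoms$name,
               atoms$altloc)
  if (anyDuplicated(key)) {
    abort("duplicate atoms: (chain, res_number, insert, name, altloc) must be unique")
  }
  cols <- c("serial", "name", "element", "res_name", "res_number", "chain",
            "insert", "x", "y", "z", "mass", "occupancy", "altloc")
  atoms <- atoms[, c(cols, setdiff(names(atoms), cols))]
  class(atoms) <- c("pc_structure", class(atoms))
  atoms
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via bio3d) into an atom tibble. When a
#' position has alternate locations, the highest-occupancy altloc is kept;
#' ties resolve to altloc "A".
#'
#' @param path Path to a PDB file.
#' @return A `pc_structure` tibble.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) abort(paste0("no atom records in ", path))
  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = .guess_element(a$elety, ifelse(is.na(a$elesy), "", a$elesy)),
    res_name = trimws(a$resid),
    res_number = as.integer(a$resno),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", a$alt)
  )
  atoms$mass <- .mass_from_element(atoms$element)
  # altloc filter: highest occupancy, ties -> altloc "A" (then first)
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$res_number, .data$insert, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy),
                   .data$altloc != "A", .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)
  as_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' @param s A `pc_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  s <- as_structure(s)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$res_number, resid = s$res_name, eleno = s$serial,
    elety = s$name, chain = s$chain, insert = ifelse(nzchar(s$insert), s$insert, NA),
    o = s$occupancy, b = rep(0, nrow(s)), elesy = s$element
  )
  invisible(path)
}

#' Extract the coordinate matrix of a structure
#'
#' @param s A `pc_structure` (or any data frame with x, y, z columns).
#' @return A numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s) {
  m <- as.matrix(as.data.frame(s)[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a structure
#'
#' @param s A `pc_structure`.
#' @param xyz Matrix of new coordinates (atoms x 3).
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}
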