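# Residue-range parsing and backbone core-mask construction.
#
# A "core" mask selects the backbone atoms (N, CA, C; optionally O) of the
# structurally conserved residue ranges shared between compared structures,
# so that fluctuation and PCA analyses operate on identical atom sets.

#' Parse residue-range tokens
#'
#' Tokens have the printed form `"<start><aa?>-<end><aa?>"`, e.g. `"7L-33K"`:
#' residues 7 through 33 inclusive, with one-letter amino-acid identities
#' given for the endpoints. The letter codes are optional (`"7-33"`).
#'
#' @param tokens Character vector of range tokens.
#' @param chain Chain identifier the ranges refer to (default `"A"`).
#' @return A tibble with one row per token: `token`, `start_number`,
#'   `start_aa`, `end_number`, `end_aa`, `chain`, `n_residues`.
#' @examples
#' parse_residue_range("7L-33K")
#' @export
parse_residue_range <- function(tokens, chain = "A") {
  m <- regmatches(tokens,
                  regexec("^([0-9]+)([A-Za-z]?)-([0-9]+)([A-Za-z]?)$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    abort(paste0("malformed residue-range token(s): ",
                 paste(tokens[bad], collapse = ", ")))
  }
  out <- tibble(
    token = tokens,
    start_number = as.integer(vapply(m, `[`, "", 2L)),
    start_aa = toupper(vapply(m, `[`, "", 3L)),
    end_number = as.integer(vapply(m, `[`, "", 4L)),
    end_aa = toupper(vapply(m, `[`, "", 5L)),
    chain = chain
  )
  rev <- out$start_number > out$end_number
  if (any(rev)) {
    abort(paste0("range start exceeds end in token(s): ",
                 paste(tokens[rev], collapse = ", ")))
  }
  out$n_residues <- out$end_number - out$start_number + 1L
  out
}

.backbone_names <- function(include_o = FALSE) {
  if (include_o) c("N", "CA", "C", "O") else c("N", "CA", "C")
}

#' Build a backbone core mask from residue ranges
#'
#' Selects, for every residue covered by `ranges`, the backbone atoms in
#' residue-major order (N, CA, C within each residue; O appended when
#' `include_o = TRUE`). One-letter endpoint identities present in the range
#' tokens are validated against the structure's residue names.
#'
#' @param s A `pc_structure`.
#' @param ranges Character vector of range tokens, or the tibble returned by
#'   [parse_residue_range()].
#' @param chain Chain to select from (default `"A"`).
#' @param include_o Also include backbone carbonyl O atoms.
#' @return An `atom_mask`: list with integer `indices` into the atom table
#'   and a `labels` tibble (`res_number`, `atom_name`).
#' @export
build_core_mask <- function(s, ranges, chain = "A", include_o = FALSE) {
  s <- as_structure(s)
  if (is.character(ranges)) ranges <- parse_residue_range(ranges, chain = chain)
  bb <- .backbone_names(include_o)
  idx_all <- integer(0)
  for (r in seq_len(nrow(ranges))) {
    rr <- ranges[r, ]
    for (res in seq.int(rr$start_number, rr$end_number)) {
      sel <- which(s$chain == rr$chain & s$res_number == res & s$insert == "")
      if (length(sel) == 0L) {
        abort(paste0("residue ", res, " (chain ", rr$chain,
                     ") required by range '", rr$token,
                     "' is absent from the structure"))
      }
      # endpoint letter-code validation
      aa <- ""
      if (res == rr$start_number) aa <- rr$start_aa
      if (res == rr$end_number && nzchar(rr$end_aa)) aa <- rr$end_aa
      if (nzchar(aa)) {
        found3 <- unique(s$res_name[sel])[1]
        found1 <- unname(.aa3to1[found3])
        if (!is.na(found1) && found1 != aa) {
          abort(paste0("residue ", res, " is ", found3, " (", found1,
                       ") but range '", rr$token, "' names it ", aa))
        }
      }
      for (an in bb) {
        i <- sel[match(an, s$name[sel])]
        if (is.na(i)) {
          abort(paste0("residue ", res, " (chain ", rr$chain,
                       ") is missing backbone atom ", an))
        }
        idx_all <- c(idx_all, i)
      }
    }
  }
  new_atom_mask(idx_all, s, include_o)
}

new_atom_mask <- function(indices, s, include_o = FALSE) {
  stopifnot(!anyDuplicated(indices))
  structure(
    list(
      indices = as.integer(indices),
      labels = tibble(res_number = s$res_number[indices],
                      atom_name = s$name[indices]),
      include_o = include_o
    ),
    class = "atom_mask"
  )
}

#' @export
length.atom_mask <- function(x) length(x$indices)

#' @export
print.atom_mask <- function(x, ...) {
  cat("<atom_mask> ", length(x$indices), " atoms over ",
      length(unique(x$labels$res_number)), " residues",
      if (x$include_o) " (N, CA, C, O)" else " (N, CA, C)", "\n", sep = "")
  invisible(x)
}

.mask_indices <- function(mask, n_atoms) {
  if (is.null(mask)) return(seq_len(n_atoms))
  idx <- if (inherits(mask, "atom_mask")) mask$indices else as.integer(mask)
  if (any(idx < 1L | idx > n_atoms)) abort("mask indices out of bounds")
  idx
}
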