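#' Atomic structure container
#'
#' A cleaned atom table for one bioassembly: heavy atoms only, no waters,
#' one alternate location per site, with residues partitioned into subunits
#' by chain tag.  This is the common currency of the whole pipeline: the
#' parser produces it, the featurizer consumes it, and the synthetic
#' generator emulates it.
#'
#' @param atoms data.frame with columns `element` (uppercase symbol), `name`
#'   (atom name), `x`, `y`, `z` (Angstrom), `altloc` (code or ""), and
#'   `res_idx` (1-based index into `residues`).
#' @param residues data.frame with columns `name` (component code),
#'   `author_number` (number + insertion code as printed in the source file),
#'   `chain_tag` (subunit identifier).
#' @param source_id free-text provenance.
#'
#' @return An object of class `atomic_structure` with elements `atoms`,
#'   `residues`, `subunits` (list of residue index vectors, one per chain
#'   tag, covering every residue exactly once) and `source_id`.
#' @export
atomic_structure <- function(atoms, residues, source_id = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  req_a <- c("element", "name", "x", "y", "z", "altloc", "res_idx")
  req_r <- c("name", "author_number", "chain_tag")
  if (!all(req_a %in% names(atoms))) stop("atoms table is missing columns")
  if (!all(req_r %in% names(residues))) stop("residues table is missing columns")
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(!nzchar(atoms$element))) stop("atoms with empty element symbol")
  ri <- atoms$res_idx
  if (any(ri < 1L | ri > nrow(residues))) stop("res_idx out of range")
  if (!all(seq_len(nrow(residues)) %in% ri)) stop("residue without atoms")
  tags <- residues$chain_tag
  subunits <- split(seq_len(nrow(residues)), factor(tags, levels = unique(tags)))
  structure(list(atoms = atoms, residues = residues,
                 subunits = subunits, source_id = source_id),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("<atomic_structure> %d atoms, %d residues, %d subunits (%s)\n",
              nrow(x$atoms), nrow(x$residues), length(x$subunits),
              x$source_id))
  invisible(x)
}

#' Number of atoms / residues in a structure
#' @param structure an [atomic_structure()].
#' @return integer count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Atom coordinates as an N x 3 matrix (Angstrom)
#' @param structure an [atomic_structure()].
#' @return numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(structure) {
  cbind(x = structure$atoms$x, y = structure$atoms$y, z = structure$atoms$z)
}

#' Apply a rigid transform to a structure
#'
#' Rotates coordinates by `R` and then translates by `t`.  Used by the
#' equivariance checks and by fixture construction.
#'
#' @param structure an [atomic_structure()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (Angstrom).
#' @return the transformed [atomic_structure()].
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atom_coords(structure) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}

# residue index -> subunit (chain tag) position, as integer vector
residue_subunit_map <- function(structure) {
  m <- integer(n_residues(structure))
  for (s in seq_along(structure$subunits)) m[structure$subunits[[s]]] <- s
  m
}

# atom -> residue grouping helpers
atoms_of_residues <- function(structure, res_idx) {
  which(structure$atoms$res_idx %in% res_idx)
}
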