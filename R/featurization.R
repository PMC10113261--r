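# Featurization: element one-hot encoding, k-nearest-neighbour geometric
# graphs, subunit categorization, 5 Angstrom interface labelling and the
# interaction-type count matrix over the molecule catalogue.

#' Default element vocabulary
#'
#' The 30 element symbols used for one-hot encoding: the common organic
#' elements plus the metals and halides most frequent in deposited
#' structures.  Elements outside the vocabulary map to a reserved "unknown"
#' slot rather than erroring, so exotic entries degrade gracefully.
#'
#' @return character vector of 30 uppercase element symbols.
#' @export
default_element_vocab <- function() {
  c("C", "N", "O", "S", "P", "SE",
    "NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU", "CL", "BR", "I", "F",
    "NI", "CO", "CD", "HG", "W", "MO", "B", "SI", "AS", "V", "SR", "CS")
}

#' Default molecule catalogue
#'
#' Five disjoint lists of component codes: 20 standard amino acids, 8
#' nucleotides (RNA and DNA), 16 ions, 31 biological ligands and 4 lipids,
#' for a catalogue of 79 components in total.  The amino-acid and nucleotide
#' lists are canonical; the ion/ligand/lipid lists are editable defaults
#' chosen among the components most frequently seen in deposited structures.
#' The interaction-type matrix dimension adapts to whatever catalogue is
#' supplied.
#'
#' @return named list with elements `amino_acids`, `nucleic_acids`, `ions`,
#'   `ligands`, `lipids`.
#' @export
default_molecule_categories <- function() {
  list(
    amino_acids = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL"),
    nucleic_acids = c("A", "C", "G", "U", "DA", "DC", "DG", "DT"),
    ions = c("ZN", "MG", "CA", "NA", "K", "CL", "FE", "FE2",
             "MN", "CU", "NI", "CO", "CD", "HG", "SR", "CS"),
    ligands = c("HEM", "ATP", "ADP", "AMP", "ANP", "GTP", "GDP", "GNP",
                "NAD", "NAI", "NAP", "NDP", "FAD", "FMN", "SAM", "SAH",
                "COA", "ACO", "PLP", "TPP", "BTN", "B12", "GLC", "GAL",
                "MAN", "FUC", "NAG", "BMA", "SIA", "UDP", "RET"),
    lipids = c("CLR", "PLM", "OLA", "POV")
  )
}

#' Interface channel names
#' @return the five output channels, in canonical order.
#' @export
interface_channels <- function() {
  c("protein", "nucleic_acid", "ion", "ligand", "lipid")
}

#' Flat molecule catalogue
#' @param cats category lists, as [default_molecule_categories()].
#' @return character vector concatenating the five lists (length 79 for the
#'   default catalogue).
#' @export
molecule_catalogue <- function(cats = default_molecule_categories()) {
  unlist(cats, use.names = FALSE)
}

#' One-hot encode atom elements
#'
#' The element is the only per-atom input feature: no mass, radius, charge
#' or hydrophobicity enters the model.
#'
#' @param structure an [atomic_structure()].
#' @param vocab element vocabulary; defaults to the 30-symbol
#'   [default_element_vocab()].
#' @return binary matrix of size N x (length(vocab) + 1); the final column
#'   is the reserved unknown slot.  Exactly one 1 per row.
#' @export
encode_elements <- function(structure, vocab = default_element_vocab()) {
  if (anyDuplicated(vocab)) stop("element vocabulary has duplicates")
  el <- structure$atoms$element
  pos <- match(el, vocab)
  pos[is.na(pos)] <- length(vocab) + 1L
  m <- matrix(0, length(el), length(vocab) + 1L,
              dimnames = list(NULL, c(vocab, "UNK")))
  m[cbind(seq_along(el), pos)] <- 1
  m
}

#' Build a k-nearest-neighbour graph on atom coordinates
#'
#' For each atom, the `nn` nearest other atoms by Euclidean distance; ties
#' broken by ascending atom index and self excluded.  When fewer than `nn`
#' neighbours exist the remaining slots are flagged in `sink_mask` and carry
#' zero distance and zero displacement; downstream attention treats them as
#' sink nodes with zero state.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param nn neighbour count (>= 1).
#' @return a `neighbor_graph`: list with `idx` (N x nn, 1-based, 1 for sink
#'   slots), `dist` (N x nn, Angstrom), `rhat_x`/`rhat_y`/`rhat_z` (N x nn
#'   unit displacement components, (x_j - x_i)/d_ij), `sink_mask` (N x nn
#'   logical) and `nn`.
#' @export
build_knn_graph <- function(coords, nn) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (nrow(coords) < 1L) stop("need at least one atom")
  if (nn < 1L) stop("nn must be >= 1")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  res <- knn_cpp(coords, as.integer(nn))
  idx <- res$idx
  dist <- res$dist
  sink <- res$sink
  n <- nrow(coords)
  # displacement unit vectors; zero on sink slots
  j <- ifelse(sink, 1L, idx)
  dx <- matrix(coords[j, 1], n, nn) - coords[, 1]
  dy <- matrix(coords[j, 2], n, nn) - coords[, 2]
  dz <- matrix(coords[j, 3], n, nn) - coords[, 3]
  dsafe <- ifelse(dist > 0, dist, 1)
  rx <- ifelse(sink, 0, dx / dsafe)
  ry <- ifelse(sink, 0, dy / dsafe)
  rz <- ifelse(sink, 0, dz / dsafe)
  idx[sink] <- 1L
  structure(list(idx = idx, dist = dist,
                 rhat_x = rx, rhat_y = ry, rhat_z = rz,
                 sink_mask = sink, nn = as.integer(nn)),
            class = "neighbor_graph")
}

#' Categorize subunits into molecule classes
#'
#' A subunit is `protein` or `nucleic_acid` when more than half of its
#' residues carry codes from the respective list; single-residue subunits
#' are looked up in the ion/ligand/lipid lists; everything else (including
#' crystallization additives) is `ignored` and contributes no labels.
#'
#' @param structure an [atomic_structure()].
#' @param cats molecule catalogue, as [default_molecule_categories()].
#' @return character vector, one category per subunit (named by chain tag);
#'   values in `protein`, `nucleic_acid`, `ion`, `ligand`, `lipid`,
#'   `ignored`.
#' @export
categorize_subunits <- function(structure, cats = default_molecule_categories()) {
  out <- character(length(structure$subunits))
  names(out) <- names(structure$subunits)
  for (s in seq_along(structure$subunits)) {
    res_names <- structure$residues$name[structure$subunits[[s]]]
    n <- length(res_names)
    if (mean(res_names %in% cats$amino_acids) > 0.5) {
      out[s] <- "protein"
    } else if (mean(res_names %in% cats$nucleic_acids) > 0.5) {
      out[s] <- "nucleic_acid"
    } else if (n == 1L && res_names %in% cats$ions) {
      out[s] <- "ion"
    } else if (n == 1L && res_names %in% cats$ligands) {
      out[s] <- "ligand"
    } else if (n == 1L && res_names %in% cats$lipids) {
      out[s] <- "lipid"
    } else {
      out[s] <- "ignored"
    }
  }
  out
}

# minimum-distance contacts between two coordinate sets, strict cutoff;
# returns 2-column matrix of (row in A, row in B) index pairs, chunked so
# the full distance matrix is never materialised for large inputs.
cross_contacts <- function(A, B, cutoff, chunk = 1024L) {
  c2 <- cutoff^2
  nb2 <- rowSums(B^2)
  out <- list()
  nA <- nrow(A)
  for (start in seq(1L, nA, by = chunk)) {
    end <- min(start + chunk - 1L, nA)
    Ac <- A[start:end, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), nb2, "+") - 2 * tcrossprod(Ac, B)
    hit <- which(d2 < c2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      hit[, 1L] <- hit[, 1L] + start - 1L
      out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

#' Label interface residues by 5 Angstrom contacts
#'
#' A protein residue is an interface residue for channel `c` when any of its
#' heavy atoms lies strictly within `cutoff` of a heavy atom of a residue in
#' a *different* subunit of category `c`.  Structures are cleaned before
#' labelling, so all contacts are heavy-atom contacts.  Ignored subunits
#' contribute no labels.
#'
#' @param structure an [atomic_structure()].
#' @param categories per-subunit categories from [categorize_subunits()];
#'   computed if `NULL`.
#' @param cutoff contact distance in Angstrom (default 5.0, strict `<`).
#' @param cats molecule catalogue used when `categories` is `NULL`.
#' @return an `interface_labels` object: list with `labels` (binary matrix,
#'   protein residues x 5 channels), `residue_index` (row index into
#'   `structure$residues`), `channels`.
#' @export
label_interfaces <- function(structure, categories = NULL, cutoff = 5.0,
                             cats = default_molecule_categories()) {
  if (is.null(categories)) categories <- categorize_subunits(structure, cats)
  if (!any(categories == "protein")) stop("no protein subunit in structure")
  channels <- interface_channels()
  sub_of_res <- residue_subunit_map(structure)
  prot_subs <- which(categories == "protein")
  prot_res <- sort(unlist(structure$subunits[prot_subs], use.names = FALSE))
  lab <- matrix(0L, length(prot_res), length(channels),
                dimnames = list(NULL, channels))
  row_of_res <- integer(n_residues(structure))
  row_of_res[prot_res] <- seq_along(prot_res)
  xyz <- atom_coords(structure)
  res_of_atom <- structure$atoms$res_idx
  nsub <- length(structure$subunits)
  for (s in prot_subs) {
    as_idx <- which(sub_of_res[res_of_atom] == s)
    for (t in seq_len(nsub)) {
      if (t == s || categories[t] == "ignored") next
      at_idx <- which(sub_of_res[res_of_atom] == t)
      hits <- cross_contacts(xyz[as_idx, , drop = FALSE],
                             xyz[at_idx, , drop = FALSE], cutoff)
      if (nrow(hits) > 0L) {
        touched <- unique(res_of_atom[as_idx[hits[, 1L]]])
        lab[row_of_res[touched], categories[t]] <- 1L
      }
    }
  }
  structure(list(labels = lab, residue_index = prot_res, channels = channels),
            class = "interface_labels")
}

#' Interaction-type matrix over the molecule catalogue
#'
#' Counts residue pairs in contact (strictly within `cutoff`, across
#' different subunits) by the catalogue position of their component codes.
#' The matrix is symmetric by construction; channel labels for any subset of
#' the catalogue can be regenerated from the accompanying per-residue
#' contact table without re-measuring distances.
#'
#' @inheritParams label_interfaces
#' @return list with `counts` (M x M symmetric integer matrix, M the
#'   catalogue size, 79 by default), `residue_contacts` (residues x M counts
#'   of contacting partner residues by partner code) and `catalogue`.
#' @export
build_interaction_matrix <- function(structure, cutoff = 5.0,
                                     cats = default_molecule_categories()) {
  catalogue <- molecule_catalogue(cats)
  M <- length(catalogue)
  counts <- matrix(0L, M, M, dimnames = list(catalogue, catalogue))
  rc <- matrix(0L, n_residues(structure), M, dimnames = list(NULL, catalogue))
  sub_of_res <- residue_subunit_map(structure)
  xyz <- atom_coords(structure)
  res_of_atom <- structure$atoms$res_idx
  code_pos <- match(structure$residues$name, catalogue)
  nsub <- length(structure$subunits)
  if (nsub >= 2L) {
    for (s in seq_len(nsub - 1L)) {
      as_idx <- which(sub_of_res[res_of_atom] == s)
      for (t in seq.int(s + 1L, nsub)) {
        at_idx <- which(sub_of_res[res_of_atom] == t)
        hits <- cross_contacts(xyz[as_idx, , drop = FALSE],
                               xyz[at_idx, , drop = FALSE], cutoff)
        if (nrow(hits) == 0L) next
        pairs <- unique(cbind(res_of_atom[as_idx[hits[, 1L]]],
                              res_of_atom[at_idx[hits[, 2L]]]))
        for (k in seq_len(nrow(pairs))) {
          r1 <- pairs[k, 1L]; r2 <- pairs[k, 2L]
          c1 <- code_pos[r1]; c2 <- code_pos[r2]
          if (!is.na(c2)) rc[r1, c2] <- rc[r1, c2] + 1L
          if (!is.na(c1)) rc[r2, c1] <- rc[r2, c1] + 1L
          if (!is.na(c1) && !is.na(c2)) {
            counts[c1, c2] <- counts[c1, c2] + 1L
            counts[c2, c1] <- counts[c2, c1] + 1L
          }
        }
      }
    }
  }
  list(counts = counts, residue_contacts = rc, catalogue = catalogue)
}

#' Regenerate channel labels from a per-residue contact table
#'
#' Selects interface targets as any contact with a catalogue subset, the
#' mechanism that lets training channels be redefined without rebuilding the
#' dataset.
#'
#' @param im result of [build_interaction_matrix()].
#' @param structure the structure the matrix was built from.
#' @param categories per-subunit categories (for selecting protein residues).
#' @param cats molecule catalogue.
#' @return an `interface_labels` object comparable to [label_interfaces()].
#' @export
labels_from_interaction_matrix <- function(im, structure, categories = NULL,
                                           cats = default_molecule_categories()) {
  if (is.null(categories)) categories <- categorize_subunits(structure, cats)
  channels <- interface_channels()
  subsets <- list(protein = cats$amino_acids, nucleic_acid = cats$nucleic_acids,
                  ion = cats$ions, ligand = cats$ligands, lipid = cats$lipids)
  sub_of_res <- residue_subunit_map(structure)
  prot_subs <- which(categories == "protein")
  prot_res <- sort(unlist(structure$subunits[prot_subs], use.names = FALSE))
  lab <- matrix(0L, length(prot_res), length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    cols <- match(subsets[[ch]], im$catalogue)
    any_contact <- rowSums(im$residue_contacts[prot_res, cols, drop = FALSE]) > 0L
    lab[, ch] <- as.integer(any_contact)
  }
  structure(list(labels = lab, residue_index = prot_res, channels = channels),
            class = "interface_labels")
}
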