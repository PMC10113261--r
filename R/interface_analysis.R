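# Post-prediction analysis for predicted structure models: pLDDT/PAE
# quality gating, grouping of gated interface residues into patches by
# C-alpha linkage, patch quality filtering and overlap detection.

#' Per-residue pLDDT from a predicted-model PDB
#'
#' AlphaFold-style models store pLDDT (0-100) in the B-factor column; the
#' value of each residue's first atom is taken as the residue pLDDT.
#'
#' @param structure an [atomic_structure()] parsed from such a model.
#' @return numeric vector, one value per residue.
#' @export
residue_plddt <- function(structure) {
  if (is.null(structure$atoms$bfac)) stop("structure carries no B-factors")
  first <- !duplicated(structure$atoms$res_idx)
  out <- numeric(n_residues(structure))
  out[structure$atoms$res_idx[first]] <- structure$atoms$bfac[first]
  out
}

#' Read a predicted-aligned-error matrix from JSON
#'
#' Accepts either a bare square matrix or the AlphaFold-EBI container with
#' a `predicted_aligned_error` field.
#'
#' @param path JSON file.
#' @return square numeric matrix (Angstrom).
#' @export
read_pae_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(names(obj)) && !is.null(obj$predicted_aligned_error)) {
    obj <- obj$predicted_aligned_error
  } else if (is.null(names(obj)) && length(obj) >= 1L &&
             is.list(obj[[1]]) &&
             !is.null(obj[[1]]$predicted_aligned_error)) {
    obj <- obj[[1]]$predicted_aligned_error
  }
  m <- do.call(rbind, lapply(obj, function(r) as.numeric(unlist(r))))
  if (nrow(m) != ncol(m)) stop("PAE matrix must be square")
  if (any(m < 0)) stop("PAE must be non-negative")
  m
}

#' Model-quality gate for predicted structures
#'
#' A model passes when at least 70 percent of its residues have pLDDT
#' above 70 and (when a PAE matrix is available) the mean predicted aligned
#' error over ordered pairs of distinct well-folded residues (pLDDT > 70)
#' is below 10 Angstrom.  Models without PAE pass on the pLDDT condition
#' alone, flagged in the `"pae_missing"` attribute.
#'
#' @param plddt per-residue pLDDT in `[0, 100]`.
#' @param pae optional square PAE matrix (Angstrom).
#' @param min_fraction pLDDT coverage threshold (default 0.70, inclusive).
#' @param plddt_gate well-folded threshold (default 70, strict `>`).
#' @param max_mean_pae PAE threshold (default 10, strict `<`).
#' @return logical.
#' @export
model_quality_filter <- function(plddt, pae = NULL, min_fraction = 0.70,
                                 plddt_gate = 70, max_mean_pae = 10) {
  stopifnot(all(plddt >= 0 & plddt <= 100))
  ok <- mean(plddt > plddt_gate) >= min_fraction
  pae_missing <- is.null(pae)
  if (ok && !pae_missing) {
    wf <- which(plddt > plddt_gate)
    if (length(wf) >= 2L) {
      sub <- pae[wf, wf, drop = FALSE]
      ok <- mean(sub[row(sub) != col(sub)]) < max_mean_pae
    }
  }
  structure(ok, pae_missing = pae_missing)
}

#' Group gated interface residues into patches
#'
#' Residues that are well folded (pLDDT above the gate) and predicted at an
#' interface (confidence above the gate) are connected whenever their
#' C-alpha atoms lie within the linkage distance; connected components form
#' the interface patches of each channel.
#'
#' @param result a [prediction_result()] (one row per residue).
#' @param ca_coords R x 3 matrix of representative (C-alpha) coordinates
#'   aligned with the rows of `result`.
#' @param plddt per-residue pLDDT aligned with `result` (use 100s for
#'   experimental structures).
#' @param conf_gate interface confidence gate (default 0.5, strict `>`).
#' @param plddt_gate well-folded gate (default 70, strict `>`).
#' @param link C-alpha linkage distance (default 10 Angstrom, inclusive).
#' @return list of patches; each is a list with `channel`, `members` (row
#'   indices into `result`), `mean_confidence` and `center` (mean C-alpha).
#' @export
group_interfaces <- function(result, ca_coords, plddt,
                             conf_gate = 0.5, plddt_gate = 70, link = 10) {
  channels <- attr(result, "channels")
  conf <- as.matrix(as.data.frame(result)[channels])
  stopifnot(nrow(ca_coords) == nrow(conf), length(plddt) == nrow(conf))
  patches <- list()
  for (ch in channels) {
    gated <- which(conf[, ch] > conf_gate & plddt > plddt_gate)
    if (length(gated) == 0L) next
    xy <- ca_coords[gated, , drop = FALSE]
    d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * tcrossprod(xy)
    adj <- d2 <= link^2
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    for (cc in seq_len(max(comp))) {
      members <- gated[comp == cc]
      patches[[length(patches) + 1L]] <- list(
        channel = ch,
        members = members,
        mean_confidence = mean(conf[members, ch]),
        center = colMeans(ca_coords[members, , drop = FALSE]))
    }
  }
  patches
}

#' Keep only high-quality patches
#'
#' @param patches list from [group_interfaces()].
#' @param min_mean_conf strict lower bound on the mean member confidence
#'   (default 0.8).
#' @return filtered patch list.
#' @export
quality_patches <- function(patches, min_mean_conf = 0.8) {
  Filter(function(p) p$mean_confidence > min_mean_conf, patches)
}

#' Do two interface patches overlap?
#'
#' Two quality patches of different types overlap when they share at least
#' `min_shared` residues; same-channel pairs are never reported as
#' overlapping.
#'
#' @param a,b patches (lists with `channel` and `members`).
#' @param min_shared residue-sharing threshold (default 5, inclusive).
#' @return logical.
#' @export
patches_overlap <- function(a, b, min_shared = 5L) {
  if (identical(a$channel, b$channel)) return(FALSE)
  length(intersect(a$members, b$members)) >= min_shared
}

#' Pairwise overlap matrix of a patch list
#' @param patches list of patches.
#' @param min_shared see [patches_overlap()].
#' @return logical matrix.
#' @export
overlap_matrix <- function(patches, min_shared = 5L) {
  n <- length(patches)
  m <- matrix(FALSE, n, n)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- patches_overlap(patches[[i]], patches[[j]],
                                            min_shared)
    }
  }
  m
}
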