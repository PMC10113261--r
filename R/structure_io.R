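# Structure parsing, cleaning and prediction serialization.
#
# Cleaning rules: all MODEL records are merged into one structure with chain
# names tagged by model number; every non-polymer molecule becomes its own
# subunit; subunits duplicated by model concatenation are removed; the first
# alternate location is kept; water, heavy water, hydrogen and deuterium
# atoms are removed.

WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O", "SOL", "TIP", "TIP3", "OH2")

# hydrogen/deuterium detection: element field when present, else an
# atom-name heuristic (leading digits stripped, first letter H/D), with the
# standard exception of single-atom residues whose code equals the atom name
# (e.g. mercury "HG" ions in legacy files without an element column).
is_hydrogen_atom <- function(element, name, resid) {
  el <- toupper(trimws(element))
  has_el <- nzchar(el)
  by_el <- has_el & el %in% c("H", "D")
  stripped <- sub("^[0-9]+", "", toupper(trimws(name)))
  first <- substr(stripped, 1L, 1L)
  by_name <- !has_el & first %in% c("H", "D") &
    toupper(trimws(resid)) != toupper(trimws(name))
  by_el | by_name
}

#' Parse and clean a PDB structure
#'
#' Reads a (possibly multi-model) PDB file and applies the cleaning rules
#' used throughout the pipeline: models merged into a single structure with
#' chains tagged `"<chain>:<model>"`, non-polymer molecules split into their
#' own subunits, duplicated subunits removed, first alternate location kept,
#' and water/heavy-water/hydrogen/deuterium atoms removed.
#'
#' @param path PDB file.
#' @param use_first_assembly_only when `TRUE`, keep only the first MODEL of
#'   the file instead of merging all models (for callers that supply full
#'   bioassembly files where later models replicate the first).
#' @param cats molecule catalogue used to recognise polymer residues.
#' @return an [atomic_structure()].
#' @export
parse_structure <- function(path, use_first_assembly_only = FALSE,
                            cats = default_molecule_categories()) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nmod <- nrow(xyz)
  if (use_first_assembly_only) nmod <- 1L
  nat <- nrow(at)
  if (is.null(nat) || nat == 0L) stop("empty or unparseable PDB file: ", path)

  tabs <- vector("list", nmod)
  for (k in seq_len(nmod)) {
    cx <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    tabs[[k]] <- data.frame(
      model = k,
      chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
      resno = at$resno,
      insert = ifelse(is.na(at$insert), "", at$insert),
      resid = toupper(at$resid),
      elety = at$elety,
      alt = ifelse(is.na(at$alt), "", at$alt),
      element = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
      x = cx[, 1], y = cx[, 2], z = cx[, 3],
      bfac = ifelse(is.na(at$b), 0, at$b),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)

  # element fallback from atom name for files without an element column
  noel <- !nzchar(tab$element)
  if (any(noel)) {
    guess <- sub("^[0-9]+", "", toupper(trimws(tab$elety[noel])))
    two <- substr(guess, 1L, 2L)
    known2 <- two %in% default_element_vocab() &
      two == toupper(trimws(tab$resid[noel]))
    tab$element[noel] <- ifelse(known2, two, substr(guess, 1L, 1L))
  }

  # waters, hydrogens, deuteriums out
  tab <- tab[!(tab$resid %in% WATER_NAMES), , drop = FALSE]
  if (nrow(tab) > 0L) {
    tab <- tab[!is_hydrogen_atom(tab$element, tab$elety, tab$resid), ,
               drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("empty structure after cleanup: ", path)

  # first alternate location per atom site
  site <- paste(tab$model, tab$chain, tab$resno, tab$insert, tab$resid,
                tab$elety, sep = "\r")
  tab <- tab[!duplicated(site), , drop = FALSE]

  # residue decomposition, in file order
  author <- paste0(tab$resno, tab$insert)
  rkey <- paste(tab$model, tab$chain, tab$resno, tab$insert, tab$resid,
                sep = "\r")
  res_idx <- match(rkey, unique(rkey))
  first_of_res <- !duplicated(rkey)
  res_name <- tab$resid[first_of_res]
  res_author <- author[first_of_res]
  res_chain <- tab$chain[first_of_res]
  res_model <- tab$model[first_of_res]

  # chain tagging: polymers by chain and model; each non-polymer molecule
  # becomes its own subunit
  polymer <- res_name %in% c(cats$amino_acids, cats$nucleic_acids)
  tag <- ifelse(polymer,
                paste0(res_chain, ":", res_model),
                paste0(res_chain, ":", res_model, ":", res_name, res_author))

  atoms <- data.frame(element = tab$element, name = tab$elety,
                      x = tab$x, y = tab$y, z = tab$z,
                      altloc = tab$alt, res_idx = res_idx,
                      bfac = tab$bfac,
                      stringsAsFactors = FALSE)
  residues <- data.frame(name = res_name, author_number = res_author,
                         chain_tag = tag, stringsAsFactors = FALSE)
  st <- atomic_structure(atoms, residues, source_id = basename(path))
  dedup_subunits(st)
}

# remove subunits that duplicate an earlier one: identical residue-name
# sequence and maximum coordinate deviation below `tol` Angstrom.
dedup_subunits <- function(structure, tol = 1e-3) {
  subs <- structure$subunits
  ns <- length(subs)
  if (ns < 2L) return(structure)
  sig <- vapply(subs, function(ri)
    paste(structure$residues$name[ri], collapse = "|"), "")
  xyz <- atom_coords(structure)
  keep <- rep(TRUE, ns)
  sub_atoms <- lapply(subs, function(ri) atoms_of_residues(structure, ri))
  for (i in seq_len(ns - 1L)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, ns)) {
      if (!keep[j] || sig[i] != sig[j]) next
      ai <- sub_atoms[[i]]; aj <- sub_atoms[[j]]
      if (length(ai) != length(aj)) next
      if (max(abs(xyz[ai, , drop = FALSE] - xyz[aj, , drop = FALSE])) < tol) {
        keep[j] <- FALSE
      }
    }
  }
  if (all(keep)) return(structure)
  keep_res <- sort(unlist(subs[keep], use.names = FALSE))
  subset_structure(structure, keep_res)
}

# restrict a structure to a residue subset (indices into residues table)
subset_structure <- function(structure, res_keep) {
  res_keep <- sort(res_keep)
  amask <- structure$atoms$res_idx %in% res_keep
  atoms <- structure$atoms[amask, , drop = FALSE]
  atoms$res_idx <- match(atoms$res_idx, res_keep)
  residues <- structure$residues[res_keep, , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  atomic_structure(atoms, residues, structure$source_id)
}

#' Per-residue prediction container
#'
#' @param table data.frame with columns `chain_tag`, `author_number`,
#'   `residue_name` followed by one numeric confidence column per channel.
#' @param channels ordered channel names (must match table columns).
#' @return a `prediction_result` (data.frame subclass).
#' @export
prediction_result <- function(table, channels) {
  stopifnot(all(c("chain_tag", "author_number", "residue_name") %in%
                  names(table)),
            all(channels %in% names(table)))
  for (ch in channels) {
    v <- table[[ch]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      stop("confidences must lie in [0, 1] (channel ", ch, ")")
    }
  }
  attr(table, "channels") <- channels
  class(table) <- c("prediction_result", "data.frame")
  table
}

#' Write predictions into the B-factor column of a PDB file
#'
#' Each atom's B-factor is set to 100 x the confidence of its parent residue
#' for the requested channel, rounded to 2 decimals, so a round-trip parse
#' recovers confidences to within 0.005.  Subunit tags are mapped to
#' single-character chain identifiers for the fixed-width format.
#'
#' @param structure the [atomic_structure()] the predictions refer to.
#' @param result a [prediction_result()] with one row per scored residue.
#' @param channel channel name to encode.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prediction_pdb <- function(structure, result, channel, path) {
  channels <- attr(result, "channels")
  if (!channel %in% channels) stop("unknown channel: ", channel)
  conf_by_res <- rep(0, n_residues(structure))
  key_struct <- paste(structure$residues$chain_tag,
                      structure$residues$author_number, sep = "\r")
  key_res <- paste(result$chain_tag, result$author_number, sep = "\r")
  hit <- match(key_struct, key_res)
  conf_by_res[!is.na(hit)] <- result[[channel]][hit[!is.na(hit)]]
  write_structure_pdb(structure, path,
                      bfactor_by_residue = round(100 * conf_by_res, 2))
}

#' Write an atomic structure as a PDB file
#'
#' Subunit tags are mapped to single-character chain identifiers (A-Z,
#' a-z, 0-9, recycled) to fit the fixed-width format.
#'
#' @param structure an [atomic_structure()].
#' @param path output file.
#' @param bfactor_by_residue optional numeric vector (one value per
#'   residue) written to the B-factor column; defaults to zeros.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, bfactor_by_residue = NULL) {
  if (is.null(bfactor_by_residue)) {
    bfactor_by_residue <- rep(0, n_residues(structure))
  }
  chain_pool <- c(LETTERS, letters, as.character(0:9))
  tags <- names(structure$subunits)
  chain_of_sub <- chain_pool[(seq_along(tags) - 1L) %% length(chain_pool) + 1L]
  sub_of_res <- residue_subunit_map(structure)

  a <- structure$atoms
  ri <- a$res_idx
  author <- structure$residues$author_number[ri]
  resno <- as.integer(sub("([A-Za-z]*)$", "", author))
  insert <- sub("^-?[0-9]+", "", author)
  b <- bfactor_by_residue[ri]
  xyz <- as.vector(t(cbind(a$x, a$y, a$z)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = resno,
                   resid = structure$residues$name[ri],
                   eleno = seq_len(nrow(a)),
                   elety = a$name,
                   chain = chain_of_sub[sub_of_res[ri]],
                   insert = ifelse(nzchar(insert), insert, ""),
                   o = rep(1, nrow(a)), b = b,
                   elesy = a$element)
  invisible(path)
}

#' Write a per-residue prediction table
#'
#' Tab-separated text: one row per residue with `chain_tag`,
#' `author_number`, `residue_name` and one column per channel, at full float
#' precision (17 significant digits).
#'
#' @param result a [prediction_result()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(result, path) {
  channels <- attr(result, "channels")
  df <- as.data.frame(result)
  for (ch in channels) df[[ch]] <- sprintf("%.17g", df[[ch]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_prediction_table()]
#' @param path TSV file.
#' @return a [prediction_result()].
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE)
  df$author_number <- as.character(df$author_number)
  meta <- c("chain_tag", "author_number", "residue_name")
  prediction_result(df, setdiff(names(df), meta))
}
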