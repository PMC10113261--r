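# Shared fixture builders: tiny structures assembled in code, PDB text
# fixtures written on the fly, and small reference oracles.

# a minimal structure from residue specs: list of lists with fields
# name, chain_tag, atoms (matrix of coords), elements (optional)
make_structure <- function(res_specs, source_id = "fixture") {
  atoms <- list()
  residues <- list()
  for (i in seq_along(res_specs)) {
    rs <- res_specs[[i]]
    xyz <- rs$atoms
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
    el <- rs$elements
    if (is.null(el)) el <- rep("C", nrow(xyz))
    nm <- rs$atom_names
    if (is.null(nm)) nm <- c("CA", sprintf("X%d", seq_len(max(0, nrow(xyz) - 1))))
    atoms[[i]] <- data.frame(element = el, name = nm[seq_len(nrow(xyz))],
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             altloc = "", res_idx = i,
                             stringsAsFactors = FALSE)
    residues[[i]] <- data.frame(
      name = rs$name,
      author_number = if (is.null(rs$author)) as.character(i) else rs$author,
      chain_tag = rs$chain_tag, stringsAsFactors = FALSE)
  }
  atomic_structure(do.call(rbind, atoms), do.call(rbind, residues),
                   source_id = source_id)
}

# a small two-chain structure with one contact at `gap` Angstrom
two_chain_fixture <- function(gap = 4.0) {
  make_structure(list(
    list(name = "ALA", chain_tag = "A:1",
         atoms = rbind(c(0, 0, 0), c(1.4, 0, 0))),
    list(name = "GLY", chain_tag = "A:1",
         atoms = rbind(c(0, 3.8, 0))),
    list(name = "SER", chain_tag = "B:1",
         atoms = rbind(c(gap, 0, 0), c(gap + 1.4, 0, 0))),
    list(name = "VAL", chain_tag = "B:1",
         atoms = rbind(c(gap, 3.8, 0)))
  ))
}

# hand-written PDB text fixture: 2 models of a 3-residue peptide, plus
# waters, hydrogens and an altloc pair in model 1
write_multimodel_pdb <- function(path) {
  at <- function(serial, name, alt, resn, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, resn, chain, resno, x, y, z, 1, 0, el)
  }
  l <- c("MODEL     1",
         at(1, " N  ", " ", "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
         at(2, " CA ", " ", "ALA", "A", 1, 1.5, 0.0, 0.0, "C"),
         at(3, " CB ", "A", "ALA", "A", 1, 2.0, 1.0, 0.0, "C"),
         at(4, " CB ", "B", "ALA", "A", 1, 2.1, 1.1, 0.0, "C"),
         at(5, " H  ", " ", "ALA", "A", 1, -0.5, 0.5, 0.0, "H"),
         at(6, " CA ", " ", "GLY", "A", 2, 5.0, 0.0, 0.0, "C"),
         at(7, " HA2", " ", "GLY", "A", 2, 5.5, 0.8, 0.0, "H"),
         at(8, " CA ", " ", "SER", "A", 3, 9.0, 0.0, 0.0, "C"),
         at(9, " OG ", " ", "SER", "A", 3, 9.8, 1.2, 0.0, "O"),
         at(10, " O  ", " ", "HOH", "A", 101, 20.0, 20.0, 20.0, "O"),
         at(11, " O  ", " ", "HOH", "A", 102, 22.0, 20.0, 20.0, "O"),
         "ENDMDL",
         "MODEL     2",
         at(1, " N  ", " ", "ALA", "A", 1, 0.0, 0.0, 30.0, "N"),
         at(2, " CA ", " ", "ALA", "A", 1, 1.5, 0.0, 30.0, "C"),
         at(3, " CB ", "A", "ALA", "A", 1, 2.0, 1.0, 30.0, "C"),
         at(4, " CB ", "B", "ALA", "A", 1, 2.1, 1.1, 30.0, "C"),
         at(5, " H  ", " ", "ALA", "A", 1, -0.5, 0.5, 30.0, "H"),
         at(6, " CA ", " ", "GLY", "A", 2, 5.0, 0.0, 30.0, "C"),
         at(7, " HA2", " ", "GLY", "A", 2, 5.5, 0.8, 30.0, "H"),
         at(8, " CA ", " ", "SER", "A", 3, 9.0, 0.0, 30.0, "C"),
         at(9, " OG ", " ", "SER", "A", 3, 9.8, 1.2, 30.0, "O"),
         at(10, " O  ", " ", "HOH", "A", 101, 20.0, 20.0, 50.0, "O"),
         at(11, " O  ", " ", "HOH", "A", 102, 22.0, 20.0, 50.0, "O"),
         "ENDMDL",
         "END")
  writeLines(l, path)
  path
}

write_water_only_pdb <- function(path) {
  l <- c(sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 1, " O  ", " ", "HOH", "A", 1, 0, 0, 0, 1, 0, "O"),
         "END")
  writeLines(l, path)
  path
}

# brute-force kNN oracle: full pairwise sort with ties by ascending index
knn_oracle <- function(coords, nn) {
  n <- nrow(coords)
  idx <- matrix(1L, n, nn)
  dist <- matrix(0, n, nn)
  sink <- matrix(TRUE, n, nn)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    d2 <- numeric(length(others))
    for (k in seq_along(others)) {
      dx <- coords[others[k], 1] - coords[i, 1]
      dy <- coords[others[k], 2] - coords[i, 2]
      dz <- coords[others[k], 3] - coords[i, 3]
      d2[k] <- dx * dx + dy * dy + dz * dz
    }
    o <- order(d2, others)
    take <- min(nn, length(others))
    if (take > 0) {
      idx[i, seq_len(take)] <- others[o[seq_len(take)]]
      dist[i, seq_len(take)] <- sqrt(d2[o[seq_len(take)]])
      sink[i, seq_len(take)] <- FALSE
    }
  }
  list(idx = idx, dist = dist, sink = sink)
}

# brute-force interface label oracle: all residue pairs, min atom distance
label_oracle <- function(structure, cutoff = 5.0) {
  categories <- categorize_subunits(structure)
  channels <- interface_channels()
  sub_of_res <- interformer:::residue_subunit_map(structure)
  xyz <- atom_coords(structure)
  prot_res <- which(categories[sub_of_res] == "protein")
  lab <- matrix(0L, length(prot_res), length(channels),
                dimnames = list(NULL, channels))
  for (ii in seq_along(prot_res)) {
    r <- prot_res[ii]
    ar <- which(structure$atoms$res_idx == r)
    for (r2 in seq_len(n_residues(structure))) {
      if (sub_of_res[r2] == sub_of_res[r]) next
      cat2 <- categories[sub_of_res[r2]]
      if (cat2 == "ignored") next
      a2 <- which(structure$atoms$res_idx == r2)
      dmin <- Inf
      for (p in ar) for (q in a2) {
        d <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin < cutoff) lab[ii, cat2] <- 1L
    }
  }
  lab
}

# random structure: a few residues with random atoms, two chains
random_two_chain <- function(n_res = 8, atoms_per_res = 3, spread = 12) {
  specs <- list()
  for (i in seq_len(n_res)) {
    specs[[i]] <- list(
      name = sample(default_molecule_categories()$amino_acids, 1),
      chain_tag = if (i <= n_res / 2) "A:1" else "B:1",
      atoms = matrix(runif(atoms_per_res * 3, 0, spread), ncol = 3))
  }
  make_structure(specs)
}

small_model_config <- function(channels = "protein") {
  model_config(S = 4L, nn_schedule = list(c(1L, 3L), c(1L, 4L)),
               n_key = 2L, n_head_atom = 2L, n_head_pool = 2L,
               channels = channels)
}
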