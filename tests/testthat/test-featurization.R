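# Element encoding, kNN graphs, subunit categories, 5 Angstrom labels and
# the interaction-type matrix.

test_that("element one-hot has the documented width and unknown slot", {
  expect_length(default_element_vocab(), 30L)
  st <- make_structure(list(list(
    name = "ALA", chain_tag = "A:1",
    atoms = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    elements = c("C", "ZN", "XX"))))
  oh <- encode_elements(st)
  expect_equal(dim(oh), c(3L, 31L))
  expect_equal(rowSums(oh), c(1, 1, 1))
  expect_equal(unname(oh[1, "C"]), 1)
  expect_equal(unname(oh[2, "ZN"]), 1)
  expect_equal(unname(oh[3, "UNK"]), 1)
  expect_error(encode_elements(st, c("C", "C")), "duplicates")
})

test_that("collinear and tied kNN cases follow the documented rules", {
  # 3 collinear atoms at x = 0, 1, 3 with nn = 1
  g <- build_knn_graph(cbind(c(0, 1, 3), 0, 0), 1L)
  expect_equal(as.vector(g$idx), c(2L, 1L, 2L))
  # wait: nearest of atom 2 (x=1) is atom 1 (d=1) vs atom 3 (d=2) -> atom 1
  # nearest of atom 1 is atom 2; nearest of atom 3 is atom 2
  expect_equal(g$idx[1, 1], 2L)
  expect_equal(g$idx[2, 1], 1L)
  expect_equal(g$idx[3, 1], 2L)
  # unit square, corner atom has two neighbours at distance 1: ties broken
  # by ascending atom index
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  g2 <- build_knn_graph(sq, 2L)
  expect_equal(g2$idx[1, ], c(2L, 3L))
  expect_equal(g2$dist[1, ], c(1, 1))
  # displacement vectors are unit and point from i to j
  expect_equal(g2$rhat_x[1, 1], 1)
  expect_equal(g2$rhat_y[1, 2], 1)
  expect_error(build_knn_graph(cbind(NA, 1, 1), 1L), "non-finite")
})

test_that("kNN graph matches the brute-force oracle on random point sets", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(2:200, 1)
    coords <- matrix(runif(n * 3, 0, 30), n, 3)
    for (nn in c(1L, 8L, 64L)) {
      g <- build_knn_graph(coords, nn)
      o <- knn_oracle(coords, nn)
      expect_identical(g$idx[!o$sink], o$idx[!o$sink])
      expect_equal(g$dist, o$dist, tolerance = 1e-12)
      expect_identical(unname(g$sink_mask), o$sink)
    }
  }
})

test_that("subunits are categorized by composition and lookup", {
  st <- make_structure(list(
    list(name = "ALA", chain_tag = "A:1", atoms = c(0, 0, 0)),
    list(name = "GLY", chain_tag = "A:1", atoms = c(3.8, 0, 0)),
    list(name = "DA", chain_tag = "B:1", atoms = c(10, 0, 0)),
    list(name = "DT", chain_tag = "B:1", atoms = c(13, 0, 0)),
    list(name = "ZN", chain_tag = "C:1:ZN1", atoms = c(20, 0, 0),
         elements = "ZN"),
    list(name = "ATP", chain_tag = "D:1:ATP1", atoms = c(25, 0, 0)),
    list(name = "CLR", chain_tag = "E:1:CLR1", atoms = c(30, 0, 0)),
    list(name = "XYZ", chain_tag = "F:1:XYZ1", atoms = c(35, 0, 0))))
  cats <- categorize_subunits(st)
  expect_equal(unname(cats),
               c("protein", "nucleic_acid", "ion", "ligand", "lipid",
                 "ignored"))
})

test_that("interface labels respect the strict 5 Angstrom rule", {
  # closest atom pair sits at exactly 4.9: (1.4,0,0) vs (6.3,0,0)
  st <- two_chain_fixture(gap = 4.9 + 1.4)
  lab <- label_interfaces(st)
  expect_equal(lab$labels[, "protein"], c(1L, 0L, 1L, 0L))
  st51 <- two_chain_fixture(gap = 5.1 + 1.4)
  lab51 <- label_interfaces(st51)
  expect_equal(sum(lab51$labels), 0L)
  expect_error(label_interfaces(make_structure(list(
    list(name = "ZN", chain_tag = "A:1:ZN1", atoms = c(0, 0, 0),
         elements = "ZN")))), "no protein")
})

test_that("labels match the brute-force oracle on random structures", {
  set.seed(12)
  for (rep in 1:8) {
    st <- random_two_chain(n_res = sample(4:10, 1),
                           atoms_per_res = sample(2:4, 1))
    lab <- label_interfaces(st)
    expect_equal(unname(lab$labels), unname(label_oracle(st)))
  }
})

test_that("labels are invariant under rigid transforms and atom order", {
  set.seed(13)
  for (rep in 1:5) {
    st <- random_two_chain(n_res = 8)
    lab <- label_interfaces(st)
    st2 <- transform_structure(st, random_rotation(), runif(3, -30, 30))
    expect_equal(label_interfaces(st2)$labels, lab$labels)
    # permute atoms within each residue
    a <- st$atoms
    perm <- unlist(lapply(split(seq_len(nrow(a)), a$res_idx), sample))
    st3 <- atomic_structure(a[perm, ], st$residues)
    expect_equal(label_interfaces(st3)$labels, lab$labels)
  }
})

test_that("increasing the cutoff never clears a label", {
  set.seed(14)
  for (rep in 1:5) {
    st <- random_two_chain(n_res = 8)
    l1 <- label_interfaces(st, cutoff = 4.0)$labels
    l2 <- label_interfaces(st, cutoff = 6.0)$labels
    expect_true(all(l2 >= l1))
  }
})

test_that("interaction matrix counts contacts over the 79-component catalogue", {
  expect_length(molecule_catalogue(), 79L)
  cats <- default_molecule_categories()
  expect_equal(lengths(cats)[c("amino_acids", "nucleic_acids", "ions",
                               "ligands", "lipids")],
               c(amino_acids = 20L, nucleic_acids = 8L, ions = 16L,
                 ligands = 31L, lipids = 4L))
  expect_false(anyDuplicated(molecule_catalogue()) > 0)

  # no contacts -> zero matrix
  far <- two_chain_fixture(gap = 50)
  im0 <- build_interaction_matrix(far)
  expect_true(all(im0$counts == 0))

  # one ALA-ZN contact -> two symmetric entries of 1
  st <- make_structure(list(
    list(name = "ALA", chain_tag = "A:1", atoms = c(0, 0, 0)),
    list(name = "GLY", chain_tag = "A:1", atoms = c(0, 3.8, 0)),
    list(name = "ZN", chain_tag = "B:1:ZN1", atoms = c(4.5, 0, 0),
         elements = "ZN")))
  im <- build_interaction_matrix(st)
  expect_equal(im$counts["ALA", "ZN"], 1L)
  expect_equal(im$counts["ZN", "ALA"], 1L)
  expect_equal(sum(im$counts), 2L)
  expect_true(isSymmetric(unname(im$counts)))
})

test_that("channel labels regenerate from the per-residue contact table", {
  set.seed(15)
  for (rep in 1:5) {
    st <- plant_complex(synth_config(residues_per_chain = c(8L, 12L),
                                     two_chain_fraction = 0.5))
    im <- build_interaction_matrix(st)
    regen <- labels_from_interaction_matrix(im, st)
    direct <- label_interfaces(st)
    expect_equal(regen$labels, direct$labels)
    expect_equal(regen$residue_index, direct$residue_index)
  }
})
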