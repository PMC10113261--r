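# Parsing, cleaning rules and prediction serialization.

test_that("multi-model fixture is merged, tagged, and cleaned", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(path)
  st <- parse_structure(path)
  # 2 models x 3 residues; waters and hydrogens gone; one altloc kept
  expect_equal(length(st$subunits), 2L)
  expect_setequal(names(st$subunits), c("A:1", "A:2"))
  expect_equal(n_residues(st), 6L)
  # heavy atoms per peptide: ALA(N,CA,CB) + GLY(CA) + SER(CA,OG) = 6
  expect_equal(n_atoms(st), 2L * 6L)
  expect_false(any(st$atoms$element %in% c("H", "D")))
  expect_false(any(st$residues$name %in% c("HOH", "DOD")))
  # altloc: exactly one CB in each ALA, the first one (x = 2.0)
  cb <- st$atoms[st$atoms$name == "CB", ]
  expect_equal(nrow(cb), 2L)
  expect_equal(cb$x, c(2.0, 2.0))
  expect_equal(cb$altloc, c("A", "A"))
})

test_that("first-assembly flag keeps only model 1", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(path)
  st <- parse_structure(path, use_first_assembly_only = TRUE)
  expect_equal(length(st$subunits), 1L)
  expect_equal(n_atoms(st), 6L)
})

test_that("water-only file and unparseable input raise errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_water_only_pdb(path)
  expect_error(parse_structure(path), "empty structure")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(parse_structure(bad))
})

test_that("duplicated subunits from model concatenation are removed", {
  # two identical models (same coordinates): dedup keeps one subunit
  path <- withr::local_tempfile(fileext = ".pdb")
  at <- function(serial, name, resn, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, " ", resn, chain, resno, x, y, z, 1, 0, el)
  }
  body <- c(at(1, " CA ", "ALA", "A", 1, 0, 0, 0, "C"),
            at(2, " CA ", "GLY", "A", 2, 3.8, 0, 0, "C"))
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", body, "ENDMDL", "END"), path)
  st <- parse_structure(path)
  expect_equal(length(st$subunits), 1L)
  expect_equal(n_residues(st), 2L)
})

test_that("non-polymer molecules become their own subunits", {
  st <- make_structure(list(
    list(name = "ALA", chain_tag = "A:1", atoms = c(0, 0, 0)),
    list(name = "GLY", chain_tag = "A:1", atoms = c(3.8, 0, 0)),
    list(name = "ZN", chain_tag = "A:1:ZN3", atoms = c(10, 0, 0),
         elements = "ZN", atom_names = "ZN")))
  expect_equal(length(st$subunits), 2L)
  # and via the parser: a HETATM zinc on the same chain letter
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1, " CA ", " ", "ALA", "A", 1, 0, 0, 0, 1, 0, "C"),
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            2, " CA ", " ", "GLY", "A", 2, 3.8, 0, 0, 1, 0, "C"),
    sprintf("HETATM%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            3, "ZN  ", " ", " ZN", "A", 3, 8, 0, 0, 1, 0, "ZN"),
    "END"), path)
  stp <- parse_structure(path)
  expect_equal(length(stp$subunits), 2L)
  expect_true(any(grepl("ZN", names(stp$subunits))))
})

test_that("prediction PDB round-trips confidences through the B-factor column", {
  st <- make_structure(list(
    list(name = "ALA", chain_tag = "A:1", atoms = rbind(c(0, 0, 0), c(1.4, 0, 0))),
    list(name = "GLY", chain_tag = "A:1", atoms = c(3.8, 0, 0)),
    list(name = "SER", chain_tag = "A:1", atoms = c(7.6, 0, 0))))
  tab <- data.frame(chain_tag = "A:1", author_number = c("1", "2", "3"),
                    residue_name = c("ALA", "GLY", "SER"),
                    protein = c(0.1, 0.9, 0.5), stringsAsFactors = FALSE)
  res <- prediction_result(tab, "protein")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_prediction_pdb(st, res, "protein", path)
  back <- parse_structure(path)
  expect_equal(n_atoms(back), 4L)
  # per-residue B-factors are 100 x confidence
  expect_equal(back$atoms$bfac, c(10, 10, 90, 50))
  recovered <- back$atoms$bfac[!duplicated(back$atoms$res_idx)] / 100
  expect_true(all(abs(recovered - c(0.1, 0.9, 0.5)) <= 0.005))
  expect_error(write_prediction_pdb(st, res, "nucleic_acid", path),
               "unknown channel")
  # cleanup idempotence: re-parsing and re-writing changes nothing
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_prediction_pdb(back, res, "protein", path2)
  back2 <- parse_structure(path2)
  expect_equal(back2$atoms[c("element", "x", "y", "z")],
               back$atoms[c("element", "x", "y", "z")])
})

test_that("prediction table round-trips at full precision", {
  channels <- interface_channels()
  tab <- data.frame(chain_tag = c("A:1", "A:1"), author_number = c("1", "2"),
                    residue_name = c("ALA", "GLY"), stringsAsFactors = FALSE)
  set.seed(1)
  for (ch in channels) tab[[ch]] <- runif(2)
  res <- prediction_result(tab, channels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_table(res, path)
  back <- read_prediction_table(path)
  expect_equal(attr(back, "channels"), channels)
  for (ch in channels) expect_identical(back[[ch]], tab[[ch]])
  # header-only file for an empty result
  empty <- prediction_result(tab[0, ], channels)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_table(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
  # column arithmetic: 1 residue, 5 channels -> 1 row, 8 columns
  one <- read_prediction_table({
    p <- withr::local_tempfile(fileext = ".tsv")
    write_prediction_table(prediction_result(tab[1, ], channels), p); p
  })
  expect_equal(dim(as.data.frame(one)), c(1L, 8L))
})

test_that("subunit partition covers all residues exactly once", {
  set.seed(2)
  st <- plant_complex(synth_config(residues_per_chain = c(8L, 10L)))
  expect_equal(sort(unlist(st$subunits, use.names = FALSE)),
               seq_len(n_residues(st)))
  expect_error(atomic_structure(st$atoms[0, ], st$residues), "empty")
})
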