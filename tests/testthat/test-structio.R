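test_that("a minimal co-complex parses into one chain and one ligand", {
  p <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  m <- parse_structure(p)
  expect_s3_class(m, "structure_model")
  expect_length(m$chains, 1)
  expect_equal(m$chains[["A"]]$sequence, "AS")
  expect_length(m$ligands, 2) # ZN plus the 2-residue peptide chain itself
  zn <- m$ligands[[1]]
  expect_equal(zn$component_id, "ZN")
  expect_equal(zn$kind_hint, "non-polymer")
})

test_that("hydrogens and waters are removed during parsing", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HB1 ALA A   1       1.500   0.000   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A 201       2.000   0.000   0.000  1.00  0.00           O",
    "HETATM    5 ZN    ZN A 101       3.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  )
  m <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines))
  res <- m$chains[["A"]]$residues[[1]]
  expect_setequal(res$atoms$name, c("CA", "CB"))
  expect_length(m$ligands, 2) # ZN + the one-residue peptide; never HOH
  expect_false(any(vapply(m$ligands, function(l) l$component_id, "") == "HOH"))
})

test_that("the highest-occupancy alt-loc conformer is kept, ties to first", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CB AALA A   2       4.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  CB BALA A   2       5.000   0.000   0.000  0.50  0.00           C",
    "HETATM    7 ZN    ZN A 101       9.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  )
  m <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines))
  r1 <- m$chains[["A"]]$residues[[1]]
  cb1 <- r1$atoms[r1$atoms$name == "CB", ]
  expect_equal(nrow(cb1), 1)
  expect_equal(cb1$x, 2.0) # occupancy 0.6 wins
  r2 <- m$chains[["A"]]$residues[[2]]
  cb2 <- r2$atoms[r2$atoms$name == "CB", ]
  expect_equal(cb2$x, 4.0) # tie -> first in file order
})

test_that("short peptide chains double as ligand instances, long ones do not", {
  mk_chain_lines <- function(chain, n, x0, serial0) {
    unlist(lapply(seq_len(n), function(i) {
      c(
        sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial0 + 2 * i - 2, chain, i, x0 + i * 4, 0, 0),
        sprintf("ATOM  %5d  CB  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial0 + 2 * i - 1, chain, i, x0 + i * 4, 1.5, 0)
      )
    }))
  }
  for (n_pep in c(25L, 31L)) {
    lines <- c(
      mk_chain_lines("A", 40, 0, 1),
      mk_chain_lines("B", n_pep, 500, 100),
      "END"
    )
    m <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines))
    expect_length(m$chains, 2)
    pep_lig <- Filter(function(l) l$component_id == "PEP_B", m$ligands)
    expect_length(pep_lig, if (n_pep <= 30) 1 else 0)
  }
})

test_that("multi-model entries keep only the first model", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3 ZN    ZN A 101       3.000   0.000   0.000  1.00  0.00          ZN",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      50.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1      51.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3 ZN    ZN A 101      53.000   0.000   0.000  1.00  0.00          ZN",
    "ENDMDL",
    "END"
  )
  m <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines))
  expect_equal(m$model_index, 1L)
  expect_equal(m$chains[["A"]]$residues[[1]]$atoms$x[1], 0)
})

test_that("structures without protein chains or unreadable files error", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 ZN    ZN A 101       0.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  ), bad)
  expect_error(parse_structure(bad), "protein")
  expect_error(parse_structure("/nonexistent/file.pdb"), "not found")
})

test_that("min side-chain distance matches hand geometry and min over pairs", {
  res <- mk_residue("CYS", mk_atoms(c("CA", "SG"), c("C", "S"),
    rbind(c(-5, 0, 0), c(0, 0, 0))))
  lig <- mk_ligand(rbind(c(3, 4, 0)))
  expect_equal(min_sidechain_distance(res, lig), 5.0) # 3-4-5 triangle
  res2 <- mk_residue("SER", mk_atoms(c("OG", "OG1"), c("O", "O"),
    rbind(c(0, 0, 0), c(0, 0, 10))))
  lig2 <- mk_ligand(rbind(c(0, 0, 3), c(0, 0, 100)))
  expect_equal(min_sidechain_distance(res2, lig2), 3.0)
})

test_that("min side-chain distance equals a brute-force pair loop", {
  set.seed(42)
  for (rep in 1:5) {
    rxyz <- matrix(rnorm(15, sd = 5), 5, 3)
    lxyz <- matrix(rnorm(21, sd = 5), 7, 3)
    res <- mk_residue("LYS", mk_atoms(paste0("S", 1:5), rep("C", 5), rxyz))
    lig <- mk_ligand(lxyz)
    brute <- Inf
    for (i in 1:5) for (j in 1:7) {
      brute <- min(brute, sqrt(sum((rxyz[i, ] - lxyz[j, ])^2)))
    }
    expect_equal(min_sidechain_distance(res, lig), brute, tolerance = 1e-12)
  }
})

test_that("distances are invariant under joint rigid rotation + translation", {
  set.seed(7)
  rxyz <- matrix(rnorm(12), 4, 3)
  lxyz <- matrix(rnorm(9) + 3, 3, 3)
  theta <- 0.83
  R <- rbind(
    c(cos(theta), -sin(theta), 0),
    c(sin(theta), cos(theta), 0),
    c(0, 0, 1)
  )
  shift <- c(11, -4, 2.5)
  d0 <- min_sidechain_distance(
    mk_residue("LEU", mk_atoms(paste0("S", 1:4), rep("C", 4), rxyz)),
    mk_ligand(lxyz)
  )
  d1 <- min_sidechain_distance(
    mk_residue("LEU", mk_atoms(paste0("S", 1:4), rep("C", 4),
      sweep(rxyz %*% t(R), 2, shift, "+"))),
    mk_ligand(sweep(lxyz %*% t(R), 2, shift, "+"))
  )
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("glycine uses CA as proxy by default and NA sentinel when excluded", {
  gly <- mk_residue("GLY", mk_atoms(c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))))
  lig <- mk_ligand(rbind(c(1, 2, 0)))
  expect_equal(min_sidechain_distance(gly, lig, glycine = "ca_proxy"), 2.0)
  expect_true(is.na(min_sidechain_distance(gly, lig, glycine = "exclude")))
})

test_that("chain selection takes the nearest sequence-identical chain", {
  mk_chain_lines <- function(chain, x0) {
    c(
      sprintf("ATOM      1  CA  ALA %s   1    %8.3f   0.000   0.000  1.00  0.00           C", chain, x0),
      sprintf("ATOM      2  CB  ALA %s   1    %8.3f   1.000   0.000  1.00  0.00           C", chain, x0)
    )
  }
  lines <- c(
    mk_chain_lines("B", 2.1), mk_chain_lines("A", 8.7),
    "HETATM    9 ZN    ZN C 101       0.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  )
  m <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines))
  lig <- Filter(function(l) l$component_id == "ZN", m$ligands)[[1]]
  expect_equal(select_chain_for_ligand(m, "A", lig)$id, "B")
  # exact tie -> lexicographically smaller id
  lines_tie <- c(
    mk_chain_lines("B", 5), mk_chain_lines("A", -5),
    "HETATM    9 ZN    ZN C 101       0.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  )
  m2 <- parse_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), lines_tie))
  lig2 <- Filter(function(l) l$component_id == "ZN", m2$ligands)[[1]]
  expect_equal(select_chain_for_ligand(m2, "A", lig2)$id, "A")
  expect_error(select_chain_for_ligand(m2, "WRONGSEQ", lig2), "matches")
})

test_that("parse -> serialize -> parse preserves coordinates exactly", {
  fam <- make_toy_family(
    family_spec(n_states = 5, n_instances = 1, binding_states = c(2, 4), seed = 9),
    withr::local_tempdir()
  )
  m1 <- parse_structure(fam$structure_paths[1])
  out <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m1, out)
  m2 <- parse_structure(out)
  a1 <- do.call(rbind, lapply(m1$chains[["A"]]$residues, function(r) r$atoms))
  a2 <- do.call(rbind, lapply(m2$chains[["A"]]$residues, function(r) r$atoms))
  expect_equal(a1[, c("x", "y", "z")], a2[, c("x", "y", "z")])
})

test_that("mmCIF and PDB readers agree on the same content", {
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.type_symbol",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 CA . ALA A 1 1.000 0.000 0.000 1.00 C 1",
    "ATOM 2 CB . ALA A 1 2.000 0.000 0.000 1.00 C 1",
    "HETATM 3 ZN . ZN A 101 5.000 0.000 0.000 1.00 ZN 1",
    "#"
  ), cif)
  m <- parse_structure(cif, format = "mmcif")
  expect_equal(m$chains[["A"]]$sequence, "A")
  expect_equal(m$ligands[[1]]$component_id, "ZN")
  expect_equal(m$ligands[[1]]$atoms$x, 5)
})
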