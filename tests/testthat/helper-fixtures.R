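# Shared fixture builders: tiny hand-written structures and instance sets.

# A minimal PDB: two-residue chain plus a zinc, with optional extras.
write_mini_pdb <- function(path, lines = NULL) {
  if (is.null(lines)) {
    lines <- c(
      "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
      "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
      "ATOM      4  N   SER A   2       3.000   0.000   0.000  1.00  0.00           N",
      "ATOM      5  CA  SER A   2       4.000   0.000   0.000  1.00  0.00           C",
      "ATOM      6  OG  SER A   2       5.000   0.000   0.000  1.00  0.00           O",
      "HETATM    7 ZN    ZN A 101       8.000   0.000   0.000  1.00  0.00          ZN",
      "END"
    )
  }
  writeLines(lines, path)
  path
}

# Build a residue object directly (bypassing file parsing).
mk_residue <- function(name, atoms, chain_id = "A", number = 1L) {
  list(
    chain_id = chain_id, number = number, icode = "", name = name,
    record = "ATOM",
    atoms = data.frame(
      name = atoms$name, element = atoms$element,
      x = atoms$x, y = atoms$y, z = atoms$z,
      occupancy = 1, alt = "", stringsAsFactors = FALSE
    )
  )
}

mk_atoms <- function(name, element, xyz) {
  data.frame(
    name = name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, alt = "", stringsAsFactors = FALSE
  )
}

mk_ligand <- function(xyz, element = "C") {
  structure(
    list(
      component_id = "LIG", copy_key = "A:900",
      atoms = mk_atoms(paste0("L", seq_len(nrow(xyz))),
        rep(element, length.out = nrow(xyz)), xyz),
      kind_hint = "non-polymer"
    ),
    class = "ligand_instance"
  )
}

# Instance set with given per-state distance rows and aligned sequences.
mk_instances <- function(dists, seqs, binding = NULL, accession = "DOM1",
                         ligand_class = "SMALL_MOLECULE") {
  lapply(seq_len(nrow(dists)), function(i) {
    domain_instance(
      id = sprintf("inst%02d", i),
      seq = strsplit(seqs[i], "")[[1]],
      dist = dists[i, ],
      binding = if (is.null(binding)) NULL else binding[i, ],
      accession = accession, ligand_class = ligand_class
    )
  })
}

# Load a generated toy family into instances.
load_toy <- function(fam, ...) {
  load_family_instances(
    file.path(fam$dir, "structures"), fam$model_path,
    fam$hits_path, fam$annotation_path, ...
  )
}
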