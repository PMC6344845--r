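# Structure ingestion: co-complex PDB/mmCIF parsing, chain/ligand resolution,
# and residue-to-ligand heavy-atom distances.

# Backbone atom names of amino-acid residues; everything else heavy is side chain.
PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Parse a protein-ligand co-complex structure
#'
#' Reads a PDB or mmCIF file into a light-weight structure model. Hydrogens
#' (and deuteriums) are removed, waters are never treated as ligands, only the
#' first coordinate model of multi-model (e.g. NMR) entries is kept, and for
#' alternate locations of an atom the highest-occupancy conformer is retained
#' (ties broken by file order).
#'
#' Polymer chains are exposed both as chains and, where they can act as
#' ligands, as ligand instances: peptide chains of at most
#' `peptide_ligand_max` residues and nucleic-acid chains of any length.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param peptide_ligand_max maximum length (residues) for a peptide chain to
#'   be considered a ligand; longer peptide partners are excluded.
#' @return an object of class `structure_model` with elements `entry_id`,
#'   `chains` (named list), `ligands` (list of ligand instances) and
#'   `model_index`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            peptide_ligand_max = 30L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- switch(format,
    pdb = read_pdb_atoms(path),
    mmcif = read_mmcif_atoms(path)
  )
  build_structure_model(raw,
    entry_id = toupper(sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
      basename(path),
      ignore.case = TRUE
    )),
    peptide_ligand_max = peptide_ligand_max
  )
}

# Read PDB into the internal raw atom table via bio3d. Keeps the first model
# and all alternate locations (resolved later by occupancy).
read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e))
    }
  )
  a <- pdb$atom
  element <- a$elesy
  element[is.na(element) | element == ""] <- guess_element(a$elety[is.na(element) | element == ""])
  data.frame(
    record = a$type,
    name = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = toupper(element),
    stringsAsFactors = FALSE
  )
}

guess_element <- function(name) {
  # Strip digits/primes; 4-character names starting with H are hydrogens.
  el <- sub("^[0-9]*", "", gsub("['*0-9]", "", name))
  two <- toupper(substr(el, 1, 2))
  one <- toupper(substr(el, 1, 1))
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "MN", "FE", "NA", "CA", "CU", "NI", "CO", "SE"),
    two, one
  )
}

# Minimal mmCIF reader restricted to the atom_site category. Values are
# whitespace-delimited with optional single/double quoting; '.' and '?' mean
# absent. Only the first coordinate model is kept.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  if (length(loop_starts) == 0) stop("mmCIF parse error in '", path, "': no loop_ block")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_atom_site\\.", tags))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
      fields <- cif_split(ln)
      if (length(fields) != length(tags)) {
        stop("mmCIF parse error at line ", i, " of '", path, "': expected ",
          length(tags), " fields, found ", length(fields))
      }
      rows[[length(rows) + 1L]] <- fields
      i <- i + 1L
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_atom_site\\.", "", tags)
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% colnames(m)) return(cif_na(m[, nm]))
      rep(NA_character_, nrow(m))
    }
    model_num <- pick("pdbx_PDB_model_num")
    keep <- if (all(is.na(model_num))) rep(TRUE, nrow(m)) else model_num == model_num[1]
    m <- m[keep, , drop = FALSE]
    sel <- function(v) v[keep]
    return(data.frame(
      record = sel(pick("group_PDB")),
      name = sel(pick("label_atom_id", "auth_atom_id")),
      alt = ifelse(is.na(sel(pick("label_alt_id"))), "", sel(pick("label_alt_id"))),
      resid = sel(pick("auth_comp_id", "label_comp_id")),
      chain = sel(pick("auth_asym_id", "label_asym_id")),
      resno = as.integer(sel(pick("auth_seq_id", "label_seq_id"))),
      insert = ifelse(is.na(sel(pick("pdbx_PDB_ins_code"))), "", sel(pick("pdbx_PDB_ins_code"))),
      x = as.numeric(sel(pick("Cartn_x"))),
      y = as.numeric(sel(pick("Cartn_y"))),
      z = as.numeric(sel(pick("Cartn_z"))),
      occupancy = ifelse(is.na(as.numeric(sel(pick("occupancy")))), 1,
        as.numeric(sel(pick("occupancy")))),
      element = toupper(sel(pick("type_symbol"))),
      stringsAsFactors = FALSE
    ))
  }
  stop("mmCIF parse error in '", path, "': no atom_site loop found")
}

cif_split <- function(line) {
  out <- character(0)
  rest <- line
  while (nchar(rest) > 0) {
    rest <- sub("^\\s+", "", rest)
    if (nchar(rest) == 0) break
    ch <- substr(rest, 1, 1)
    if (ch %in% c("'", "\"")) {
      end <- regexpr(paste0(ch, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) stop("unterminated quote in mmCIF value")
      out <- c(out, substr(rest, 2, end))
      rest <- substr(rest, end + 2, nchar(rest))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) {
        out <- c(out, rest)
        rest <- ""
      } else {
        out <- c(out, substr(rest, 1, sp - 1))
        rest <- substr(rest, sp, nchar(rest))
      }
    }
  }
  out
}

cif_na <- function(v) {
  v[v %in% c(".", "?")] <- NA_character_
  v
}

# Shared post-processing: hydrogen/water removal, alt-loc resolution, chain
# and ligand assembly.
build_structure_model <- function(raw, entry_id, peptide_ligand_max = 30L) {
  if (is.na(entry_id) || !nzchar(entry_id)) entry_id <- "UNKNOWN"
  raw <- raw[!(raw$element %in% c("H", "D")), , drop = FALSE]
  raw$element[is.na(raw$element) | raw$element == ""] <- guess_element(raw$name[is.na(raw$element) | raw$element == ""])
  raw <- raw[!(raw$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(raw) == 0) stop("empty structure: no heavy atoms in '", entry_id, "'")

  # Alternate locations: one conformer per (chain, residue, atom name), the
  # one with the highest occupancy; ties resolved by file order.
  raw$ord <- seq_len(nrow(raw))
  key <- paste(raw$chain, raw$resno, raw$insert, raw$resid, raw$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(raw)), key), function(idx) {
    idx[which.max(raw$occupancy[idx])]
  }), use.names = FALSE)
  raw <- raw[sort(keep), , drop = FALSE]

  rkey <- paste(raw$chain, raw$resno, raw$insert, raw$resid, sep = "\r")
  res_order <- unique(rkey)
  residues <- lapply(res_order, function(k) {
    idx <- which(rkey == k)
    r <- raw[idx, , drop = FALSE]
    list(
      chain_id = r$chain[1],
      number = r$resno[1],
      icode = r$insert[1],
      name = r$resid[1],
      record = r$record[1],
      atoms = data.frame(
        name = r$name, element = r$element,
        x = r$x, y = r$y, z = r$z,
        occupancy = r$occupancy, alt = r$alt,
        stringsAsFactors = FALSE
      )
    )
  })

  is_water <- vapply(residues, function(r) r$name %in% WATER_CODES, logical(1))
  residues <- residues[!is_water]
  if (length(residues) == 0) stop("empty structure: only water in '", entry_id, "'")

  res_chain <- vapply(residues, function(r) r$chain_id, character(1))
  res_name <- vapply(residues, function(r) r$name, character(1))
  res_rec <- vapply(residues, function(r) r$record, character(1))

  chains <- list()
  ligands <- list()
  for (cid in unique(res_chain)) {
    in_chain <- res_chain == cid
    poly <- in_chain & res_rec == "ATOM" & (is_amino3(res_name) | is_nucleotide3(res_name))
    if (any(poly)) {
      cres <- residues[poly]
      names3 <- res_name[poly]
      type <- if (mean(is_amino3(names3)) >= 0.5) "protein" else "nucleic"
      seq1 <- if (type == "protein") aa_one(names3) else nuc_one(names3)
      chains[[cid]] <- structure(
        list(
          id = cid, residues = cres,
          sequence = paste(seq1, collapse = ""),
          type = type
        ),
        class = "structure_chain"
      )
    }
    # Everything else in the chain (HETATM groups, non-standard ATOM residues)
    # becomes a candidate ligand instance, one per residue group.
    het <- which(in_chain & !poly)
    for (i in het) {
      r <- residues[[i]]
      ligands[[length(ligands) + 1L]] <- new_ligand_instance(
        component_id = r$name,
        copy_key = paste0(r$chain_id, ":", r$number, r$icode),
        atoms = r$atoms,
        kind_hint = "non-polymer"
      )
    }
  }

  if (!any(vapply(chains, function(ch) ch$type == "protein", logical(1)))) {
    stop("empty structure: no protein chains in '", entry_id, "'")
  }

  # Polymer ligands: short peptides and nucleic-acid chains.
  for (ch in chains) {
    n <- length(ch$residues)
    as_ligand <- (ch$type == "protein" && n <= peptide_ligand_max) ||
      ch$type == "nucleic"
    if (as_ligand) {
      ligands[[length(ligands) + 1L]] <- new_ligand_instance(
        component_id = paste0(if (ch$type == "protein") "PEP_" else "NUC_", ch$id),
        copy_key = paste0(ch$id, ":polymer"),
        atoms = chain_atoms(ch),
        kind_hint = "polymer"
      )
    }
  }

  structure(
    list(entry_id = entry_id, chains = chains, ligands = ligands, model_index = 1L),
    class = "structure_model"
  )
}

new_ligand_instance <- function(component_id, copy_key, atoms, kind_hint) {
  stopifnot(nrow(atoms) > 0)
  structure(
    list(
      component_id = component_id, copy_key = copy_key,
      atoms = atoms, kind_hint = kind_hint
    ),
    class = "ligand_instance"
  )
}

# All heavy atoms of a chain as one atom table, with per-atom residue index.
chain_atoms <- function(chain) {
  parts <- lapply(seq_along(chain$residues), function(i) {
    a <- chain$residues[[i]]$atoms
    a$residue_index <- i
    a
  })
  do.call(rbind, parts)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$entry_id, "\n", sep = "")
  for (ch in x$chains) {
    cat(sprintf(
      "  chain %s (%s): %d residues\n", ch$id, ch$type,
      length(ch$residues)
    ))
  }
  cat(sprintf("  ligand instances: %d\n", length(x$ligands)))
  invisible(x)
}

# Distances --------------------------------------------------------------

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# Minimum Euclidean distance between two heavy-atom coordinate sets.
min_pair_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Minimum side-chain heavy-atom distance from a residue to a ligand
#'
#' The minimum Euclidean distance between any heavy (non-hydrogen) side-chain
#' atom of `residue` and any heavy atom of `ligand`. Backbone atoms
#' (N, CA, C, O, OXT) are excluded. Glycine has no side-chain heavy atom: by
#' default its CA is used as a proxy (`glycine = "ca_proxy"`); with
#' `glycine = "exclude"`, residues with no eligible atom return `NA`, the
#' "no side chain" sentinel.
#'
#' @param residue a residue from a `structure_model` chain.
#' @param ligand a `ligand_instance` (or any atom table with x/y/z/element).
#' @param glycine `"ca_proxy"` or `"exclude"`.
#' @return distance in Angstroms, or `NA` if the residue has no eligible atom.
#' @export
min_sidechain_distance <- function(residue, ligand,
                                   glycine = c("ca_proxy", "exclude")) {
  glycine <- match.arg(glycine)
  atoms <- residue$atoms
  heavy <- !(atoms$element %in% c("H", "D"))
  side <- heavy & !(atoms$name %in% PROTEIN_BACKBONE)
  if (!any(side)) {
    if (glycine == "ca_proxy" && any(heavy & atoms$name == "CA")) {
      side <- heavy & atoms$name == "CA"
    } else {
      return(NA_real_)
    }
  }
  lat <- if (inherits(ligand, "ligand_instance")) ligand$atoms else ligand
  lheavy <- !(lat$element %in% c("H", "D"))
  if (!any(lheavy)) return(NA_real_)
  min_pair_distance(atom_xyz(atoms[side, , drop = FALSE]),
                    atom_xyz(lat[lheavy, , drop = FALSE]))
}

# Minimum all-heavy-atom distance from a chain to a ligand.
chain_min_distance <- function(chain, ligand) {
  lat <- if (inherits(ligand, "ligand_instance")) ligand$atoms else ligand
  min_pair_distance(atom_xyz(chain_atoms(chain)), atom_xyz(lat))
}

#' Select the chain closest to a ligand among sequence-identical chains
#'
#' Among chains of `model` whose sequence is exactly `sequence`, returns the
#' chain with the smallest heavy-atom distance to `ligand`. Exact distance
#' ties are broken by lexicographic chain id. A polymer ligand's own chain is
#' never a candidate.
#'
#' @param model a `structure_model`.
#' @param sequence 1-letter protein sequence the chain must match exactly.
#' @param ligand a `ligand_instance`.
#' @return the selected chain.
#' @export
select_chain_for_ligand <- function(model, sequence, ligand) {
  self_chain <- if (ligand$kind_hint == "polymer") {
    sub(":polymer$", "", ligand$copy_key)
  } else {
    NA_character_
  }
  cand <- Filter(
    function(ch) ch$sequence == sequence && !identical(ch$id, self_chain),
    model$chains
  )
  if (length(cand) == 0) {
    stop("no chain in '", model$entry_id, "' matches the given sequence")
  }
  d <- vapply(cand, chain_min_distance, numeric(1), ligand = ligand)
  ids <- vapply(cand, function(ch) ch$id, character(1))
  cand[[order(d, ids)[1]]]
}

# PDB serialization ------------------------------------------------------

format_pdb_atom <- function(record, serial, name, resid, chain, resno, icode,
                            x, y, z, occ, element) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf("%-3s", name)
  name4 <- if (nchar(name) >= 4) name4 else paste0(" ", name4)
  sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, name4, " ", resid, chain, resno,
    ifelse(nzchar(icode), icode, " "), x, y, z, occ, 0, element
  )
}

#' Write a structure model as a minimal PDB file
#'
#' Serializes polymer chains as ATOM records and non-polymer ligand instances
#' as HETATM records, at standard fixed-column precision (3 decimals).
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  lines <- character(0)
  serial <- 0L
  for (ch in model$chains) {
    for (r in ch$residues) {
      for (i in seq_len(nrow(r$atoms))) {
        serial <- serial + 1L
        a <- r$atoms[i, ]
        lines <- c(lines, format_pdb_atom(
          "ATOM", serial, a$name, r$name, ch$id, r$number, r$icode,
          a$x, a$y, a$z, a$occupancy, a$element
        ))
      }
    }
  }
  for (lig in model$ligands) {
    if (lig$kind_hint == "polymer") next
    ckey <- strsplit(lig$copy_key, ":", fixed = TRUE)[[1]]
    resno <- as.integer(gsub("[^0-9-]", "", ckey[2]))
    for (i in seq_len(nrow(lig$atoms))) {
      serial <- serial + 1L
      a <- lig$atoms[i, ]
      lines <- c(lines, format_pdb_atom(
        "HETATM", serial, a$name, lig$component_id, ckey[1], resno, "",
        a$x, a$y, a$z, a$occupancy, a$element
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
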