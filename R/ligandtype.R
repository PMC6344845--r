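# Ligand grouping: DNA/RNA (base vs backbone), ions by name, small molecules,
# and metabolite-/drug-likeness by fingerprint Tanimoto similarity.

LIGAND_CLASSES <- c(
  "DNA_BASE", "DNA_BACKBONE", "RNA_BASE", "RNA_BACKBONE",
  "PEPTIDE", "ION", "METABOLITE", "DRUGLIKE", "SMALL_MOLECULE"
)

# Phosphate + sugar atom names of a nucleotide (PDB v3 primes and legacy '*').
NUCLEIC_BACKBONE <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
  "O5*", "C5*", "C4*", "O4*", "C3*", "O3*", "C2*", "O2*", "C1*"
)

#' Classify a nucleic-acid chain as DNA or RNA
#'
#' RNA is recognized by the 2'-hydroxyl of the ribose sugar: a chain is RNA
#' iff any of its residues carries an O2' atom, and DNA otherwise.
#'
#' @param chain a nucleic chain from a `structure_model`.
#' @return `"RNA"` or `"DNA"`.
#' @export
classify_nucleic_chain <- function(chain) {
  if (length(chain$residues) == 0) stop("empty chain")
  has_o2p <- vapply(chain$residues, function(r) {
    any(r$atoms$name %in% c("O2'", "O2*"))
  }, logical(1))
  if (any(has_o2p)) "RNA" else "DNA"
}

#' Partition a nucleotide residue's heavy atoms into base and backbone
#'
#' Backbone = phosphate + sugar atoms (P, OP1/2/3, O5', C5', C4', O4', C3',
#' O3', C2', O2', C1'); base = all remaining heavy atoms. The two sets
#' partition the residue's heavy atoms. Modified nucleotides are partitioned
#' over whatever standard atom names are present.
#'
#' @param residue a nucleotide residue.
#' @return list with atom tables `base` and `backbone`.
#' @export
partition_nucleic_atoms <- function(residue) {
  looks_nucleotide <- is_nucleotide3(residue$name) ||
    any(residue$atoms$name %in% c("C1'", "C1*"))
  if (!looks_nucleotide) {
    stop("residue '", residue$name, "' is not a nucleotide")
  }
  atoms <- residue$atoms[!(residue$atoms$element %in% c("H", "D")), , drop = FALSE]
  bb <- atoms$name %in% NUCLEIC_BACKBONE
  list(
    base = atoms[!bb, , drop = FALSE],
    backbone = atoms[bb, , drop = FALSE]
  )
}

# Subset a polymer nucleic ligand's atom table to base or backbone atoms.
nucleic_atom_subset <- function(atoms, part = c("base", "backbone")) {
  part <- match.arg(part)
  bb <- atoms$name %in% NUCLEIC_BACKBONE
  if (part == "backbone") atoms[bb, , drop = FALSE] else atoms[!bb, , drop = FALSE]
}

#' Tanimoto coefficient between two bit fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both fingerprints are empty.
#'
#' @param fp_a,fp_b equal-length logical/0-1 vectors.
#' @return coefficient in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b))
  }
  a <- as.logical(fp_a)
  b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Compute a bit fingerprint for a SMILES string
#'
#' Linear-path (Open Babel FP2) 1024-bit fingerprint by default.
#'
#' @param smiles SMILES string.
#' @param type Open Babel fingerprint name (default `"FP2"`).
#' @return 0/1 numeric vector, or `NULL` if the SMILES cannot be parsed.
#' @export
smiles_fingerprint <- function(smiles, type = "FP2") {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("package 'ChemmineOB' is required for fingerprint computation")
  }
  fp <- tryCatch(
    suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), type
    )),
    error = function(e) NULL
  )
  if (is.null(fp)) return(NULL)
  v <- as.numeric(fp)
  if (length(v) == 0) return(NULL)
  v
}

#' Build a reference compound set from SMILES
#'
#' @param smiles character vector of SMILES (e.g. a metabolite or drug list).
#' @param name label for the set.
#' @return object of class `reference_set` holding the fingerprint matrix.
#'   SMILES that fail to parse are dropped with a warning.
#' @export
reference_set <- function(smiles, name = "reference") {
  if (length(smiles) == 0) stop("empty reference set '", name, "'")
  fps <- lapply(smiles, smiles_fingerprint)
  bad <- vapply(fps, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " reference SMILES in '", name, "' failed to parse and were dropped")
  }
  if (all(bad)) stop("no parseable SMILES in reference set '", name, "'")
  structure(
    list(
      name = name, smiles = smiles[!bad],
      fingerprints = do.call(rbind, fps[!bad])
    ),
    class = "reference_set"
  )
}

#' Read a reference compound set from a SMILES file
#'
#' One SMILES per line, with an optional tab-separated identifier.
#'
#' @param path file path.
#' @param name label for the set.
#' @return a `reference_set`.
#' @export
read_reference_set <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  smiles <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  reference_set(smiles, name = name)
}

# Maximum Tanimoto of one fingerprint against a reference set.
max_tanimoto <- function(fp, ref) {
  if (is.null(fp)) return(NA_real_)
  max(apply(ref$fingerprints, 1, tanimoto, fp_b = fp))
}

#' Classify a chemical compound into ligand groups
#'
#' A compound whose full name contains the standalone word "ion"
#' (case-insensitive) is an ION. Any other compound is a SMALL_MOLECULE and
#' additionally METABOLITE and/or DRUGLIKE if its maximum Tanimoto
#' coefficient against the respective reference set is at least `threshold`.
#'
#' @param compound list with `component_id`, `full_name` and (for small
#'   molecules) `smiles`.
#' @param metabolites,drugs `reference_set` objects (either may be `NULL`).
#' @param threshold Tanimoto cutoff (default 0.9).
#' @return character vector of ligand class labels; `character(0)` with a
#'   warning if the compound's SMILES cannot be parsed.
#' @export
classify_ligand <- function(compound, metabolites = NULL, drugs = NULL,
                            threshold = 0.9) {
  stopifnot(nzchar(compound$component_id))
  if (is.null(compound$full_name) || !nzchar(compound$full_name)) {
    stop("compound '", compound$component_id, "' has no full name")
  }
  if (grepl("\\bion\\b", compound$full_name, ignore.case = TRUE)) {
    return("ION")
  }
  classes <- "SMALL_MOLECULE"
  if (!is.null(metabolites) || !is.null(drugs)) {
    fp <- if (!is.null(compound$smiles) && nzchar(compound$smiles)) {
      smiles_fingerprint(compound$smiles)
    } else {
      NULL
    }
    if (is.null(fp)) {
      warning("compound '", compound$component_id,
        "' has no parseable SMILES; skipping similarity classification")
      return(character(0))
    }
    if (!is.null(metabolites) && isTRUE(max_tanimoto(fp, metabolites) >= threshold)) {
      classes <- c(classes, "METABOLITE")
    }
    if (!is.null(drugs) && isTRUE(max_tanimoto(fp, drugs) >= threshold)) {
      classes <- c(classes, "DRUGLIKE")
    }
  }
  classes
}

#' Read a compound table (component id, full name, SMILES)
#'
#' @param path TSV with columns `component_id`, `full_name`, `smiles`.
#' @return data.frame.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("component_id", "full_name", "smiles")
  if (!all(need %in% names(df))) {
    stop("compound table '", path, "' must have columns: ",
      paste(need, collapse = ", "))
  }
  df
}
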