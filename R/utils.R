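#' @keywords internal
"_PACKAGE"

# Amino-acid tables ------------------------------------------------------

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1 <- stats::setNames(names(AA3), unname(AA3))

# Standard nucleotide component codes (DNA and RNA) and their 1-letter codes.
NUC3 <- c(
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "I",
  A = "A", C = "C", G = "G", U = "U", I = "I", T = "T", N = "N"
)

WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")

is_amino3 <- function(x) x %in% names(AA3)
is_nucleotide3 <- function(x) x %in% names(NUC3)

aa_one <- function(x) {
  out <- AA3[x]
  out[is.na(out)] <- "X"
  unname(out)
}

nuc_one <- function(x) {
  out <- NUC3[x]
  out[is.na(out)] <- "N"
  unname(out)
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 17L + as.integer(stream) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
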