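# Domain models and domain-instance hits; the per-instance inclusion filters
# (gathering threshold, terminal positions, consensus at high-information
# positions, at least one annotated binding residue).

AA_ORDER <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Construct a domain (profile HMM) model
#'
#' @param accession family accession.
#' @param n_match_states number of match states (>= 1).
#' @param gathering_threshold bit-score inclusion threshold.
#' @param emissions `n_match_states` x 20 matrix of match-state emission
#'   probabilities, columns in alphabetical amino-acid order
#'   (ACDEFGHIKLMNPQRSTVWY); each row must sum to 1.
#' @return object of class `domain_model`.
#' @export
domain_model <- function(accession, n_match_states, gathering_threshold,
                         emissions) {
  stopifnot(nzchar(accession), n_match_states >= 1)
  emissions <- as.matrix(emissions)
  if (nrow(emissions) != n_match_states || ncol(emissions) != 20) {
    stop("emissions must be n_match_states x 20")
  }
  if (any(abs(rowSums(emissions) - 1) > 1e-9)) {
    stop("emission distributions must each sum to 1")
  }
  colnames(emissions) <- AA_ORDER
  structure(
    list(
      accession = accession,
      n_match_states = as.integer(n_match_states),
      gathering_threshold = gathering_threshold,
      emissions = emissions
    ),
    class = "domain_model"
  )
}

#' Read domain models from JSON
#'
#' JSON array of objects with fields `accession`, `n_match_states`,
#' `gathering_threshold` and `emissions` (list of 20-vectors).
#'
#' @param path JSON file path.
#' @return named list of `domain_model` objects.
#' @export
read_domain_models <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- lapply(raw, function(m) {
    em <- if (is.matrix(m$emissions)) m$emissions else do.call(rbind, m$emissions)
    domain_model(
      accession = m$accession,
      n_match_states = m$n_match_states,
      gathering_threshold = m$gathering_threshold,
      emissions = em
    )
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "accession"))
}

#' Write domain models to JSON
#' @param models named list of `domain_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_models <- function(models, path) {
  out <- lapply(models, function(m) {
    list(
      accession = m$accession,
      n_match_states = m$n_match_states,
      gathering_threshold = m$gathering_threshold,
      emissions = lapply(seq_len(nrow(m$emissions)), function(i) unname(m$emissions[i, ]))
    )
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Walk an M/I/D alignment path into a match-state -> residue-index map.
alignment_to_state_map <- function(alignment, hmm_from, ali_from) {
  ops <- strsplit(alignment, "")[[1]]
  if (length(ops) == 0 || !all(ops %in% c("M", "I", "D"))) {
    stop("alignment path must be a non-empty string over {M, I, D}")
  }
  state <- as.integer(hmm_from)
  res <- as.integer(ali_from)
  keys <- integer(0)
  vals <- integer(0)
  for (op in ops) {
    if (op == "M") {
      keys <- c(keys, state)
      vals <- c(vals, res)
      state <- state + 1L
      res <- res + 1L
    } else if (op == "I") {
      res <- res + 1L
    } else {
      state <- state + 1L
    }
  }
  stats::setNames(vals, keys)
}

state_map_to_alignment <- function(state_map) {
  keys <- as.integer(names(state_map))
  vals <- as.integer(state_map)
  ops <- character(0)
  state <- keys[1]
  res <- vals[1]
  for (i in seq_along(keys)) {
    while (state < keys[i]) {
      ops <- c(ops, "D")
      state <- state + 1L
    }
    while (res < vals[i]) {
      ops <- c(ops, "I")
      res <- res + 1L
    }
    ops <- c(ops, "M")
    state <- state + 1L
    res <- res + 1L
  }
  paste(ops, collapse = "")
}

new_domain_hit <- function(protein_id, accession, bit_score, state_map) {
  keys <- as.integer(names(state_map))
  vals <- as.integer(state_map)
  if (length(keys) == 0 || any(diff(keys) <= 0) || any(diff(vals) <= 0)) {
    stop("state_map must be strictly increasing in both keys and values")
  }
  structure(
    list(
      protein_id = protein_id, accession = accession,
      bit_score = bit_score, state_map = stats::setNames(vals, keys)
    ),
    class = "domain_hit"
  )
}

#' Parse a domain hit table
#'
#' The table is a headered TSV in a domtblout-like per-domain dialect with
#' columns `protein_id`, `accession`, `bit_score`, `hmm_from`, `ali_from` and
#' `alignment`, where `alignment` is the alignment path over `M` (match state
#' aligned to a residue), `I` (inserted residue) and `D` (deleted match
#' state). Insertions advance only the residue index; deletions leave match
#' states unmapped.
#'
#' @param path hit table path.
#' @param models optional named list of `domain_model`s for validation of
#'   state indices against the model length.
#' @return list of `domain_hit` objects.
#' @export
parse_domain_hits <- function(path, models = NULL) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("cannot read hit table '", path, "': ", conditionMessage(e))
  )
  need <- c("protein_id", "accession", "bit_score", "hmm_from", "ali_from", "alignment")
  if (!all(need %in% names(df))) {
    stop("hit table '", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sm <- tryCatch(
      alignment_to_state_map(row$alignment, row$hmm_from, row$ali_from),
      error = function(e) {
        stop("malformed hit at line ", i + 1L, " of '", path, "': ",
          conditionMessage(e))
      }
    )
    if (!is.null(models)) {
      m <- models[[row$accession]]
      if (!is.null(m) && max(as.integer(names(sm))) > m$n_match_states) {
        stop("malformed hit at line ", i + 1L, " of '", path,
          "': match state beyond model length")
      }
    }
    new_domain_hit(row$protein_id, row$accession, row$bit_score, sm)
  })
}

#' Write domain hits in the hit-table dialect read by [parse_domain_hits()]
#' @param hits list of `domain_hit` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  df <- do.call(rbind, lapply(hits, function(h) {
    data.frame(
      protein_id = h$protein_id, accession = h$accession,
      bit_score = h$bit_score,
      hmm_from = as.integer(names(h$state_map))[1],
      ali_from = as.integer(h$state_map)[1],
      alignment = state_map_to_alignment(h$state_map),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Information content of a match-state emission distribution
#'
#' `log2(20) - H(p)` in bits, relative to a uniform background over the 20
#' amino acids; ranges from 0 (uniform) to `log2(20)` (point mass).
#'
#' @param emission probability vector of length 20.
#' @return information content in bits.
#' @export
information_content <- function(emission) {
  if (length(emission) != 20 || any(emission < 0)) {
    stop("emission must be a length-20 non-negative vector")
  }
  if (abs(sum(emission) - 1) > 1e-6) {
    stop("emission distribution must sum to 1 (got ", sum(emission), ")")
  }
  p <- emission[emission > 0]
  h <- -sum(p * log2(p))
  log2(20) - h
}

#' Apply the domain-instance inclusion filters
#'
#' An instance passes when it (i) meets the family's gathering threshold,
#' (ii) has residues at the first and last match states, (iii) carries the
#' modal amino acid at every mapped match state whose emission information
#' content is at least `ic_threshold` bits, and (iv) maps at least one
#' residue annotated as ligand-binding.
#'
#' @param hit a `domain_hit`.
#' @param model the matching `domain_model`.
#' @param sequence the protein sequence the hit indexes into.
#' @param binding_residues integer vector of annotated binding residue
#'   indices (1-based).
#' @param ic_threshold information-content threshold in bits (default 4).
#' @return object of class `instance_filter` with `passed` and `reasons`.
#' @export
filter_instance <- function(hit, model, sequence, binding_residues,
                            ic_threshold = 4) {
  if (hit$accession != model$accession) {
    stop("hit accession '", hit$accession, "' does not match model '",
      model$accession, "'")
  }
  reasons <- character(0)
  if (hit$bit_score < model$gathering_threshold) {
    reasons <- c(reasons, "gathering")
  }
  keys <- as.integer(names(hit$state_map))
  if (!(1L %in% keys) || !(model$n_match_states %in% keys)) {
    reasons <- c(reasons, "terminal_positions")
  }
  ic <- apply(model$emissions, 1, information_content)
  high <- which(ic >= ic_threshold)
  bad_consensus <- FALSE
  for (s in intersect(high, keys)) {
    em <- model$emissions[s, ]
    modal <- AA_ORDER[em >= max(em) - 1e-12]
    obs <- substr(sequence, hit$state_map[[as.character(s)]], hit$state_map[[as.character(s)]])
    if (!(obs %in% modal)) bad_consensus <- TRUE
  }
  if (bad_consensus) reasons <- c(reasons, "consensus_at_high_IC")
  if (length(intersect(as.integer(hit$state_map), binding_residues)) == 0) {
    reasons <- c(reasons, "no_binding_residue")
  }
  structure(
    list(passed = length(reasons) == 0, reasons = reasons),
    class = "instance_filter"
  )
}

#' @export
print.instance_filter <- function(x, ...) {
  if (x$passed) {
    cat("<instance_filter> passed\n")
  } else {
    cat("<instance_filter> failed:", paste(x$reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a binding-annotation table
#'
#' BioLiP-style TSV with columns `structure_id`, `chain`, `ligand_id` and
#' `binding_positions` (comma-separated 1-based residue indices in the
#' chain's sequence).
#'
#' @param path TSV path.
#' @return data.frame with a list-column `positions` of integer vectors.
#' @export
read_binding_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
    colClasses = c(binding_positions = "character"))
  need <- c("structure_id", "chain", "ligand_id", "binding_positions")
  if (!all(need %in% names(df))) {
    stop("annotation table '", path, "' must have columns: ",
      paste(need, collapse = ", "))
  }
  df$positions <- lapply(strsplit(df$binding_positions, ","), function(v) {
    as.integer(v[nzchar(trimws(v))])
  })
  df
}
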