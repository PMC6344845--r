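# Transfer of per-match-state binding frequencies onto residues of query
# protein sequences via domain hits.

#' Project binding frequencies onto query protein residues
#'
#' Every (hit, mapped match state) pair with a frequency entry yields one
#' annotated site. The `confident` flag is set when the (accession,
#' ligand class) pair is in the confident set and the site's frequency
#' reaches that pair's threshold. Residues covered by several domains or
#' ligand classes yield several rows; see [collapse_sites()] for the
#' per-residue maximum view.
#'
#' @param hits list of `domain_hit`s on query proteins.
#' @param tables a binding-frequency table: a `bindfreq` object, a list of
#'   them, or a data.frame in the release shape (see [write_bindfreq()]).
#' @param confident optional confident set: a data.frame with columns
#'   `accession`, `ligand_class`, `threshold`, or a list of
#'   `confident_interaction`s. With `NULL`, no site is flagged confident.
#' @return data.frame with columns `protein_id`, `residue_index`,
#'   `ligand_class`, `domain`, `frequency`, `confident`.
#' @export
transfer_frequencies <- function(hits, tables, confident = NULL) {
  tab <- normalize_bindfreq_table(tables)
  conf <- normalize_confident_set(confident)
  out <- list()
  for (h in hits) {
    rows <- tab[tab$domain_accession == h$accession, , drop = FALSE]
    if (nrow(rows) == 0) {
      warning("hit on '", h$protein_id, "' references unknown accession '",
        h$accession, "'; skipped")
      next
    }
    keys <- as.integer(names(h$state_map))
    vals <- as.integer(h$state_map)
    for (lc in unique(rows$ligand_class)) {
      sub <- rows[rows$ligand_class == lc, , drop = FALSE]
      freq <- stats::setNames(sub$binding_frequency, sub$match_state)
      thr <- NA_real_
      if (!is.null(conf)) {
        hitrow <- conf$accession == h$accession & conf$ligand_class == lc
        if (any(hitrow)) thr <- conf$threshold[which(hitrow)[1]]
      }
      f <- freq[as.character(keys)]
      keep <- !is.na(f)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        protein_id = h$protein_id,
        residue_index = vals[keep],
        ligand_class = lc,
        domain = h$accession,
        frequency = unname(f[keep]),
        confident = !is.na(thr) & unname(f[keep]) >= thr,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      protein_id = character(0), residue_index = integer(0),
      ligand_class = character(0), domain = character(0),
      frequency = numeric(0), confident = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

normalize_bindfreq_table <- function(tables) {
  if (inherits(tables, "bindfreq")) tables <- list(tables)
  if (is.data.frame(tables)) {
    need <- c("domain_accession", "ligand_class", "match_state", "binding_frequency")
    stopifnot(all(need %in% names(tables)))
    return(tables)
  }
  do.call(rbind, lapply(tables, as.data.frame))
}

normalize_confident_set <- function(confident) {
  if (is.null(confident)) return(NULL)
  if (inherits(confident, "confident_interaction")) confident <- list(confident)
  if (is.data.frame(confident)) return(confident)
  do.call(rbind, lapply(confident, function(ci) {
    data.frame(
      accession = ci$accession, ligand_class = ci$ligand_class,
      threshold = ci$threshold, stringsAsFactors = FALSE
    )
  }))
}

#' Collapse annotated sites to one row per residue
#'
#' Keeps, for each (protein, residue), the row with the maximum frequency
#' (confident rows win ties).
#'
#' @param sites data.frame from [transfer_frequencies()].
#' @return collapsed data.frame.
#' @export
collapse_sites <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$protein_id, sites$residue_index, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(sites)), key), function(idx) {
    idx[order(-sites$frequency[idx], -sites$confident[idx])[1]]
  }), use.names = FALSE)
  out <- sites[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotated sites as TSV
#' @param sites data.frame from [transfer_frequencies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export confident sites as BED intervals
#'
#' Contiguous runs of confident residues per (protein, ligand class) become
#' 0-based half-open intervals.
#'
#' @param sites data.frame from [transfer_frequencies()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_confident_bed <- function(sites, path) {
  conf <- sites[sites$confident, , drop = FALSE]
  lines <- character(0)
  if (nrow(conf) > 0) {
    key <- paste(conf$protein_id, conf$ligand_class, sep = "\r")
    for (k in unique(key)) {
      sub <- conf[key == k, , drop = FALSE]
      pos <- sort(unique(sub$residue_index))
      runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
      for (run in runs) {
        lines <- c(lines, sprintf(
          "%s\t%d\t%d\t%s", sub$protein_id[1],
          min(run) - 1L, max(run), sub$ligand_class[1]
        ))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read query protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_query_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  stats::setNames(unname(seqs), ids)
}
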