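# Core scoring engine: per-match-state minimum-distance profiles across
# structural instances, Henikoff sequence weighting, weighted binding
# frequencies at a distance cutoff, and bootstrap standard errors.

#' Build one domain instance from a hit, a structure and a ligand
#'
#' Resolves the hit's chain (the chain closest to the ligand among chains
#' sequence-identical to the hit's chain, following the closest-chain rule),
#' then records for every mapped match state the residue's amino acid, its
#' minimum side-chain heavy-atom distance to the ligand, and whether the
#' residue is annotated as binding.
#'
#' For the nucleic ligand classes the ligand's atoms are restricted to the
#' base or backbone subset before distances are computed.
#'
#' @param hit a `domain_hit`; its `protein_id` must be `<entry>_<chain>`.
#' @param model a `structure_model` containing that chain.
#' @param ligand a `ligand_instance` from `model`.
#' @param ligand_class one of the ligand class labels (see `LIGAND_CLASSES`).
#' @param binding_residues optional integer vector of annotated binding
#'   residue indices (1-based sequence positions) for this chain-ligand pair.
#' @param glycine glycine handling for side-chain distances
#'   (see [min_sidechain_distance()]).
#' @param n_states total number of match states of the domain model (default:
#'   largest mapped state of the hit).
#' @return object of class `domain_instance` with per-state vectors `seq`,
#'   `dist` and `binding` (NA at unmapped states).
#' @export
build_instance <- function(hit, model, ligand, ligand_class = "SMALL_MOLECULE",
                           binding_residues = NULL,
                           glycine = c("ca_proxy", "exclude"),
                           n_states = NULL) {
  glycine <- match.arg(glycine)
  chain_id <- sub("^.*_", "", hit$protein_id)
  chain0 <- model$chains[[chain_id]]
  if (is.null(chain0)) {
    stop("chain '", chain_id, "' of hit '", hit$protein_id,
      "' not found in structure '", model$entry_id, "'")
  }
  chain <- select_chain_for_ligand(model, chain0$sequence, ligand)

  lig_atoms <- ligand$atoms
  if (ligand_class %in% c("DNA_BASE", "RNA_BASE")) {
    lig_atoms <- nucleic_atom_subset(lig_atoms, "base")
  } else if (ligand_class %in% c("DNA_BACKBONE", "RNA_BACKBONE")) {
    lig_atoms <- nucleic_atom_subset(lig_atoms, "backbone")
  }
  if (nrow(lig_atoms) == 0) {
    stop("ligand '", ligand$component_id, "' has no atoms in the requested subset")
  }

  n_states <- n_states %||% max(as.integer(names(hit$state_map)))
  seqv <- rep(NA_character_, n_states)
  dist <- rep(NA_real_, n_states)
  bind <- rep(NA, n_states)
  keys <- as.integer(names(hit$state_map))
  vals <- as.integer(hit$state_map)
  for (i in seq_along(keys)) {
    res_idx <- vals[i]
    if (res_idx > length(chain$residues)) {
      stop("hit '", hit$protein_id, "' maps beyond chain length")
    }
    res <- chain$residues[[res_idx]]
    d <- min_sidechain_distance(res, lig_atoms, glycine = glycine)
    # "no side chain" sentinel (glycine-excluded mode): state left unmapped.
    if (is.na(d)) next
    seqv[keys[i]] <- substr(chain$sequence, res_idx, res_idx)
    dist[keys[i]] <- d
    bind[keys[i]] <- if (is.null(binding_residues)) NA else res_idx %in% binding_residues
  }
  structure(
    list(
      id = paste0(model$entry_id, "_", chain$id, ":", ligand$copy_key),
      accession = hit$accession, ligand_class = ligand_class,
      n_states = n_states, seq = seqv, dist = dist, binding = bind
    ),
    class = "domain_instance"
  )
}

#' Construct a domain instance directly from per-state vectors
#'
#' Mostly useful in tests and simulations; `build_instance()` is the
#' structure-driven constructor.
#'
#' @param id instance identifier.
#' @param seq per-state amino-acid characters (NA at unmapped states).
#' @param dist per-state minimum distances (NA at unmapped states).
#' @param binding optional per-state logical binding labels.
#' @param accession,ligand_class instance metadata.
#' @return a `domain_instance`.
#' @export
domain_instance <- function(id, seq, dist, binding = NULL,
                            accession = "DOM", ligand_class = "SMALL_MOLECULE") {
  stopifnot(length(seq) == length(dist))
  if (is.null(binding)) binding <- rep(NA, length(seq))
  stopifnot(length(binding) == length(seq))
  if (any(!is.na(dist) & dist < 0)) stop("distances must be non-negative")
  structure(
    list(
      id = id, accession = accession, ligand_class = ligand_class,
      n_states = length(seq), seq = as.character(seq),
      dist = as.numeric(dist), binding = as.logical(binding)
    ),
    class = "domain_instance"
  )
}

#' Aggregate instances into a per-state distance profile
#'
#' @param instances list of `domain_instance` objects sharing one accession
#'   and one ligand class.
#' @return object of class `distance_profile` with instance-by-state matrices
#'   `dist`, `seq` and `binding` (rows named by instance id).
#' @export
build_distance_profile <- function(instances) {
  stopifnot(length(instances) >= 1)
  acc <- unique(vapply(instances, `[[`, character(1), "accession"))
  lc <- unique(vapply(instances, `[[`, character(1), "ligand_class"))
  if (length(acc) > 1) stop("mixed accessions: ", paste(acc, collapse = ", "))
  if (length(lc) > 1) stop("mixed ligand classes: ", paste(lc, collapse = ", "))
  n_states <- max(vapply(instances, `[[`, integer(1), "n_states"))
  pad <- function(v, fill) c(v, rep(fill, n_states - length(v)))
  ids <- vapply(instances, `[[`, character(1), "id")
  dist <- do.call(rbind, lapply(instances, function(x) pad(x$dist, NA_real_)))
  seqm <- do.call(rbind, lapply(instances, function(x) pad(x$seq, NA_character_)))
  bind <- do.call(rbind, lapply(instances, function(x) pad(x$binding, NA)))
  rownames(dist) <- rownames(seqm) <- rownames(bind) <- ids
  structure(
    list(
      accession = acc, ligand_class = lc, n_states = n_states,
      instance_ids = ids, dist = dist, seq = seqm, binding = bind
    ),
    class = "distance_profile"
  )
}

#' Henikoff & Henikoff position-based sequence weights
#'
#' For alignment column `c` with `r_c` distinct residue types, an instance
#' carrying a type shared by `n` instances receives column score
#' `1 / (r_c * n)`. An instance's raw weight is the mean of its column scores
#' over its non-gap columns; weights are normalized to sum to 1. Gap cells
#' contribute no residue type and receive no score.
#'
#' @param alignment character matrix (instances x match states), NA for gaps;
#'   or a `distance_profile` (its `seq` matrix is used).
#' @return named numeric vector of weights summing to 1.
#' @export
henikoff_weights <- function(alignment) {
  if (inherits(alignment, "distance_profile")) alignment <- alignment$seq
  stopifnot(is.matrix(alignment), nrow(alignment) >= 1, ncol(alignment) >= 1)
  n <- nrow(alignment)
  if (n == 1) {
    return(stats::setNames(1, rownames(alignment)))
  }
  raw <- numeric(n)
  ncols <- integer(n)
  for (c_ in seq_len(ncol(alignment))) {
    col <- alignment[, c_]
    ok <- !is.na(col)
    if (!any(ok)) next
    tab <- table(col[ok])
    r_c <- length(tab)
    sc <- 1 / (r_c * as.numeric(tab[col[ok]]))
    raw[ok] <- raw[ok] + sc
    ncols[ok] <- ncols[ok] + 1L
  }
  if (any(ncols == 0)) {
    stop("instance(s) with all-gap alignment rows: ",
      paste(rownames(alignment)[ncols == 0], collapse = ", "))
  }
  w <- raw / ncols
  w <- w / sum(w)
  stats::setNames(w, rownames(alignment))
}

#' Weighted per-state binding frequencies at a distance cutoff
#'
#' For match state `s`, the binding frequency is the weighted fraction of
#' instances mapping `s` whose minimum side-chain distance is within
#' `cutoff`: `sum(w_i [d_is <= cutoff]) / sum(w_i over i mapping s)`. States
#' mapped by no instance are reported as NA (absent), not 0.
#'
#' @param profile a `distance_profile`.
#' @param weights named weight vector over instances (default: Henikoff
#'   weights computed from the profile's alignment).
#' @param cutoff distance cutoff in Angstroms (default 3.6).
#' @return numeric vector of per-state frequencies (NA where absent), with
#'   attribute `n_instances` (per-state mapped-instance counts).
#' @export
binding_frequency <- function(profile, weights = NULL, cutoff = 3.6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(weights)) weights <- henikoff_weights(profile)
  if (length(weights) != nrow(profile$dist)) {
    stop("need one weight per instance")
  }
  freq <- rep(NA_real_, profile$n_states)
  n_inst <- integer(profile$n_states)
  for (s in seq_len(profile$n_states)) {
    mapped <- !is.na(profile$dist[, s])
    n_inst[s] <- sum(mapped)
    if (!any(mapped)) next
    wtot <- sum(weights[mapped])
    freq[s] <- sum(weights[mapped & profile$dist[, s] <= cutoff]) / wtot
  }
  attr(freq, "n_instances") <- n_inst
  freq
}

#' Bootstrap standard errors of binding frequencies
#'
#' Resamples instances with replacement `B` times; per resample the Henikoff
#' weights are recomputed (set `recompute_weights = FALSE` to reuse the
#' original weights) and per-state frequencies recalculated. The per-state SE
#' is the standard deviation over resamples in which the state was mapped.
#'
#' @param instances list of `domain_instance`s (>= 2) or a `distance_profile`.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param cutoff distance cutoff in Angstroms.
#' @param recompute_weights recompute Henikoff weights per resample?
#' @return numeric vector of per-state standard errors (NA where absent).
#' @export
bootstrap_se <- function(instances, B = 1000, seed = 1, cutoff = 3.6,
                         recompute_weights = TRUE) {
  profile <- if (inherits(instances, "distance_profile")) {
    instances
  } else {
    build_distance_profile(instances)
  }
  n <- nrow(profile$dist)
  if (n < 2) stop("bootstrap requires at least 2 instances")
  if (B < 2) stop("B must be at least 2")
  w0 <- if (recompute_weights) NULL else henikoff_weights(profile)
  mat <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = profile$n_states)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      sub <- profile
      sub$dist <- profile$dist[idx, , drop = FALSE]
      sub$seq <- profile$seq[idx, , drop = FALSE]
      rownames(sub$dist) <- rownames(sub$seq) <- paste0("b", seq_len(n))
      w <- if (recompute_weights) henikoff_weights(sub) else {
        wi <- w0[idx]
        wi / sum(wi)
      }
      out[b, ] <- binding_frequency(sub, weights = unname(w), cutoff = cutoff)
    }
    out
  })
  apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col)
  })
}

#' Fit per-domain-position ligand-binding frequencies
#'
#' The central estimator: aggregates structural instances of one
#' domain-ligand pair into a distance profile, computes Henikoff sequence
#' weights, and estimates the weighted fraction of instances within `cutoff`
#' of the ligand at each match state, optionally with bootstrap standard
#' errors.
#'
#' @param instances list of `domain_instance` objects (one domain-ligand
#'   pair).
#' @param cutoff residue-to-ligand distance cutoff in Angstroms (default
#'   3.6, capturing hydrogen bonds and van der Waals contacts while excluding
#'   water-mediated interactions).
#' @param bootstrap number of bootstrap resamples for standard errors
#'   (0 to skip; 1000 is the conventional choice).
#' @param seed RNG seed for the bootstrap.
#' @param recompute_weights recompute Henikoff weights inside each bootstrap
#'   resample (default TRUE).
#' @return object of class `bindfreq` with components `accession`,
#'   `ligand_class`, `frequency`, `se`, `n_instances`, `weights`, `cutoff`
#'   and the underlying `profile`.
#' @seealso [binding_frequency()], [bootstrap_se()], [cross_validate()]
#' @export
bindfreq <- function(instances, cutoff = 3.6, bootstrap = 0, seed = 1,
                     recompute_weights = TRUE) {
  profile <- if (inherits(instances, "distance_profile")) {
    instances
  } else {
    build_distance_profile(instances)
  }
  w <- henikoff_weights(profile)
  freq <- binding_frequency(profile, weights = w, cutoff = cutoff)
  se <- if (bootstrap > 0 && nrow(profile$dist) >= 2) {
    bootstrap_se(profile, B = bootstrap, seed = seed, cutoff = cutoff,
      recompute_weights = recompute_weights)
  } else {
    rep(NA_real_, profile$n_states)
  }
  structure(
    list(
      accession = profile$accession, ligand_class = profile$ligand_class,
      frequency = as.numeric(freq), se = se,
      n_instances = attr(freq, "n_instances"),
      weights = w, cutoff = cutoff, profile = profile
    ),
    class = "bindfreq"
  )
}

#' @export
print.bindfreq <- function(x, ...) {
  cat(sprintf(
    "<bindfreq> %s / %s: %d match states, %d instances, cutoff %.1f A\n",
    x$accession, x$ligand_class, length(x$frequency),
    nrow(x$profile$dist), x$cutoff
  ))
  shown <- which(!is.na(x$frequency) & x$frequency > 0)
  if (length(shown)) {
    cat("  positive-frequency states:\n")
    for (s in shown) {
      cat(sprintf("    state %3d: %.3f%s (n=%d)\n", s, x$frequency[s],
        if (is.na(x$se[s])) "" else sprintf(" +/- %.3f", x$se[s]),
        x$n_instances[s]))
    }
  } else {
    cat("  no positive-frequency states\n")
  }
  invisible(x)
}

#' @export
coef.bindfreq <- function(object, ...) {
  stats::setNames(object$frequency, seq_along(object$frequency))
}

#' @export
summary.bindfreq <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, accession = object$accession,
    ligand_class = object$ligand_class, cutoff = object$cutoff),
    class = "summary.bindfreq")
}

#' @export
print.summary.bindfreq <- function(x, ...) {
  cat(sprintf("Binding frequencies for %s / %s (cutoff %.1f A)\n",
    x$accession, x$ligand_class, x$cutoff))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bindfreq <- function(x, ...) {
  data.frame(
    domain_accession = x$accession,
    ligand_class = x$ligand_class,
    match_state = seq_along(x$frequency),
    binding_frequency = x$frequency,
    bootstrap_se = x$se,
    n_instances = x$n_instances,
    stringsAsFactors = FALSE
  )
}

#' @export
plot.bindfreq <- function(x, ...) {
  f <- ifelse(is.na(x$frequency), 0, x$frequency)
  bp <- graphics::barplot(f,
    names.arg = seq_along(f),
    xlab = "match state", ylab = "binding frequency",
    ylim = c(0, 1.05),
    main = paste(x$accession, "/", x$ligand_class), ...
  )
  ok <- !is.na(x$se) & !is.na(x$frequency)
  if (any(ok)) {
    graphics::arrows(bp[ok], pmax(0, x$frequency[ok] - x$se[ok]),
      bp[ok], pmin(1, x$frequency[ok] + x$se[ok]),
      angle = 90, code = 3, length = 0.02
    )
  }
  invisible(x)
}

#' Write a binding-frequency table as TSV
#'
#' One row per match state with columns `domain_accession`, `ligand_class`,
#' `match_state`, `binding_frequency`, `bootstrap_se`, `n_instances` (the
#' release shape of the resource).
#'
#' @param x a `bindfreq` object or a list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bindfreq <- function(x, path) {
  if (inherits(x, "bindfreq")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-frequency table written by [write_bindfreq()]
#' @param path TSV path.
#' @return data.frame in the release shape.
#' @export
read_bindfreq <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
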