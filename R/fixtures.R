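# Synthetic co-complex generator: toy domain families with planted binding
# geometry, and toy proteomes with site lists, so the whole pipeline is
# testable without external databases.

#' Specification of a synthetic domain family
#'
#' Describes a family of single-chain co-complex structures with a planted
#' interface: residues at `binding_states` sit (on average) within
#' `binding_distance_mean` of the ligand, all others at
#' `nonbinding_distance_mean`, with Gaussian noise truncated at 1.5 Angstroms.
#' Sequences are mutated from a random consensus at `mutation_rate`;
#' `redundancy` appends that many exact structural+sequence copies of each
#' instance (uniform redundancy, under which Henikoff weighting leaves
#' frequencies exactly unchanged).
#'
#' @param n_states match states per domain.
#' @param n_instances number of (distinct) structural instances.
#' @param binding_states indices of planted binding states.
#' @param binding_distance_mean,nonbinding_distance_mean mean planted
#'   distances in Angstroms (must straddle the 3.6 cutoff).
#' @param distance_noise_sd Gaussian noise on planted distances.
#' @param mutation_rate per-position substitution probability from the
#'   consensus.
#' @param redundancy exact-duplicate copies appended per instance.
#' @param seed RNG seed.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_states = 12, n_instances = 10,
                        binding_states = c(3, 5, 9),
                        binding_distance_mean = 3.0,
                        nonbinding_distance_mean = 6.5,
                        distance_noise_sd = 0.25,
                        mutation_rate = 0.1,
                        redundancy = 0, seed = 1) {
  if (!(binding_distance_mean < 3.6 && 3.6 < nonbinding_distance_mean)) {
    stop("binding_distance_mean < 3.6 < nonbinding_distance_mean required")
  }
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate in [0,1]")
  if (any(binding_states < 1) || any(binding_states > n_states)) {
    stop("binding_states out of range")
  }
  structure(
    list(
      n_states = as.integer(n_states), n_instances = as.integer(n_instances),
      binding_states = as.integer(binding_states),
      binding_distance_mean = binding_distance_mean,
      nonbinding_distance_mean = nonbinding_distance_mean,
      distance_noise_sd = distance_noise_sd,
      mutation_rate = mutation_rate,
      redundancy = as.integer(redundancy), seed = as.integer(seed)
    ),
    class = "family_spec"
  )
}

# Random unit vectors, reasonably separated by rejection on pairwise cosine.
random_directions <- function(n) {
  out <- matrix(NA_real_, n, 3)
  i <- 1L
  while (i <= n) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (i == 1 || all(out[seq_len(i - 1), , drop = FALSE] %*% v < 0.95)) {
      out[i, ] <- v
      i <- i + 1L
    }
  }
  out
}

truncated_normal <- function(n, mean, sd, lower = 1.5) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 1000L) {
      out[bad] <- lower
      break
    }
  }
  out
}

#' Generate a synthetic domain family with planted binding geometry
#'
#' Writes, under `dir`: one PDB per instance (`structures/`), a hit table
#' (`hits.tsv`), domain-model metadata (`model.json`) and a binding
#' annotation table (`annotation.tsv`). Residues are two-atom stubs (CA plus
#' one side-chain atom placed so that its minimum distance to the ligand
#' equals the planted value exactly); the ligand is a compact 3-8 heavy-atom
#' pseudo-molecule. Residues within 3.6 Angstroms of the ligand are annotated
#' as binding. Fully reproducible from `spec$seed`.
#'
#' @param spec a `family_spec`.
#' @param dir output directory (created if needed).
#' @param accession domain accession used in the hit table and model.
#' @return list with paths, the spec, and the planted ground truth
#'   (consensus, per-instance sequences and distances, binding states).
#' @export
make_toy_family <- function(spec, dir, accession = "TOYDOM") {
  stopifnot(inherits(spec, "family_spec"))
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  aa_pool <- setdiff(AA_ORDER, "G") # two-atom stubs: keep glycine out
  with_seed(spec$seed, {
    n <- spec$n_instances
    ns <- spec$n_states
    n_lig <- sample(3:8, 1)
    lig_xyz <- matrix(stats::runif(n_lig * 3, -0.6, 0.6), n_lig, 3)
    lig_el <- sample(c("C", "N", "O"), n_lig, replace = TRUE)
    dirs <- random_directions(ns)
    consensus <- sample(aa_pool, ns, replace = TRUE)

    mean_d <- ifelse(seq_len(ns) %in% spec$binding_states,
      spec$binding_distance_mean, spec$nonbinding_distance_mean)
    sequences <- matrix(NA_character_, n, ns)
    dists <- matrix(NA_real_, n, ns)
    for (i in seq_len(n)) {
      s <- consensus
      mut <- stats::runif(ns) < spec$mutation_rate
      for (j in which(mut)) s[j] <- sample(setdiff(aa_pool, s[j]), 1)
      sequences[i, ] <- s
      dists[i, ] <- if (spec$distance_noise_sd > 0) {
        truncated_normal(ns, mean_d, spec$distance_noise_sd)
      } else {
        pmax(mean_d, 1.5)
      }
    }

    # Uniform redundancy: `redundancy` exact copies of each instance.
    idx <- rep(seq_len(n), each = 1 + spec$redundancy)
    entry_ids <- sprintf("TOY%03d", seq_along(idx))

    structure_paths <- character(length(idx))
    ann_rows <- list()
    for (k in seq_along(idx)) {
      i <- idx[k]
      lines <- character(0)
      serial <- 0L
      for (s in seq_len(ns)) {
        u <- dirs[s, ]
        # Support point of the ligand in direction u: placing the side-chain
        # atom at support + d*u makes its minimum ligand distance exactly d.
        sup <- lig_xyz[which.max(lig_xyz %*% u), ]
        cb <- sup + dists[i, s] * u
        ca <- sup + (dists[i, s] + 1.5) * u
        res3 <- AA1[[sequences[i, s]]]
        serial <- serial + 1L
        lines <- c(lines, format_pdb_atom("ATOM", serial, "CA", res3, "A",
          s, "", ca[1], ca[2], ca[3], 1, "C"))
        serial <- serial + 1L
        lines <- c(lines, format_pdb_atom("ATOM", serial, "CB", res3, "A",
          s, "", cb[1], cb[2], cb[3], 1, "C"))
      }
      for (j in seq_len(n_lig)) {
        serial <- serial + 1L
        lines <- c(lines, format_pdb_atom("HETATM", serial,
          paste0(lig_el[j], j), "LIG", "A", 900L, "",
          lig_xyz[j, 1], lig_xyz[j, 2], lig_xyz[j, 3], 1, lig_el[j]))
      }
      p <- file.path(dir, "structures", paste0(entry_ids[k], ".pdb"))
      writeLines(c(lines, "END"), p)
      structure_paths[k] <- p
      binding <- which(round(dists[i, ], 3) <= 3.6)
      ann_rows[[k]] <- data.frame(
        structure_id = entry_ids[k], chain = "A", ligand_id = "LIG",
        binding_positions = paste(binding, collapse = ","),
        stringsAsFactors = FALSE
      )
    }

    hits <- lapply(seq_along(idx), function(k) {
      new_domain_hit(
        protein_id = paste0(entry_ids[k], "_A"), accession = accession,
        bit_score = 25,
        state_map = stats::setNames(seq_len(ns), seq_len(ns))
      )
    })
    hits_path <- file.path(dir, "hits.tsv")
    write_domain_hits(hits, hits_path)

    # Emissions: consensus amino acid favoured, remainder uniform.
    emissions <- t(vapply(seq_len(ns), function(s) {
      e <- rep(0.3 / 19, 20)
      e[match(consensus[s], AA_ORDER)] <- 0.7
      e
    }, numeric(20)))
    model <- domain_model(accession, ns, gathering_threshold = 20,
      emissions = emissions)
    model_path <- file.path(dir, "model.json")
    write_domain_models(list(model), model_path)

    annotation_path <- file.path(dir, "annotation.tsv")
    utils::write.table(do.call(rbind, ann_rows), annotation_path,
      sep = "\t", quote = FALSE, row.names = FALSE)

    list(
      dir = dir, structure_paths = structure_paths, hits_path = hits_path,
      model_path = model_path, annotation_path = annotation_path,
      accession = accession, spec = spec,
      truth = list(
        consensus = consensus, sequences = sequences, distances = dists,
        binding_states = spec$binding_states, instance_of = idx,
        entry_ids = entry_ids
      )
    )
  })
}

#' Generate a synthetic proteome with binding sites and sites of interest
#'
#' Emits a FASTA of random protein sequences, a per-protein binding-site TSV,
#' and a site-of-interest list. Each protein's binding residues are a random
#' subset (its binding fraction drawn uniformly in
#' `[0.5, 1.5] x binding_fraction` so success probabilities vary across
#' proteins). Interest sites are drawn independently (protein chosen
#' proportional to length, then a residue with weight `enrichment` inside
#' binding sites and 1 outside), so `enrichment = 1` is exactly the
#' Poisson-binomial null.
#'
#' @param dir output directory.
#' @param n_proteins number of proteins.
#' @param length_range integer range of protein lengths.
#' @param binding_fraction mean fraction of residues that are binding sites.
#' @param n_interest_sites number of sites of interest to draw.
#' @param enrichment relative weight of binding positions when drawing
#'   interest sites (>= 0; 1 = null, 0 = never binding).
#' @param seed RNG seed.
#' @return list with `fasta`, `binding_path`, `sites_path` plus in-memory
#'   `lengths`, `binding_sites` and `sites`.
#' @export
make_toy_proteome <- function(dir, n_proteins = 12, length_range = c(80, 160),
                              binding_fraction = 0.3, n_interest_sites = 200,
                              enrichment = 1, seed = 1) {
  if (enrichment < 0) stop("enrichment must be >= 0")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n_proteins))
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    names(lens) <- ids
    frac <- stats::runif(n_proteins, 0.5 * binding_fraction, 1.5 * binding_fraction)
    frac <- pmin(frac, 0.95)
    binding_sites <- lapply(seq_len(n_proteins), function(i) {
      k <- max(1L, round(frac[i] * lens[i]))
      sort(sample.int(lens[i], k))
    })
    names(binding_sites) <- ids

    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ORDER, L, replace = TRUE), collapse = "")
    }, character(1))
    fasta <- file.path(dir, "proteome.fasta")
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), fasta)

    prot_idx <- sample.int(n_proteins, n_interest_sites, replace = TRUE,
      prob = lens / sum(lens))
    sites <- data.frame(
      protein_id = ids[prot_idx],
      residue_index = vapply(prot_idx, function(i) {
        w <- rep(1, lens[i])
        w[binding_sites[[i]]] <- enrichment
        if (sum(w) == 0) {
          sample(setdiff(seq_len(lens[i]), binding_sites[[i]]), 1)
        } else {
          sample.int(lens[i], 1, prob = w)
        }
      }, integer(1)),
      stringsAsFactors = FALSE
    )

    binding_path <- file.path(dir, "binding_sites.tsv")
    utils::write.table(
      data.frame(
        protein_id = rep(ids, lengths(binding_sites)),
        residue_index = unlist(binding_sites, use.names = FALSE)
      ),
      binding_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    sites_path <- file.path(dir, "sites.tsv")
    utils::write.table(sites, sites_path, sep = "\t", quote = FALSE,
      row.names = FALSE)

    list(
      fasta = fasta, binding_path = binding_path, sites_path = sites_path,
      lengths = lens, binding_sites = binding_sites, sites = sites
    )
  })
}
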