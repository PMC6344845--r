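# Evaluation: interface consistency (two-fold PCC), sequence-identity
# clustering, up-to-10-fold cross-validation with precision-recall curves,
# and confident-threshold determination at a minimum precision.

#' Interface-consistency score (mean two-fold PCC)
#'
#' Repeatedly splits the instances at random into two near-equal folds,
#' averages the per-state minimum residue-to-ligand distances within each
#' fold, and computes the Pearson correlation between the two per-state mean
#' vectors over states observed in both folds. Returns the mean PCC over
#' repetitions.
#'
#' @param instances list of `domain_instance`s (>= 3 recommended) or a
#'   `distance_profile`.
#' @param reps number of random-split repetitions (default 10).
#' @param seed RNG seed.
#' @return mean PCC, with attribute `per_rep` (per-repetition values, NA
#'   where a repetition was skipped for sharing < 2 states).
#' @export
consistency_pcc <- function(instances, reps = 10, seed = 1) {
  profile <- if (inherits(instances, "distance_profile")) {
    instances
  } else {
    build_distance_profile(instances)
  }
  n <- nrow(profile$dist)
  if (n < 2) stop("consistency requires at least 2 instances")
  vals <- with_seed(seed, {
    out <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      perm <- sample.int(n)
      half <- perm[seq_len(floor(n / 2))]
      m1 <- colMeans(profile$dist[half, , drop = FALSE], na.rm = TRUE)
      m2 <- colMeans(profile$dist[setdiff(perm, half), , drop = FALSE], na.rm = TRUE)
      shared <- is.finite(m1) & is.finite(m2)
      if (sum(shared) < 2) {
        warning("consistency repetition ", r, " skipped: < 2 shared states")
        next
      }
      out[r] <- stats::cor(m1[shared], m2[shared])
    }
    out
  })
  if (all(is.na(vals))) stop("consistency undefined: all repetitions skipped")
  structure(mean(vals, na.rm = TRUE), per_rep = vals)
}

#' Pairwise sequence identity between two domain instances
#'
#' Fraction of match-state columns where both instances carry a residue and
#' the residues are equal; 0 when no columns are shared.
#'
#' @param a,b `domain_instance`s with the same accession.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (a$accession != b$accession) {
    stop("accession mismatch: ", a$accession, " vs ", b$accession)
  }
  n <- min(length(a$seq), length(b$seq))
  sa <- a$seq[seq_len(n)]
  sb <- b$seq[seq_len(n)]
  shared <- !is.na(sa) & !is.na(sb)
  if (!any(shared)) return(0)
  mean(sa[shared] == sb[shared])
}

#' Group instances by single-linkage sequence identity
#'
#' Connected components of the graph linking instances with pairwise
#' identity at or above `threshold`; identities between different groups are
#' all below `threshold`.
#'
#' @param instances list of `domain_instance`s.
#' @param threshold identity threshold (default 0.90).
#' @return integer vector of group memberships (1-based), named by instance
#'   id.
#' @export
cluster_by_identity <- function(instances, threshold = 0.90) {
  n <- length(instances)
  stopifnot(n >= 1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (pairwise_identity(instances[[i]], instances[[j]]) >= threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)),
    vapply(instances, `[[`, character(1), "id"))
}

#' Number of sequence-distinct instance groups
#'
#' Convenience wrapper counting identity groups at a threshold; with the
#' default threshold 1 this counts exactly-distinct aligned sequences
#' (the non-redundancy criterion for the representable-NR set).
#'
#' @param instances list of `domain_instance`s.
#' @param threshold identity threshold (default 1, i.e. exact duplicates).
#' @return integer group count.
#' @export
n_distinct_sequences <- function(instances, threshold = 1) {
  max(cluster_by_identity(instances, threshold = threshold))
}

#' Randomly assign units to up to k near-equal folds
#'
#' @param units character vector of unit ids (instances or identity groups).
#' @param k_max maximum number of folds (default 10); the realized `k` is
#'   `min(k_max, length(units))`.
#' @param seed RNG seed.
#' @param mode `"instance"` or `"identity90"` (metadata only).
#' @return object of class `fold_assignment` with `unit_ids`, `fold_of`
#'   (named integer vector) and `k`.
#' @export
assign_folds <- function(units, k_max = 10, seed = 1, mode = "instance") {
  n <- length(units)
  if (n < 2) stop("fold assignment requires at least 2 units")
  k <- min(k_max, n)
  fold_of <- with_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = n)[order(sample.int(n))], units)
  })
  structure(
    list(unit_ids = units, fold_of = fold_of, k = k, mode = mode),
    class = "fold_assignment"
  )
}

#' Precision-recall curve with average-precision AUPRC
#'
#' Thresholds are the distinct scores in descending order; all pairs tied at
#' a score cross each threshold together. AUPRC is the average precision
#' (step integration): `sum over thresholds of delta-TP x precision / P`.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) true labels.
#' @return object of class `pr_curve` with `threshold`, `precision`,
#'   `recall`, `auprc` and `baseline`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  P <- sum(labels)
  if (P == 0) stop("pr_curve undefined: no positive labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cum_pred <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp[i] <- sum(pred & labels)
    cum_pred[i] <- sum(pred)
  }
  precision <- tp / cum_pred
  recall <- tp / P
  auprc <- sum(diff(c(0, tp)) * precision) / P
  structure(
    list(
      threshold = thr, precision = precision, recall = recall,
      auprc = auprc, baseline = P / length(labels)
    ),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUPRC %.4f (baseline %.4f)\n",
    length(x$threshold), x$auprc, x$baseline))
  invisible(x)
}

#' Cross-validated evaluation of binding frequencies
#'
#' Splits instances (or identity groups) into up to `k_max` folds. For each
#' held-out fold, binding frequencies are fit on the remaining folds and used
#' as scores for every mapped state of every held-out instance; the state's
#' binary label is its annotated binding status (or, when annotations are
#' absent, contact within `label_cutoff`). States absent from the training
#' folds score 0.
#'
#' AUPRC is the mean of per-fold average precisions (folds without a positive
#' pair are skipped); a pooled curve over all held-out pairs is also
#' returned and is the basis for threshold selection.
#'
#' @param instances list of `domain_instance`s.
#' @param folds optional `fold_assignment` over instance ids; by default one
#'   is drawn with [assign_folds()].
#' @param k_max maximum folds (default 10).
#' @param seed RNG seed for the default fold assignment.
#' @param mode `"instance"` (each instance its own unit) or `"identity90"`
#'   (identity groups at `identity_threshold` never straddle folds).
#' @param identity_threshold clustering threshold for `mode = "identity90"`.
#' @param cutoff distance cutoff used when fitting training frequencies.
#' @param label_cutoff contact cutoff for fallback labels when instances
#'   carry no binding annotation.
#' @param pool `"folds"` (AUPRC = mean per-fold AP, the default) or
#'   `"overall"` (AUPRC of the pooled curve).
#' @return object of class `cv_result` with `auprc`, `auprc_folds`,
#'   `baseline`, `fold_improvement`, the pooled `curve`, and the pooled
#'   `scores`/`labels`.
#' @export
cross_validate <- function(instances, folds = NULL, k_max = 10, seed = 1,
                           mode = c("instance", "identity90"),
                           identity_threshold = 0.90,
                           cutoff = 3.6, label_cutoff = 3.6,
                           pool = c("folds", "overall")) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  n <- length(instances)
  stopifnot(n >= 2)
  ids <- vapply(instances, `[[`, character(1), "id")
  if (is.null(folds)) {
    if (mode == "identity90") {
      grp <- cluster_by_identity(instances, threshold = identity_threshold)
      gids <- unique(unname(grp))
      if (length(gids) < 2) stop("identity90 mode: fewer than 2 groups")
      ga <- assign_folds(as.character(gids), k_max = k_max, seed = seed,
        mode = "identity90")
      fold_of <- stats::setNames(ga$fold_of[as.character(unname(grp))], ids)
      folds <- structure(
        list(unit_ids = ids, fold_of = fold_of, k = ga$k, mode = "identity90"),
        class = "fold_assignment"
      )
    } else {
      folds <- assign_folds(ids, k_max = k_max, seed = seed)
    }
  }
  fold_of <- folds$fold_of[ids]
  if (any(is.na(fold_of))) stop("fold assignment does not cover all instances")

  scores_all <- numeric(0)
  labels_all <- logical(0)
  ap_folds <- rep(NA_real_, folds$k)
  for (f in seq_len(folds$k)) {
    hold <- which(fold_of == f)
    train <- which(fold_of != f)
    if (length(hold) == 0) next
    if (length(train) == 0) stop("fold ", f, " has an empty training complement")
    train_prof <- build_distance_profile(instances[train])
    freq <- binding_frequency(train_prof,
      weights = unname(henikoff_weights(train_prof)), cutoff = cutoff)
    sc <- numeric(0)
    lb <- logical(0)
    for (i in hold) {
      inst <- instances[[i]]
      mapped <- which(!is.na(inst$dist))
      for (s in mapped) {
        s_score <- if (s <= length(freq) && !is.na(freq[s])) freq[s] else 0
        s_label <- if (!is.na(inst$binding[s])) {
          inst$binding[s]
        } else {
          inst$dist[s] <= label_cutoff
        }
        sc <- c(sc, s_score)
        lb <- c(lb, s_label)
      }
    }
    scores_all <- c(scores_all, sc)
    labels_all <- c(labels_all, lb)
    if (sum(lb) > 0) ap_folds[f] <- pr_curve(sc, lb)$auprc
  }
  if (length(scores_all) == 0) stop("cross-validation produced no held-out pairs")
  curve <- pr_curve(scores_all, labels_all)
  auprc <- if (pool == "overall") curve$auprc else mean(ap_folds, na.rm = TRUE)
  baseline <- mean(labels_all)
  structure(
    list(
      accession = instances[[1]]$accession,
      ligand_class = instances[[1]]$ligand_class,
      k = folds$k, mode = folds$mode, pool = pool,
      auprc = auprc, auprc_folds = ap_folds,
      baseline = baseline, fold_improvement = auprc / baseline,
      curve = curve, scores = scores_all, labels = labels_all
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s / %s: %d folds (%s), AUPRC %.4f, baseline %.4f (%.1fx)\n",
    x$accession, x$ligand_class, x$k, x$mode, x$auprc, x$baseline,
    x$fold_improvement
  ))
  invisible(x)
}

#' Choose the binding-frequency threshold meeting a precision requirement
#'
#' Among curve thresholds with precision at least `min_precision`, selects
#' the one maximizing recall; ties are broken toward higher precision (and
#' then toward the smaller threshold). Returns `NULL` when no threshold
#' qualifies.
#'
#' @param curve a `pr_curve` (e.g. the pooled curve of a `cv_result`).
#' @param min_precision minimum pooled precision (default 0.5).
#' @param accession,ligand_class optional metadata carried into the result.
#' @return object of class `confident_interaction` with `threshold`,
#'   `achieved_precision` and `recall`, or `NULL`.
#' @export
confident_threshold <- function(curve, min_precision = 0.5,
                                accession = NA_character_,
                                ligand_class = NA_character_) {
  if (inherits(curve, "cv_result")) {
    if (is.na(accession)) accession <- curve$accession
    if (is.na(ligand_class)) ligand_class <- curve$ligand_class
    curve <- curve$curve
  }
  ok <- which(curve$precision >= min_precision)
  if (length(ok) == 0) return(NULL)
  best <- ok[order(-curve$recall[ok], -curve$precision[ok], curve$threshold[ok])][1]
  structure(
    list(
      accession = accession, ligand_class = ligand_class,
      threshold = curve$threshold[best],
      achieved_precision = curve$precision[best],
      recall = curve$recall[best]
    ),
    class = "confident_interaction"
  )
}

#' @export
print.confident_interaction <- function(x, ...) {
  cat(sprintf(
    "<confident_interaction> %s / %s: threshold %.4f (precision %.3f, recall %.3f)\n",
    x$accession, x$ligand_class, x$threshold, x$achieved_precision, x$recall
  ))
  invisible(x)
}

#' One-stop evaluation of a domain-ligand instance set
#'
#' Computes the consistency PCC, a cross-validated PR evaluation and the
#' confident threshold, and reports them as a one-row data.frame in the
#' evaluation-report shape.
#'
#' @param instances list of `domain_instance`s.
#' @param min_nr_instances minimum number of sequence-distinct instances for
#'   the pair to be evaluated (default 3; the representable-NR criterion).
#' @param min_precision confident-set precision requirement (default 0.5).
#' @param consistency_reps repetitions for the consistency PCC (default 10).
#' @param ... passed to [cross_validate()].
#' @param seed RNG seed.
#' @return one-row data.frame; `NULL` (with a message) when the pair is not
#'   representable-NR.
#' @export
evaluate_family <- function(instances, min_nr_instances = 3,
                            min_precision = 0.5, consistency_reps = 10,
                            seed = 1, ...) {
  n_nr <- n_distinct_sequences(instances)
  if (n_nr < min_nr_instances) {
    message("pair has ", n_nr, " distinct sequences (< ", min_nr_instances,
      "); not representable-NR")
    return(NULL)
  }
  pcc <- consistency_pcc(instances, reps = consistency_reps,
    seed = sub_seed(seed, 1))
  cv <- cross_validate(instances, seed = sub_seed(seed, 2), ...)
  conf <- confident_threshold(cv, min_precision = min_precision)
  data.frame(
    domain = instances[[1]]$accession,
    ligand_class = instances[[1]]$ligand_class,
    n_instances = length(instances),
    n_distinct = n_nr,
    mean_consistency_pcc = as.numeric(pcc),
    auprc = cv$auprc,
    baseline_auprc = cv$baseline,
    fold_improvement = cv$fold_improvement,
    confident_threshold = if (is.null(conf)) NA_real_ else conf$threshold,
    achieved_precision = if (is.null(conf)) NA_real_ else conf$achieved_precision,
    stringsAsFactors = FALSE
  )
}
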