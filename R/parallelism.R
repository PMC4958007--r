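# Map each well's key set to the chosen identity level and apply feature
# exclusions. Returns list(sets = keys per well, clusters = cluster id per
# key) where clusters == keys at the nucleotide level.
level_sets <- function(dataset, level = c("nucleotide", "cluster"),
                       include_reversions = TRUE,
                       exclude_features = character()) {
  level <- match.arg(level)
  sets <- well_mutation_sets(dataset, include_reversions)
  all_keys <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(exclude_features) > 0 || level == "cluster") {
    if (is.null(dataset$annotation))
      stop("annotation required for cluster-level analysis or feature exclusion")
  }
  if (length(exclude_features) > 0 && length(all_keys) > 0) {
    cat <- annotate_catalog(all_keys, dataset$annotation)
    drop <- vapply(strsplit(cat$features, ","), function(f)
      any(f %in% exclude_features), TRUE)
    dropped <- cat$key[drop]
    sets <- lapply(sets, setdiff, y = dropped)
    all_keys <- setdiff(all_keys, dropped)
  }
  clusters <- if (level == "cluster" && length(all_keys) > 0)
    cluster_keys(all_keys, dataset$annotation)
  else stats::setNames(all_keys, all_keys)
  list(sets = sets, clusters = clusters)
}

# P_ij for two key sets under a cluster map: the mean of the two directed
# proportions of mutations with an identity-level match in the other well.
pair_parallelism <- function(si, sj, clusters) {
  if (length(si) == 0 || length(sj) == 0) return(NA_real_)
  ci <- clusters[si]; cj <- clusters[sj]
  (mean(ci %in% cj) + mean(cj %in% ci)) / 2
}

#' Pairwise parallelism between wells
#'
#' Parallelism between wells i and j is the average of two reciprocal
#' comparisons: the proportion of i's mutations found in j and the proportion
#' of j's found in i. At the nucleotide level a mutation is "found in" the
#' other well when the identical key occurs there; at the cluster
#' (regulatory/codon) level, when any mutation of the same cluster (see
#' [cluster_keys()]) occurs there. The cluster level can therefore never show
#' less parallelism than the nucleotide level for any pair. Wells whose
#' mutation set is empty after exclusions yield `NA` (missing, not zero).
#'
#' @param dataset A [mut_dataset()] (QC applied; at least two wells).
#' @param level `"nucleotide"` or `"cluster"`.
#' @param include_reversions Keep each well's own reversion key (default TRUE)?
#' @param exclude_features Feature ids whose mutations are removed before the
#'   comparison (e.g. `"D-promoter"`).
#' @return Object of class `pairwise_parallelism`: `values` (symmetric matrix
#'   with unit diagonal for nonempty wells), `wells` (well/background table),
#'   plus the flags used.
#' @export
pairwise_parallelism <- function(dataset, level = c("nucleotide", "cluster"),
                                 include_reversions = TRUE,
                                 exclude_features = character()) {
  stopifnot(inherits(dataset, "mut_dataset"))
  level <- match.arg(level)
  if (nrow(dataset$wells) < 2) stop("need at least two wells")
  ls <- level_sets(dataset, level, include_reversions, exclude_features)
  if (all(lengths(ls$sets) == 0)) stop("all wells empty after exclusions")
  wells <- dataset$wells$well_id
  n <- length(wells)
  P <- matrix(NA_real_, n, n, dimnames = list(wells, wells))
  for (i in seq_len(n)) {
    P[i, i] <- if (length(ls$sets[[i]]) > 0) 1 else NA_real_
    if (i < n) for (j in (i + 1):n) {
      v <- pair_parallelism(ls$sets[[i]], ls$sets[[j]], ls$clusters)
      P[i, j] <- v
      P[j, i] <- v
    }
  }
  structure(
    list(values = P,
         wells = dataset$wells[, c("well_id", "background_id")],
         level = level, include_reversions = include_reversions,
         exclude_features = exclude_features),
    class = "pairwise_parallelism")
}

#' @export
print.pairwise_parallelism <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("Pairwise parallelism (", x$level, " level): ", nrow(x$values),
      " wells; mean off-diagonal P_ij = ",
      round(mean(off, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

# Long table of unordered well pairs with their P values and a within-
# background indicator under the given label assignment.
pair_table <- function(P, labels = NULL) {
  wells <- P$wells$well_id
  labels <- labels %||% stats::setNames(P$wells$background_id, wells)
  idx <- which(upper.tri(P$values), arr.ind = TRUE)
  data.frame(
    i = wells[idx[, 1]], j = wells[idx[, 2]],
    value = P$values[idx],
    bg_i = unname(labels[wells[idx[, 1]]]),
    bg_j = unname(labels[wells[idx[, 2]]]),
    within = unname(labels[wells[idx[, 1]]] == labels[wells[idx[, 2]]]),
    stringsAsFactors = FALSE)
}

#' Within-background parallelism summary
#'
#' Averages P_ij over pairs of wells founded from the same background. The
#' grand mean is the unweighted mean of the per-background means (not the
#' pooled pair mean), because backgrounds contribute unequal pair counts after
#' well removal; its SE is taken over the background means.
#'
#' @param P A [pairwise_parallelism()] result.
#' @return List with `per_background` (`data.frame`: background, wells, pairs,
#'   mean), `grand_mean` and `se`.
#' @export
within_background_summary <- function(P) {
  stopifnot(inherits(P, "pairwise_parallelism"))
  tab <- pair_table(P)
  tab <- tab[tab$within & !is.na(tab$value), , drop = FALSE]
  bgs <- sort(unique(P$wells$background_id))
  per <- lapply(bgs, function(b) {
    nw <- sum(P$wells$background_id == b)
    v <- tab$value[tab$bg_i == b]
    if (nw < 2)
      warning("background ", b, " has fewer than 2 wells; no pairs")
    data.frame(background_id = b, n_wells = nw, n_pairs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  means <- per$mean[!is.na(per$mean)]
  list(per_background = per,
       grand_mean = mean(means),
       se = stats::sd(means) / sqrt(length(means)))
}

# R statistic: share of the sum of squares of within-background P values
# attributable to background, for an arbitrary label assignment.
r_statistic <- function(tab) {
  v <- tab$value[tab$within & !is.na(tab$value)]
  g <- tab$bg_i[tab$within & !is.na(tab$value)]
  if (length(v) < 2) return(NA_real_)
  sst <- sum((v - mean(v))^2)
  if (sst == 0) return(0)
  gm <- tapply(v, g, mean)
  gn <- tapply(v, g, length)
  ssb <- sum(gn * (gm - mean(v))^2)
  ssb / sst
}

#' Randomization test for a background effect on parallelism
#'
#' Partitions the sum of squares of within-background P_ij values into
#' between- and within-background components; `R_real` is the between share.
#' Because each well enters many pairs the P_ij values are non-independent,
#' so the null distribution of R is generated by permuting the well-to-
#' background labels (preserving group sizes) and recomputing R from the same
#' P matrix. The p-value uses the add-one estimator.
#'
#' @param dataset A [mut_dataset()].
#' @param level `"nucleotide"` or `"cluster"`.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional RNG seed for the permutations.
#' @param include_reversions Keep reversions (default FALSE, matching the
#'   reversion-excluded analysis)?
#' @param exclude_features Feature ids to drop before computing P.
#' @return Object of class `background_effect`: `R_real`, `null` (numeric
#'   vector), `p_value`, `n_perm`, `level`.
#' @export
background_effect_test <- function(dataset, level = c("nucleotide", "cluster"),
                                   n_perm = 9999, seed = NULL,
                                   include_reversions = FALSE,
                                   exclude_features = character()) {
  stopifnot(inherits(dataset, "mut_dataset"))
  level <- match.arg(level)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  bg_sizes <- table(dataset$wells$background_id)
  if (sum(bg_sizes >= 2) < 2)
    stop("need at least two backgrounds with at least two wells")
  P <- pairwise_parallelism(dataset, level, include_reversions,
                            exclude_features)
  labels0 <- P$wells$background_id
  idx <- which(upper.tri(P$values), arr.ind = TRUE)
  v <- P$values[idx]
  keep <- !is.na(v)
  wi <- idx[keep, 1]; wj <- idx[keep, 2]; v <- v[keep]
  r_for <- function(lab) {
    within <- lab[wi] == lab[wj]
    r_statistic(data.frame(value = v[within], bg_i = lab[wi][within],
                           within = TRUE, stringsAsFactors = FALSE))
  }
  R_real <- r_for(labels0)
  run <- function() vapply(seq_len(n_perm),
                           function(i) r_for(sample(labels0)), 0)
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(R_real = R_real, null = null,
         p_value = perm_pvalue(null, R_real, "greater"),
         n_perm = n_perm, level = level),
    class = "background_effect")
}

#' @export
print.background_effect <- function(x, ...) {
  cat("Background effect on parallelism (", x$level, " level): R_real = ",
      round(x$R_real, 4), ", p = ", signif(x$p_value, 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Occurrence spectrum of mutations across wells
#'
#' Counts, for every mutation (or grouped mutational feature), the number of
#' retained wells it occurs in, its well frequency, and its squared frequency
#' (the probability that two wells selected at random both carry it). The
#' unweighted mean squared frequency summarizes how likely a randomly chosen
#' mutation is to co-occur in a random pair of wells.
#'
#' @param dataset A [mut_dataset()] (QC applied).
#' @param include_reversions Count reversions (default FALSE)?
#' @param group_features Feature ids to collapse into a single mutational
#'   feature (e.g. `"D-promoter"`: one row counting wells with any mutation
#'   in that feature, replacing its member rows).
#' @return Object of class `occurrence_spectrum`: `spectrum` (`data.frame`
#'   with `id`, `n_wells_present`, `frequency`, `freq_squared`), `n_wells`,
#'   `mean_freq_squared`.
#' @export
occurrence_spectrum <- function(dataset, include_reversions = FALSE,
                                group_features = character()) {
  stopifnot(inherits(dataset, "mut_dataset"))
  sets <- well_mutation_sets(dataset, include_reversions)
  n_wells <- length(sets)
  keys <- sort(unique(unlist(sets, use.names = FALSE)))
  member_of <- stats::setNames(rep(NA_character_, length(keys)), keys)
  if (length(group_features) > 0) {
    if (is.null(dataset$annotation))
      stop("annotation required to group mutations by feature")
    cat <- annotate_catalog(keys, dataset$annotation)
    feats <- strsplit(cat$features, ",")
    for (gf in group_features) {
      hit <- vapply(feats, function(f) gf %in% f, TRUE)
      member_of[cat$key[hit]] <- gf
    }
  }
  ids <- ifelse(is.na(member_of), keys, member_of)
  counts <- vapply(split(keys, ids), function(members)
    sum(vapply(sets, function(s) any(members %in% s), TRUE)), 0L)
  spectrum <- data.frame(
    id = names(counts), n_wells_present = as.integer(counts),
    frequency = as.numeric(counts) / n_wells,
    freq_squared = (as.numeric(counts) / n_wells)^2,
    stringsAsFactors = FALSE)
  spectrum <- spectrum[order(-spectrum$n_wells_present, spectrum$id), ]
  rownames(spectrum) <- NULL
  structure(
    list(spectrum = spectrum, n_wells = n_wells,
         mean_freq_squared = mean(spectrum$freq_squared)),
    class = "occurrence_spectrum")
}

#' @export
print.occurrence_spectrum <- function(x, ...) {
  cat("Occurrence spectrum over", x$n_wells, "wells:",
      nrow(x$spectrum), "mutational identities; mean squared frequency",
      signif(x$mean_freq_squared, 3), "\n")
  invisible(x)
}
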