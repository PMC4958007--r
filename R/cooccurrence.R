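# Isolate-level presence matrix (isolates x mutations) restricted to given
# keys, plus the well of each isolate row.
isolate_matrix <- function(dataset, keys) {
  iso <- dataset$isolates$isolate_id
  M <- matrix(FALSE, length(iso), length(keys),
              dimnames = list(iso, keys))
  for (id in iso) M[id, intersect(dataset$genotypes[[id]], keys)] <- TRUE
  list(M = M, well = dataset$isolates$well_id)
}

# Number of wells in which each pair of columns (and block combinations)
# shares at least one isolate. `blocks` is a named list of column-index
# vectors. Returns a list: `pairs` (symmetric K x K matrix), `block_vs`
# (blocks x K matrix of any-member co-occurrence) and `block_self` (named
# vector: wells with two distinct members in one isolate).
cooccur_counts <- function(M, well, blocks = list()) {
  K <- ncol(M)
  pairs <- matrix(0L, K, K, dimnames = list(colnames(M), colnames(M)))
  block_vs <- matrix(0L, length(blocks), K,
                     dimnames = list(names(blocks), colnames(M)))
  block_self <- stats::setNames(integer(length(blocks)), names(blocks))
  for (w in unique(well)) {
    Mw <- M[well == w, , drop = FALSE]
    cross <- crossprod(Mw)
    pairs <- pairs + (cross > 0)
    for (bi in seq_along(blocks)) {
      cols <- blocks[[bi]]
      in_block <- rowSums(Mw[, cols, drop = FALSE])
      block_vs[bi, ] <- block_vs[bi, ] +
        (colSums(Mw & (in_block > 0)) > 0)
      if (any(in_block >= 2)) block_self[bi] <- block_self[bi] + 1L
    }
  }
  diag(pairs) <- 0L
  list(pairs = pairs, block_vs = block_vs, block_self = block_self)
}

# One null replicate: independently rewire each mutation's placement,
# preserving its well count and its per-well isolate counts (two-stage
# scheme), or only its total isolate count (simple isolate shuffle).
randomize_matrix <- function(M, well, two_stage = TRUE) {
  out <- M
  wells <- unique(well)
  well_rows <- split(seq_along(well), well)[wells]
  well_sizes <- lengths(well_rows)
  for (k in seq_len(ncol(M))) {
    if (!two_stage) {
      out[, k] <- sample(M[, k])
      next
    }
    occ <- tapply(M[, k], well, sum)[wells]
    occupied <- occ > 0
    counts <- as.integer(occ[occupied])
    nw <- length(counts)
    if (nw == 0) next
    col <- logical(nrow(M))
    # place the occupancy pattern on a random well set; assigning larger
    # counts to larger wells guarantees feasibility under unequal well sizes
    target <- sample(seq_along(wells), nw)
    counts <- sample(counts)
    if (any(counts > well_sizes[target])) {
      ord_t <- target[order(-well_sizes[target])]
      ord_c <- sort(counts, decreasing = TRUE)
      target <- ord_t; counts <- ord_c
      if (any(counts > well_sizes[target]))
        stop("occupancy pattern cannot be placed: a well is too small")
    }
    for (j in seq_len(nw)) {
      rows <- well_rows[[target[j]]]
      col[rows[sample.int(length(rows), counts[j])]] <- TRUE
    }
    out[, k] <- col
  }
  out
}

#' Pairwise co-occurrence randomization test
#'
#' Asks whether pairs of de novo mutations appear together in the same
#' isolate more or less often than chance expects (synergy vs repulsion).
#' Reversions and singletons (mutations seen in fewer than two wells) are
#' removed first. For each remaining pair, the observed statistic is the
#' number of wells in which the pair co-occurs in at least one isolate. The
#' null rewires each mutation's placement independently across the dataset,
#' preserving both its well count and its per-well isolate counts (a simpler
#' isolate-level shuffle is available via `two_stage = FALSE`). Expected
#' counts are null means; p-values are two-tailed
#' (`2 * min(P(X >= obs), P(X <= obs))`, add-one, capped at 1). Pairs with
#' `p < 0.05` that co-occur exactly once are dropped as the most obvious
#' false positives. No multiple-testing correction is applied to `p`, but a
#' Benjamini-Hochberg column `p_bh` is emitted as a labeled extension.
#'
#' Blocks aggregate a set of mutations into one mutational feature: a block
#' row against a single mutation counts wells where that mutation shares an
#' isolate with any block member, and the block-against-itself row counts
#' wells where one isolate carries two distinct members.
#'
#' @param dataset A [mut_dataset()] (QC applied).
#' @param n_rand Number of null randomizations (default 1000).
#' @param seed Optional RNG seed.
#' @param blocks Named list of mutation-key sets (e.g.
#'   `list("D-pro" = feature_mutations(dataset, "D-promoter"))`).
#' @param two_stage Use the marginal-preserving two-stage rewiring (default
#'   TRUE)?
#' @return Object of class `cooccurrence_table` with components `table`
#'   (`data.frame`: `a`, `b`, `observed`, `expected`, `p`, `p_bh`), `blocks`
#'   (same columns, block rows including the block-vs-itself row), `n_rand`,
#'   `n_dropped` (pairs removed by the false-positive filter) and `keys`
#'   (the non-singleton, non-reversion keys tested).
#' @export
cooccurrence_test <- function(dataset, n_rand = 1000, seed = NULL,
                              blocks = list(), two_stage = TRUE) {
  stopifnot(inherits(dataset, "mut_dataset"))
  if (n_rand < 100) warning("n_rand < 100 gives a very coarse p-value")
  counts <- count_mutations_and_events(dataset)$per_mutation_well_counts
  keys <- setdiff(names(counts)[counts >= 2], all_reversion_keys(dataset))
  keys <- sort(keys)
  if (length(keys) < 2)
    stop("need at least two non-singleton, non-reversion mutations")
  blocks <- lapply(blocks, intersect, y = keys)
  blocks <- blocks[lengths(blocks) >= 2]
  im <- isolate_matrix(dataset, keys)
  block_cols <- lapply(blocks, match, table = keys)

  obs <- cooccur_counts(im$M, im$well, block_cols)
  acc <- list(sum = obs$pairs * 0, ge = obs$pairs * 0L, le = obs$pairs * 0L,
              bv_sum = obs$block_vs * 0, bv_ge = obs$block_vs * 0L,
              bv_le = obs$block_vs * 0L,
              bs_sum = obs$block_self * 0, bs_ge = obs$block_self * 0L,
              bs_le = obs$block_self * 0L)
  run <- function() {
    for (r in seq_len(n_rand)) {
      Mr <- randomize_matrix(im$M, im$well, two_stage)
      cc <- cooccur_counts(Mr, im$well, block_cols)
      acc$sum <<- acc$sum + cc$pairs
      acc$ge <<- acc$ge + (cc$pairs >= obs$pairs)
      acc$le <<- acc$le + (cc$pairs <= obs$pairs)
      acc$bv_sum <<- acc$bv_sum + cc$block_vs
      acc$bv_ge <<- acc$bv_ge + (cc$block_vs >= obs$block_vs)
      acc$bv_le <<- acc$bv_le + (cc$block_vs <= obs$block_vs)
      acc$bs_sum <<- acc$bs_sum + cc$block_self
      acc$bs_ge <<- acc$bs_ge + (cc$block_self >= obs$block_self)
      acc$bs_le <<- acc$bs_le + (cc$block_self <= obs$block_self)
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())

  two_tailed <- function(ge, le) pmin(1, 2 * pmin((1 + ge) / (n_rand + 1),
                                                  (1 + le) / (n_rand + 1)))
  ut <- which(upper.tri(obs$pairs), arr.ind = TRUE)
  tab <- data.frame(
    a = keys[ut[, 1]], b = keys[ut[, 2]],
    observed = obs$pairs[ut], expected = acc$sum[ut] / n_rand,
    p = two_tailed(acc$ge[ut], acc$le[ut]),
    stringsAsFactors = FALSE)
  dropped <- tab$p < 0.05 & tab$observed == 1
  n_dropped <- sum(dropped)
  tab <- tab[!dropped, , drop = FALSE]
  tab$p_bh <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$a, tab$b), ]
  rownames(tab) <- NULL

  btab <- NULL
  if (length(blocks) > 0) {
    rows <- list()
    for (bi in seq_along(blocks)) {
      bn <- names(blocks)[bi]
      others <- setdiff(keys, blocks[[bi]])
      oi <- match(others, keys)
      rows[[length(rows) + 1]] <- data.frame(
        a = bn, b = others,
        observed = obs$block_vs[bi, oi],
        expected = acc$bv_sum[bi, oi] / n_rand,
        p = two_tailed(acc$bv_ge[bi, oi], acc$bv_le[bi, oi]),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        a = bn, b = bn,
        observed = obs$block_self[bi],
        expected = acc$bs_sum[bi] / n_rand,
        p = two_tailed(acc$bs_ge[bi], acc$bs_le[bi]),
        stringsAsFactors = FALSE)
    }
    btab <- do.call(rbind, rows)
    btab$p_bh <- stats::p.adjust(btab$p, method = "BH")
    rownames(btab) <- NULL
  }
  structure(
    list(table = tab, blocks = btab, n_rand = n_rand,
         n_dropped = n_dropped, keys = keys, two_stage = two_stage),
    class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("Co-occurrence test:", length(x$keys), "mutations,",
      nrow(x$table), "pairs (", x$n_dropped, "dropped );",
      sum(x$table$p < 0.05), "pairs with p < 0.05\n")
  invisible(x)
}

#' Mutation keys falling in an annotated feature
#'
#' Convenience for defining co-occurrence blocks such as all D-promoter
#' mutations.
#'
#' @param dataset A [mut_dataset()] with annotation.
#' @param feature_id Feature id from the annotation.
#' @return Character vector of catalog keys overlapping the feature.
#' @export
feature_mutations <- function(dataset, feature_id) {
  stopifnot(inherits(dataset, "mut_dataset"))
  if (is.null(dataset$annotation)) stop("dataset has no annotation")
  if (length(dataset$catalog) == 0) return(character(0))
  cat <- annotate_catalog(dataset$catalog, dataset$annotation)
  hit <- vapply(strsplit(cat$features, ","), function(f)
    feature_id %in% f, TRUE)
  cat$key[hit]
}
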