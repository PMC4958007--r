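# Unique observed genotypes of a well with multiplicities, each genotype a
# sorted character vector of mutation keys.
observed_genotypes <- function(dataset, well_id) {
  iso <- dataset$isolates$isolate_id[dataset$isolates$well_id == well_id]
  if (length(iso) == 0) stop("well has no isolates: ", well_id)
  gts <- dataset$genotypes[iso]
  sig <- vapply(gts, paste, "", collapse = "\r")
  ug <- gts[!duplicated(sig)]
  list(genotypes = unname(ug),
       multiplicity = as.integer(table(sig)[sig[!duplicated(sig)]]),
       n_isolates = length(iso))
}

# Four-gamete style compatibility against a known all-ancestral root: a pair
# of mutations is incompatible when carriers show the patterns (1,0), (0,1)
# and (1,1) simultaneously.
is_compatible <- function(genotypes, mutations) {
  if (length(mutations) < 2) return(TRUE)
  has <- vapply(mutations, function(k)
    vapply(genotypes, function(g) k %in% g, TRUE),
    logical(length(genotypes)))
  has <- matrix(has, nrow = length(genotypes))
  for (a in seq_len(ncol(has) - 1)) for (b in (a + 1):ncol(has)) {
    pa <- has[, a]; pb <- has[, b]
    if (any(pa & !pb) && any(!pa & pb) && any(pa & pb)) return(FALSE)
  }
  TRUE
}

# Greedy prefix-tree construction: insert each genotype's mutation sequence
# (global order: decreasing isolate count, ties lexicographic) into a trie
# rooted at the ancestral genotype. For a compatible matrix this is the
# unique perfect phylogeny.
greedy_trie <- function(genotypes, multiplicity, rank) {
  parent <- 0L
  gained <- NA_character_
  genotype <- list(character(0))
  n_iso <- 0L
  child_index <- list(integer(0))
  find_child <- function(node, k) {
    for (ch in child_index[[node]]) if (gained[ch] == k) return(ch)
    0L
  }
  for (gidx in seq_along(genotypes)) {
    g <- genotypes[[gidx]]
    seq_keys <- g[order(rank[g])]
    node <- 1L
    for (k in seq_keys) {
      ch <- find_child(node, k)
      if (ch == 0L) {
        parent <- c(parent, node)
        gained <- c(gained, k)
        genotype <- c(genotype, list(c(genotype[[node]], k)))
        n_iso <- c(n_iso, 0L)
        child_index <- c(child_index, list(integer(0)))
        ch <- length(parent)
        child_index[[node]] <- c(child_index[[node]], ch)
      }
      node <- ch
    }
    n_iso[node] <- n_iso[node] + multiplicity[gidx]
  }
  list(parent = parent, gained = gained, genotype = genotype, n_iso = n_iso)
}

popcount <- function(x, n_bits) {
  vapply(x, function(v)
    sum(bitwAnd(v, bitwShiftL(1L, 0:(n_bits - 1L))) != 0L), 0L)
}

# Intersection closure of a set of bitmasks; NULL when it grows past `cap`.
intersection_closure <- function(masks, cap = 64L) {
  cl <- unique(masks)
  repeat {
    new <- setdiff(unique(as.vector(outer(cl, cl, bitwAnd))), cl)
    if (length(new) == 0) break
    cl <- c(cl, new)
    if (length(cl) > cap) return(NULL)
  }
  sort(cl)
}

# Exact minimum-length gains-only tree spanning the observed genotypes.
# An optimal tree exists whose internal (Steiner) nodes are intersections of
# observed genotypes: a branching node can always be raised to the
# intersection of the genotypes below it without increasing total gains, and
# pass-through nodes splice out at no cost. The search therefore enumerates
# subsets of the intersection-closure and, for each node set, lets every node
# pick its cheapest strict-subset parent (subset order forbids cycles).
# Returns NULL when the search space is too large.
exact_steiner <- function(term_masks, n_mut, max_extra = 12L) {
  if (n_mut > 30) return(NULL)
  required <- sort(unique(c(0L, term_masks)))
  cl <- intersection_closure(required)
  if (is.null(cl)) return(NULL)
  extra <- setdiff(cl, required)
  if (length(extra) > max_extra) return(NULL)
  all_nodes <- c(required, extra)
  nn <- length(all_nodes)
  D <- matrix(Inf, nn, nn)
  for (ui in seq_len(nn)) for (vi in seq_len(nn)) {
    u <- all_nodes[ui]; v <- all_nodes[vi]
    if (ui != vi && bitwAnd(u, v) == u)
      D[ui, vi] <- popcount(bitwXor(v, u), n_mut)
  }
  n_req <- length(required)
  n_extra <- length(extra)
  best <- NULL
  best_cost <- Inf
  for (E in 0:(2^n_extra - 1)) {
    sel <- c(seq_len(n_req),
             if (n_extra > 0) n_req + which(
               bitwAnd(E, bitwShiftL(1L, seq_len(n_extra) - 1L)) != 0L))
    Dv <- D[sel, sel, drop = FALSE]
    childs <- which(all_nodes[sel] != 0L)
    par_pos <- apply(Dv[, childs, drop = FALSE], 2, which.min)
    cost <- sum(Dv[cbind(par_pos, childs)])
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(masks = all_nodes[sel], childs = childs,
                   parent_mask = all_nodes[sel][par_pos])
    }
  }
  list(cost = best_cost,
       node_masks = best$masks[best$childs],
       parent_masks = best$parent_mask)
}

# Convert an exact Steiner solution (edges possibly gaining several
# mutations) into the node-per-mutation tree representation, expanding
# multi-gain edges into chains ordered by the global mutation rank.
expand_steiner <- function(sol, mutations, rank) {
  decode <- function(mask) mutations[
    bitwAnd(mask, bitwShiftL(1L, seq_along(mutations) - 1L)) != 0L]
  parent <- 0L
  gained <- NA_character_
  genotype <- list(character(0))
  node_of <- c(`0` = 1L)
  # insert nodes in increasing popcount order so parents exist first
  ord <- order(popcount(sol$node_masks, length(mutations)))
  for (i in ord) {
    vmask <- sol$node_masks[i]
    pmask <- sol$parent_masks[i]
    pnode <- node_of[[as.character(pmask)]]
    gains <- setdiff(decode(vmask), decode(pmask))
    gains <- gains[order(rank[gains])]
    node <- pnode
    for (k in gains) {
      parent <- c(parent, node)
      gained <- c(gained, k)
      genotype <- c(genotype, list(c(genotype[[node]], k)))
      node <- length(parent)
    }
    node_of[[as.character(vmask)]] <- node
  }
  list(parent = parent, gained = gained, genotype = genotype,
       node_of = node_of)
}

#' Build the within-well genotype tree
#'
#' Reconstructs the clonal structure of one well from its sampled isolate
#' genotypes, rooted at the well's ancestral genotype (an empty de novo set).
#' When the isolate-by-mutation matrix is compatible (the four-gamete
#' condition holds against the known ancestral state for every pair of
#' mutations), the unique perfect phylogeny is returned: every mutation
#' labels exactly one edge. Otherwise `compatible` is `FALSE` and a
#' minimal-homoplasy tree is returned in which a mutation may label several
#' edges; the homoplasy count is the number of repeated edge labels. The
#' minimal tree is found exactly (a gains-only Steiner search over the
#' intersection-closure of observed genotypes) whenever that search is small
#' (`exact = TRUE`); for larger incompatible problems a greedy
#' frequency-ordered prefix tree is returned with `exact = FALSE`. Unsampled
#' intermediate genotypes appear as unobserved internal nodes.
#'
#' @param dataset A [mut_dataset()].
#' @param well_id A single well id.
#' @return Object of class `genotype_tree`: `nodes` (`data.frame` with
#'   `id`, `parent` (0 for the root), `gained` (mutation on the incoming
#'   edge), `n_isolates`, `observed`), `genotype` (list of key sets per
#'   node), `compatible`, `exact`, `homoplasy`, `well_id`, `n_isolates`.
#' @export
build_tree <- function(dataset, well_id) {
  stopifnot(inherits(dataset, "mut_dataset"))
  og <- observed_genotypes(dataset, well_id)
  mutations <- sort(unique(unlist(og$genotypes, use.names = FALSE)))
  iso_count <- vapply(mutations, function(k)
    sum(og$multiplicity[vapply(og$genotypes, function(g) k %in% g, TRUE)]),
    0L)
  ord <- order(-iso_count, mutations)
  rank <- stats::setNames(seq_along(mutations), mutations[ord])

  compatible <- is_compatible(og$genotypes, mutations)
  tr <- greedy_trie(og$genotypes, og$multiplicity, rank)
  exact <- compatible
  if (!compatible && length(mutations) <= 30) {
    masks <- vapply(og$genotypes, function(g)
      sum(bitwShiftL(1L, match(g, mutations) - 1L)), 0)
    sol <- exact_steiner(as.integer(masks), length(mutations))
    if (!is.null(sol)) {
      ex <- expand_steiner(sol, mutations, rank)
      n_iso <- integer(length(ex$parent))
      for (gidx in seq_along(og$genotypes)) {
        mask <- as.character(as.integer(masks[gidx]))
        n_iso[ex$node_of[[mask]]] <-
          n_iso[ex$node_of[[mask]]] + og$multiplicity[gidx]
      }
      tr <- list(parent = ex$parent, gained = ex$gained,
                 genotype = ex$genotype, n_iso = n_iso)
      exact <- TRUE
    }
  }
  edge_labels <- tr$gained[-1]
  homoplasy <- if (length(edge_labels))
    length(edge_labels) - length(unique(edge_labels)) else 0L
  nodes <- data.frame(
    id = seq_along(tr$parent), parent = tr$parent, gained = tr$gained,
    n_isolates = tr$n_iso, observed = tr$n_iso > 0, stringsAsFactors = FALSE)
  structure(
    list(nodes = nodes, genotype = tr$genotype, compatible = compatible,
         exact = exact, homoplasy = as.integer(homoplasy),
         well_id = well_id, n_isolates = og$n_isolates),
    class = "genotype_tree")
}

#' Build genotype trees for every well
#'
#' @param dataset A [mut_dataset()].
#' @return Named list of [build_tree()] results.
#' @export
build_well_trees <- function(dataset) {
  stats::setNames(lapply(dataset$wells$well_id, build_tree, dataset = dataset),
                  dataset$wells$well_id)
}

#' @export
print.genotype_tree <- function(x, ...) {
  cat("Genotype tree for well ", x$well_id, ": ", nrow(x$nodes), " nodes, ",
      sum(x$nodes$observed), " observed genotypes, ",
      if (x$compatible) "perfect phylogeny"
      else paste0("incompatible (homoplasy ", x$homoplasy, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Classify the clonal dynamics of a well
#'
#' Partitions within-well tree shapes into four archetypes: all sampled
#' isolates identical (`fixed_identical`, consistent with completed selective
#' sweeps); single mutations hanging as tips off one shared background
#' (`interference_star`, classic clonal interference among one-step
#' lineages); an unbranched chain of nested genotypes (`sequential_chain`,
#' mutations accumulating sequentially on the currently fittest background);
#' and anything with competing multi-step lineages (`branched_multistep`).
#'
#' @param tree A [build_tree()] result.
#' @return One of `"fixed_identical"`, `"interference_star"`,
#'   `"sequential_chain"`, `"branched_multistep"`.
#' @export
classify_dynamics <- function(tree) {
  stopifnot(inherits(tree, "genotype_tree"))
  obs <- tree$genotype[tree$nodes$observed]
  if (length(obs) == 1) return("fixed_identical")
  g0 <- Reduce(intersect, obs)
  if (all(vapply(obs, function(g) length(setdiff(g, g0)) <= 1, TRUE)))
    return("interference_star")
  sizes <- order(lengths(obs))
  chain <- TRUE
  for (i in seq_along(sizes)[-1]) {
    if (!all(obs[[sizes[i - 1]]] %in% obs[[sizes[i]]])) { chain <- FALSE; break }
  }
  if (chain) return("sequential_chain")
  "branched_multistep"
}

#' Classify mutations as adaptive from repeatability and frequency rise
#'
#' Two observational signatures mark a mutation as adaptive: (1) it arises in
#' two or more wells independently (`multi_well`), or (2) in at least one
#' well it rises to moderate/high frequency unaccompanied by another new
#' mutation (`frequency_rise`): it is carried by at least
#' `min_isolates_for_rise` isolates and the well's tree contains an edge
#' where it is the sole gain between the root or an observed genotype and an
#' observed genotype (so its rise is not explained by hitchhiking with a
#' second mutation).
#'
#' @param dataset A [mut_dataset()] (QC applied).
#' @param trees Trees from [build_well_trees()] (built if omitted).
#' @param min_isolates_for_rise Isolate-count threshold for a frequency rise
#'   (default 2 of the typical five isolates per well).
#' @return Object of class `adaptive_evidence`: `evidence` (`data.frame`:
#'   `key`, `multi_well`, `frequency_rise`, `adaptive`, `n_wells`),
#'   `n_adaptive`, `adaptive_events`, `total_events`.
#' @export
classify_adaptive <- function(dataset, trees = NULL,
                              min_isolates_for_rise = 2) {
  stopifnot(inherits(dataset, "mut_dataset"))
  trees <- trees %||% build_well_trees(dataset)
  counts <- count_mutations_and_events(dataset)
  keys <- names(counts$per_mutation_well_counts)
  multi_well <- counts$per_mutation_well_counts >= 2

  rise <- stats::setNames(rep(FALSE, length(keys)), keys)
  for (tree in trees) {
    nd <- tree$nodes
    iso_of <- function(k) sum(nd$n_isolates[
      vapply(tree$genotype, function(g) k %in% g, TRUE)])
    for (i in seq_len(nrow(nd))[-1]) {
      k <- nd$gained[i]
      if (rise[[k]]) next
      par <- nd$parent[i]
      parent_ok <- par == 1L || nd$observed[par]
      if (parent_ok && nd$observed[i] && iso_of(k) >= min_isolates_for_rise)
        rise[k] <- TRUE
    }
  }
  evidence <- data.frame(
    key = keys, multi_well = unname(multi_well),
    frequency_rise = unname(rise[keys]),
    adaptive = unname(multi_well | rise[keys]),
    n_wells = unname(counts$per_mutation_well_counts),
    stringsAsFactors = FALSE)
  structure(
    list(evidence = evidence,
         n_adaptive = sum(evidence$adaptive),
         adaptive_events = sum(evidence$n_wells[evidence$adaptive]),
         total_events = counts$events),
    class = "adaptive_evidence")
}

#' @export
print.adaptive_evidence <- function(x, ...) {
  cat("Adaptive evidence:", x$n_adaptive, "of", nrow(x$evidence),
      "mutations adaptive;", x$adaptive_events, "of", x$total_events,
      "events\n")
  invisible(x)
}

#' Venn partition of adaptive evidence by functional class
#'
#' Cross-tabulates the two adaptive signatures against the silent vs
#' non-silent (regulatory or nonsynonymous) functional split, in both
#' mutation and event units.
#'
#' @param dataset A [mut_dataset()] with annotation.
#' @param evidence A [classify_adaptive()] result.
#' @return `data.frame` with one row per (functional side, evidence cell).
#' @export
adaptive_venn <- function(dataset, evidence) {
  stopifnot(inherits(evidence, "adaptive_evidence"))
  if (is.null(dataset$annotation)) stop("dataset has no annotation")
  ev <- evidence$evidence
  cat <- annotate_catalog(ev$key, dataset$annotation)
  side <- ifelse(cat$functional_class == "silent", "silent", "non-silent")
  cell <- ifelse(ev$multi_well & ev$frequency_rise, "both",
          ifelse(ev$multi_well, "multi_well_only",
          ifelse(ev$frequency_rise, "rise_only", "neither")))
  out <- aggregate(list(mutations = rep(1L, nrow(ev)), events = ev$n_wells),
                   by = list(side = side, evidence = cell), FUN = sum)
  out[order(out$side, out$evidence), ]
}

#' Serialize a genotype tree as a Newick string
#'
#' Nodes are labeled by the mutation gained on their incoming edge (the root
#' is `"anc"`), with `_x<n>` appended for genotypes observed in n isolates.
#' Unobserved intermediate genotypes appear as unlabeled-count internal
#' nodes, and unbranched chains are preserved as nested single-child groups.
#'
#' @param tree A [build_tree()] result.
#' @return A single Newick string (semicolon-terminated).
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "genotype_tree"))
  nd <- tree$nodes
  children <- split(nd$id[-1], nd$parent[-1])
  label <- function(i) {
    base <- if (i == 1L) "anc" else gsub("[^A-Za-z0-9]", "_", nd$gained[i])
    if (nd$n_isolates[i] > 0) paste0(base, "_x", nd$n_isolates[i]) else base
  }
  rec <- function(i) {
    ch <- children[[as.character(i)]]
    if (is.null(ch) || length(ch) == 0) return(label(i))
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", label(i))
  }
  paste0(rec(1L), ";")
}
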