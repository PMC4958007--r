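# Independent oracles used to freeze expected values. These deliberately do
# not share code with the implementation under test.

# Exhaustive minimum-length gains-only parsimony via a Dreyfus-Wagner Steiner
# DP over the full subset lattice (feasible for <= 6 mutations). Terminals
# are observed genotypes given as lists of integer mutation indices; the root
# (all-ancestral genotype) is cost-free.
min_parsimony_length <- function(genotypes, n_mut) {
  masks <- unique(vapply(genotypes, function(g)
    sum(bitwShiftL(1L, g - 1L)), 0L))
  masks <- setdiff(masks, 0L)
  t <- length(masks)
  if (t == 0) return(0L)
  n_nodes <- bitwShiftL(1L, n_mut)
  pc <- vapply(0:(n_nodes - 1), function(x)
    sum(bitwAnd(x, bitwShiftL(1L, 0:(n_mut - 1))) > 0), 0L)
  INF <- 1e9
  DP <- matrix(INF, bitwShiftL(1L, t), n_nodes)
  ord <- order(-pc)
  relax <- function(row) {
    for (v in ord) {
      best <- row[v]
      for (b in 0:(n_mut - 1)) {
        w <- bitwOr(v - 1L, bitwShiftL(1L, b)) + 1L
        if (w != v && row[w] + 1 < best) best <- row[w] + 1
      }
      row[v] <- best
    }
    row
  }
  for (i in seq_len(t)) {
    S <- bitwShiftL(1L, i - 1L)
    row <- rep(INF, n_nodes)
    term <- masks[i]
    for (v in 1:n_nodes) {
      vm <- v - 1L
      if (bitwAnd(vm, bitwNot(term)) == 0)
        row[v] <- pc[bitwXor(term, vm) + 1]
    }
    DP[S + 1, ] <- relax(row)
  }
  for (S in 1:(bitwShiftL(1L, t) - 1L)) {
    if (sum(bitwAnd(S, bitwShiftL(1L, 0:(t - 1))) > 0) < 2) next
    low <- bitwAnd(S, -S)
    row <- DP[S + 1, ]
    sub <- S
    repeat {
      sub <- bitwAnd(sub - 1L, S)
      if (sub == 0) break
      if (bitwAnd(sub, low) == 0) next
      row <- pmin(row, DP[sub + 1, ] + DP[bitwXor(S, sub) + 1, ])
    }
    DP[S + 1, ] <- relax(row)
  }
  DP[bitwShiftL(1L, t), 1]
}

# Random <= 6-mutation toy matrices for the parsimony fixture set: each toy is
# a list(genotypes = list of integer index vectors, n_mut).
parsimony_toys <- function(n_toys = 40, seed = 99) {
  toys <- list(
    # hand cases: pairwise-incompatible triangle (minimum length 5) and a
    # nested compatible chain (length 3)
    list(genotypes = list(c(1, 2), c(1, 3), c(2, 3)), n_mut = 3),
    list(genotypes = list(1, c(1, 2), c(1, 2, 3)), n_mut = 3),
    list(genotypes = list(c(1, 2), 1, 2), n_mut = 2))
  withr::with_seed(seed, {
    for (i in seq_len(n_toys)) {
      n_mut <- sample(2:6, 1)
      n_iso <- sample(3:7, 1)
      mat <- matrix(stats::runif(n_iso * n_mut) < stats::runif(1, 0.25, 0.6),
                    n_iso, n_mut)
      toys[[length(toys) + 1]] <-
        list(genotypes = apply(mat, 1, which, simplify = FALSE),
             n_mut = n_mut)
    }
  })
  toys
}

# Dataset wrapper for a parsimony toy (abstract keys in index order).
toy_to_dataset <- function(toy) {
  keys <- abstract_keys(toy$n_mut)
  toy_well(lapply(toy$genotypes, function(g) keys[g]))
}

# Canonical collapsed form of a rooted genotype tree: keep the root, the
# `kept` genotypes and every branching node of the induced Steiner tree, and
# return the sorted "parent=>child" edge strings over genotype signatures.
collapse_edges <- function(parent, genotypes, kept_idx) {
  sig <- vapply(genotypes, function(g) paste(sort(g), collapse = "+"), "")
  n <- length(parent)
  on_path <- rep(FALSE, n)
  for (i in kept_idx) {
    j <- i
    while (j != 0 && !on_path[j]) {
      on_path[j] <- TRUE
      j <- parent[j]
    }
  }
  n_child <- integer(n)
  for (i in which(on_path)) if (parent[i] != 0) {
    n_child[parent[i]] <- n_child[parent[i]] + 1L
  }
  keep <- rep(FALSE, n)
  keep[1] <- TRUE
  keep[kept_idx] <- TRUE
  keep[on_path & n_child >= 2] <- TRUE
  edges <- character(0)
  for (i in which(keep)) {
    if (i == 1) next
    j <- parent[i]
    while (!keep[j]) j <- parent[j]
    edges <- c(edges, paste0(sig[j], "=>", sig[i]))
  }
  sort(edges)
}

# Collapsed edges of a reconstructed genotype_tree (kept = observed nodes).
tree_collapsed <- function(tree) {
  collapse_edges(tree$nodes$parent, tree$genotype,
                 which(tree$nodes$observed))
}

# Collapsed edges of a SimTruth well restricted to its sampled genotypes.
truth_collapsed <- function(tw) {
  collapse_edges(tw$parent, tw$genotype, unique(tw$sampled_nodes))
}

# Direct binomial log-likelihood evaluator (constant-free), used as the
# independent route for LRT expectations.
direct_binom_ll <- function(x, n, p) {
  stopifnot(length(x) == length(n), length(p) %in% c(1, length(x)))
  p <- rep_len(p, length(x))
  ll <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0) ll <- ll + x[i] * log(p[i])
    if (n[i] - x[i] > 0) ll <- ll + (n[i] - x[i]) * log(1 - p[i])
  }
  ll
}
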