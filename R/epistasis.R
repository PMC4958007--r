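#' Within- vs between-background parallelism ratio test
#'
#' One signature of background epistasis is parallelism being higher among
#' wells that share a founding background than among wells that do not. This
#' test averages P_ij over all within-background pairs and over all
#' between-background pairs, takes the ratio, and obtains a one-tailed
#' p-value by permuting the well-to-background labels and recomputing the
#' ratio (add-one estimator).
#'
#' @param dataset A [mut_dataset()].
#' @param level `"nucleotide"` or `"cluster"`.
#' @param include_reversions Keep reversions (default FALSE)?
#' @param n_boot Number of label randomizations (default 9999).
#' @param seed Optional RNG seed.
#' @return Object of class `within_between`: `mean_within`, `mean_between`,
#'   `ratio`, `null` (null ratios), `p_value`.
#' @export
within_between_test <- function(dataset, level = c("nucleotide", "cluster"),
                                include_reversions = FALSE, n_boot = 9999,
                                seed = NULL) {
  stopifnot(inherits(dataset, "mut_dataset"))
  level <- match.arg(level)
  bg_sizes <- table(dataset$wells$background_id)
  if (length(bg_sizes) < 2 || sum(bg_sizes >= 2) < 2)
    stop("need at least two backgrounds with at least two wells")
  P <- pairwise_parallelism(dataset, level, include_reversions)
  labels0 <- P$wells$background_id
  idx <- which(upper.tri(P$values), arr.ind = TRUE)
  v <- P$values[idx]
  keep <- !is.na(v)
  wi <- idx[keep, 1]; wj <- idx[keep, 2]; v <- v[keep]
  stat <- function(lab) {
    within <- lab[wi] == lab[wj]
    c(mean_within = mean(v[within]), mean_between = mean(v[!within]))
  }
  obs <- stat(labels0)
  if (is.na(obs[["mean_between"]]) || obs[["mean_between"]] == 0) {
    warning("mean between-background parallelism is zero; ratio undefined")
    return(structure(list(mean_within = obs[["mean_within"]],
                          mean_between = obs[["mean_between"]],
                          ratio = NA_real_, null = numeric(0),
                          p_value = NA_real_),
                     class = "within_between"))
  }
  ratio <- obs[["mean_within"]] / obs[["mean_between"]]
  run <- function() vapply(seq_len(n_boot), function(i) {
    s <- stat(sample(labels0))
    s[["mean_within"]] / s[["mean_between"]]
  }, 0)
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(mean_within = obs[["mean_within"]],
         mean_between = obs[["mean_between"]], ratio = ratio, null = null,
         p_value = perm_pvalue(null, ratio, "greater")),
    class = "within_between")
}

#' @export
print.within_between <- function(x, ...) {
  cat("Within/between parallelism: mean within =", round(x$mean_within, 4),
      ", mean between =", round(x$mean_between, 4),
      ", ratio =", round(x$ratio, 4), ", p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

# Well-level presence matrix (wells x mutations), optionally dropping all
# background-reversion keys.
presence_matrix <- function(dataset, exclude_reversions = TRUE) {
  sets <- well_mutation_sets(dataset, include_reversions = TRUE)
  keys <- sort(unique(unlist(sets, use.names = FALSE)))
  if (exclude_reversions) keys <- setdiff(keys, all_reversion_keys(dataset))
  M <- matrix(FALSE, length(sets), length(keys),
              dimnames = list(names(sets), keys))
  for (w in names(sets)) M[w, intersect(sets[[w]], keys)] <- TRUE
  M
}

# Per-mutation delta lnL (alternative - null) and total Lambda for a given
# background labelling of the rows of presence matrix M.
lrt_lambda <- function(M, labels) {
  N <- nrow(M)
  n_k <- colSums(M)
  phat <- n_k / N
  lnl_null <- N * (xlogx(phat) + xlogx(1 - phat))
  groups <- rowsum(M + 0, labels)            # backgrounds x mutations counts
  N_b <- as.vector(table(labels)[rownames(groups)])
  ph_b <- groups / N_b
  lnl_alt <- colSums(N_b * (xlogx(ph_b) + xlogx(1 - ph_b)))
  delta <- lnl_alt - lnl_null
  delta[delta < 0] <- 0                      # numerical guard
  list(lambda = sum(delta), delta = delta,
       lnl_null = sum(lnl_null), lnl_alt = sum(lnl_alt))
}

#' Likelihood-ratio test for mutation-by-background association
#'
#' For every mutation, compares a null model in which its probability of
#' arising is the same in every well (one Bernoulli rate, the pooled MLE)
#' with an alternative model in which the rate depends on the founding
#' background (per-background MLEs). Presence is scored at the well level
#' (the mutation occurs in at least one isolate of the well). The total
#' statistic Lambda is the sum of the per-mutation log-likelihood
#' differences, each nonnegative by construction; its null distribution is
#' obtained by permuting the well-to-background labels. Mutations present in
#' no or in all wells contribute exactly zero and are flagged.
#'
#' @param dataset A [mut_dataset()].
#' @param exclude_reversions Drop background-reversion keys (default TRUE;
#'   reversion opportunity is background-specific by construction, so they
#'   are tested separately by [reversion_lrt()]).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `lrt_result`: `lnL_null`, `lnL_alt`, `lambda`,
#'   `per_mutation_delta` (sorted decreasing), `saturated` (flagged keys),
#'   `p_value`, `method = "randomization"`.
#' @export
mutation_background_lrt <- function(dataset, exclude_reversions = TRUE,
                                    n_perm = 999, seed = NULL) {
  stopifnot(inherits(dataset, "mut_dataset"))
  # a single background makes the models coincide: Lambda is exactly zero
  M <- presence_matrix(dataset, exclude_reversions)
  labels0 <- dataset$wells$background_id[
    match(rownames(M), dataset$wells$well_id)]
  obs <- lrt_lambda(M, labels0)
  run <- function() vapply(seq_len(n_perm), function(i)
    lrt_lambda(M, sample(labels0))$lambda, 0)
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  n_k <- colSums(M)
  structure(
    list(lnL_null = obs$lnl_null, lnL_alt = obs$lnl_alt,
         lambda = obs$lambda,
         per_mutation_delta = sort(obs$delta, decreasing = TRUE),
         saturated = colnames(M)[n_k == 0 | n_k == nrow(M)],
         null = null, p_value = perm_pvalue(null, obs$lambda, "greater"),
         n_perm = n_perm, method = "randomization"),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio test (", x$method, "): Lambda = ",
      round(x$lambda, 3), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Stepwise identification of influential epistatic mutations
#'
#' Repeatedly runs [mutation_background_lrt()], removing the mutation with
#' the largest per-mutation log-likelihood difference (equivalently the
#' smallest individual likelihood under the null) while the global test
#' remains significant, and stops once the p-value is at least `alpha`. Ties
#' on the log-likelihood difference are broken by lexicographic key order.
#'
#' @param dataset A [mut_dataset()].
#' @param alpha Stopping significance level (default 0.05).
#' @param n_perm Permutations per iteration (default 999).
#' @param seed Optional RNG seed (advanced per iteration).
#' @param exclude_reversions Drop reversion keys (default TRUE).
#' @return `data.frame` with one row per removed mutation: `key`,
#'   `delta_lnl` (its contribution when removed), `p_after` (global p-value
#'   after its removal). The p-value of the full dataset is stored in the
#'   `"p_initial"` attribute.
#' @export
stepwise_influential <- function(dataset, alpha = 0.05, n_perm = 999,
                                 seed = NULL, exclude_reversions = TRUE) {
  stopifnot(inherits(dataset, "mut_dataset"))
  M <- presence_matrix(dataset, exclude_reversions)
  labels0 <- dataset$wells$background_id[
    match(rownames(M), dataset$wells$well_id)]
  step_seed <- function(i) if (is.null(seed)) NULL else substream_seed(seed, i)
  run_lrt <- function(M, s) {
    obs <- lrt_lambda(M, labels0)
    run <- function() vapply(seq_len(n_perm), function(i)
      lrt_lambda(M, sample(labels0))$lambda, 0)
    null <- if (is.null(s)) run() else with_seed(s, run())
    list(obs = obs, p = perm_pvalue(null, obs$lambda, "greater"))
  }
  cur <- run_lrt(M, step_seed(1L))
  p_initial <- cur$p
  removed <- list()
  it <- 1L
  while (cur$p < alpha && ncol(M) > 1) {
    d <- cur$obs$delta
    top <- names(d)[order(-d, names(d))][1]
    M <- M[, setdiff(colnames(M), top), drop = FALSE]
    it <- it + 1L
    nxt <- run_lrt(M, step_seed(it))
    removed[[top]] <- data.frame(key = top, delta_lnl = unname(d[top]),
                                 p_after = nxt$p, stringsAsFactors = FALSE)
    cur <- nxt
  }
  out <- if (length(removed)) do.call(rbind, removed) else
    data.frame(key = character(0), delta_lnl = numeric(0),
               p_after = numeric(0))
  rownames(out) <- NULL
  attr(out, "p_initial") <- p_initial
  out
}

#' Likelihood-ratio test for background-dependent reversion probability
#'
#' Compares a null binomial model with one shared reversion probability
#' across backgrounds against an alternative with a free per-background
#' probability. Backgrounds may contribute unequal numbers of available
#' wells. Twice the log-likelihood difference is referred to a chi-squared
#' distribution with B - 1 degrees of freedom.
#'
#' @param reverted Named integer vector: reverted wells per background, or a
#'   [mut_dataset()] (counts are then derived with [classify_reversions()]).
#' @param total Integer vector of available wells per background (ignored
#'   when `reverted` is a dataset).
#' @return Object of class `lrt_result` with `method = "chi-squared"` and a
#'   `counts` data.frame.
#' @export
reversion_lrt <- function(reverted, total = NULL) {
  if (inherits(reverted, "mut_dataset")) {
    dataset <- reverted
    flags <- classify_reversions(dataset)
    bg <- dataset$wells$background_id
    reverted <- vapply(split(flags, bg), sum, 0)
    total <- vapply(split(flags, bg), length, 0)
  }
  stopifnot(length(reverted) == length(total), all(reverted <= total))
  B <- length(reverted)
  if (B < 2) stop("need at least two backgrounds")
  p_pool <- sum(reverted) / sum(total)
  lnl_null <- binom_loglik(reverted, total, rep(p_pool, B))
  p_b <- reverted / total
  lnl_alt <- binom_loglik(reverted, total, p_b)
  lambda <- lnl_alt - lnl_null
  structure(
    list(lnL_null = lnl_null, lnL_alt = lnl_alt, lambda = lambda,
         df = B - 1L,
         p_value = stats::pchisq(2 * lambda, df = B - 1, lower.tail = FALSE),
         counts = data.frame(background_id = names(reverted) %||%
                               as.character(seq_len(B)),
                             reverted = as.integer(reverted),
                             total = as.integer(total),
                             stringsAsFactors = FALSE),
         method = "chi-squared"),
    class = "lrt_result")
}
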