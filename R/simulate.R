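#' Configuration for the synthetic replicate-adaptation generator
#'
#' The generator emulates the statistical structure the analyses in this
#' package assume: several founding genetic backgrounds, replicate wells per
#' background, a skewed per-mutation incidence spectrum with optional
#' background-dependent (epistatic) effects on the log-odds scale, mutual
#' exclusivity groups enforced along lineage paths, background-dependent
#' reversion probabilities, and within-well clonal structure grown by uniform
#' attachment.
#'
#' @param background_catalog Named character vector mapping background ids to
#'   founding mutation keys (one entry per background).
#' @param catalog Character vector of candidate de novo mutation keys (size K).
#' @param p Numeric length-K base incidence of each mutation, in `[0, 1]`;
#'   used as sampling weights for the identities drawn in each well.
#' @param delta Optional K x B matrix of background effects added to
#'   `qlogis(p)` (rows = catalog order, columns = background order); zero
#'   means no epistasis.
#' @param exclusivity_groups List of disjoint character vectors of catalog
#'   keys; no two members of a group are ever placed on the same root-to-leaf
#'   lineage path.
#' @param reversion_prob Numeric length-B probability that a well of each
#'   background acquires a reversion lineage.
#' @param lambda Mean of the (truncated) Poisson number of de novo mutations
#'   per well.
#' @param m_range Integer vector `c(min, max)` truncation support for the
#'   per-well mutation count.
#' @param wells_per_background,isolates_per_well Replication of the design.
#' @param annotation Optional [genome_annotation()] attached to simulated
#'   datasets (required for cluster-level analyses of simulated data).
#' @param seed Optional default RNG seed used by [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(background_catalog, catalog, p, delta = NULL,
                       exclusivity_groups = list(), reversion_prob = 0,
                       lambda = 4.5, m_range = c(2L, 9L),
                       wells_per_background = 8L, isolates_per_well = 5L,
                       annotation = NULL, seed = NULL) {
  B <- length(background_catalog)
  K <- length(catalog)
  stopifnot(B >= 1, K >= 1, length(p) == K)
  if (any(p < 0 | p > 1)) stop("incidence p must lie in [0, 1]")
  if (lambda <= 0) stop("lambda must be positive")
  m_range <- as.integer(m_range)
  if (m_range[1] < 0 || m_range[1] > m_range[2]) stop("invalid m_range")
  if (m_range[2] > K)
    stop("infeasible config: m_range maximum (", m_range[2],
         ") exceeds catalog size (", K, ")")
  reversion_prob <- rep_len(reversion_prob, B)
  if (any(reversion_prob < 0 | reversion_prob > 1))
    stop("reversion_prob must lie in [0, 1]")
  if (anyDuplicated(catalog)) stop("duplicate keys in catalog")
  grp_keys <- unlist(exclusivity_groups, use.names = FALSE)
  if (anyDuplicated(grp_keys))
    stop("exclusivity groups must be disjoint")
  if (!all(grp_keys %in% catalog))
    stop("exclusivity group member(s) not in catalog")
  if (is.null(delta)) {
    delta <- matrix(0, K, B)
  } else {
    delta <- as.matrix(delta)
    stopifnot(nrow(delta) == K, ncol(delta) == B)
  }
  dimnames(delta) <- list(catalog, names(background_catalog))
  structure(
    list(background_catalog = background_catalog, catalog = catalog,
         p = stats::setNames(p, catalog), delta = delta,
         exclusivity_groups = exclusivity_groups,
         reversion_prob = stats::setNames(reversion_prob,
                                          names(background_catalog)),
         lambda = lambda, m_range = m_range,
         wells_per_background = as.integer(wells_per_background),
         isolates_per_well = as.integer(isolates_per_well),
         annotation = annotation, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", length(x$background_catalog), "backgrounds x",
      x$wells_per_background, "wells x", x$isolates_per_well, "isolates;",
      length(x$catalog), "candidate mutations; lambda =", x$lambda,
      "on [", x$m_range[1], ",", x$m_range[2], "]\n")
  invisible(x)
}

# index of each catalog key's exclusivity group (NA when ungrouped)
group_index <- function(config) {
  gi <- rep(NA_integer_, length(config$catalog))
  names(gi) <- config$catalog
  for (g in seq_along(config$exclusivity_groups))
    gi[config$exclusivity_groups[[g]]] <- g
  gi
}

draw_truncated_pois <- function(n, lambda, m_range) {
  support <- m_range[1]:m_range[2]
  pr <- stats::dpois(support, lambda)
  if (sum(pr) <= 0) stop("empty truncated Poisson support")
  support[sample.int(length(support), n, replace = TRUE, prob = pr)]
}

#' Mean of the truncated Poisson per-well mutation count
#'
#' Convenience closed form used to check the generator against its target.
#'
#' @param lambda Poisson mean before truncation.
#' @param m_range Truncation support `c(min, max)`.
#' @return The truncated mean.
#' @export
truncated_pois_mean <- function(lambda, m_range) {
  support <- m_range[1]:m_range[2]
  pr <- stats::dpois(support, lambda)
  sum(support * pr) / sum(pr)
}

# Grow one well: draw identities, grow the genotype tree by uniform
# attachment, optionally inject a reversion, sample isolates.
simulate_well <- function(config, bg_index, gi, max_reject = 1000L) {
  bg <- names(config$background_catalog)[bg_index]
  m <- draw_truncated_pois(1, config$lambda, config$m_range)
  eta <- ifelse(config$p <= 0, -Inf,
                ifelse(config$p >= 1, Inf,
                       stats::qlogis(config$p) + config$delta[, bg_index]))
  w <- stats::plogis(eta)
  if (sum(w > 0) < m) stop("fewer positive-weight mutations than m")
  muts <- config$catalog[sample.int(length(w), m, prob = w)]

  # node 1 is the root (the well's ancestral genotype; empty de novo set)
  parent <- integer(1)
  gained <- NA_character_
  paths <- list(character(0))
  rejections <- 0L
  i <- 1L
  while (i <= length(muts)) {
    k <- muts[i]
    eligible <- seq_along(paths)
    if (!is.na(gi[[k]])) {
      mates <- config$catalog[!is.na(gi) & gi == gi[[k]]]
      eligible <- which(!vapply(paths, function(pp) any(mates %in% pp), TRUE))
    }
    if (length(eligible) == 0) {
      # every lineage already carries a group mate: replace this identity
      rejections <- rejections + 1L
      if (rejections > max_reject)
        stop("exclusivity constraint (group ", gi[[k]],
             ") could not be satisfied after ", max_reject, " rejections")
      remaining <- setdiff(which(w > 0), match(muts, config$catalog))
      if (length(remaining) == 0)
        stop("exclusivity constraint (group ", gi[[k]],
             "): no replacement identities available")
      muts[i] <- config$catalog[remaining[
        sample.int(length(remaining), 1, prob = w[remaining])]]
      next
    }
    at <- if (length(eligible) == 1) eligible else
      eligible[sample.int(length(eligible), 1)]
    parent <- c(parent, at)
    gained <- c(gained, k)
    paths <- c(paths, list(c(paths[[at]], k)))
    i <- i + 1L
  }

  reverted <- stats::runif(1) < config$reversion_prob[[bg]]
  if (reverted) {
    rk <- reversion_key(config$background_catalog[[bg]])
    at <- sample.int(length(paths), 1)
    parent <- c(parent, at)
    gained <- c(gained, rk)
    paths <- c(paths, list(c(paths[[at]], rk)))
    muts <- c(muts, rk)
  }

  candidates <- if (length(paths) > 1) 2:length(paths) else 1L
  picked <- candidates[sample.int(length(candidates),
                                  config$isolates_per_well, replace = TRUE)]
  list(background_id = bg, m = m, mutations = muts, parent = parent,
       gained = gained, genotype = paths, reversion = reverted,
       sampled_nodes = picked)
}

#' Simulate a replicate-adaptation dataset with a truth record
#'
#' For each well the generator draws a truncated-Poisson number of de novo
#' mutations, draws their identities without replacement with probability
#' proportional to `plogis(qlogis(p) + delta)`, grows a genotype tree by
#' attaching each successive mutation to a uniformly chosen existing genotype
#' (attachments that would place two members of an exclusivity group on the
#' same root-to-leaf path are rejected), optionally injects a reversion
#' lineage, and samples isolates uniformly with replacement from the non-root
#' genotypes. A single master seed drives deterministic per-well substreams,
#' so enlarging the design does not perturb wells already generated.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed (defaults to `config$seed`).
#' @return List with components `dataset` (a [mut_dataset()]) and `truth`
#'   (class `sim_truth`: per-well trees, sampled nodes, reversion events, and
#'   the biased mutations implied by nonzero `delta`).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  gi <- group_index(config)
  B <- length(config$background_catalog)
  W <- config$wells_per_background
  n <- config$isolates_per_well

  wells <- list()
  calls <- vector("list", B * W)
  idx <- 0L
  for (b in seq_len(B)) {
    for (wi in seq_len(W)) {
      idx <- idx + 1L
      bg <- names(config$background_catalog)[b]
      well_id <- sprintf("%s_w%d", bg, wi)
      # substream keyed by (background, well index): enlarging the design
      # leaves previously generated wells untouched
      sim <- with_seed(substream_seed(seed, (b - 1L) * 100000L + wi),
                       simulate_well(config, b, gi))
      sim$well_id <- well_id
      iso_ids <- sprintf("%s_i%d", well_id, seq_len(n))
      sim$isolate_ids <- iso_ids
      wells[[well_id]] <- sim
      rows <- lapply(seq_len(n), function(j) {
        g <- sim$genotype[[sim$sampled_nodes[j]]]
        data.frame(isolate_id = iso_ids[j], well_id = well_id,
                   background_id = bg,
                   mutation_key = if (length(g) == 0) NA_character_ else g,
                   stringsAsFactors = FALSE)
      })
      calls[[idx]] <- do.call(rbind, rows)
    }
  }
  dataset <- mut_dataset(do.call(rbind, calls), config$background_catalog,
                         config$annotation)
  biased <- config$catalog[apply(config$delta != 0, 1, any)]
  truth <- structure(
    list(wells = wells, biased_mutations = biased, seed = seed,
         config = config),
    class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$wells), "wells; seed", x$seed, ";",
      sum(vapply(x$wells, `[[`, TRUE, "reversion")), "reversion events\n")
  invisible(x)
}

#' Write a simulation truth record as JSON
#'
#' @param truth A `sim_truth` object from [simulate_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  wells <- lapply(truth$wells, function(w)
    list(well_id = w$well_id, background_id = w$background_id, m = w$m,
         mutations = w$mutations, parent = w$parent, gained = w$gained,
         reversion = w$reversion, sampled_nodes = w$sampled_nodes))
  jsonlite::write_json(
    list(seed = truth$seed, biased_mutations = truth$biased_mutations,
         wells = unname(wells)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Study-calibrated generator preset
#'
#' Returns a [sim_config()] emulating the design and headline structure of a
#' nine-background, eight-fold-replicated phage adaptation: 9 backgrounds x 8
#' wells x 5 isolates; a catalog of 110 candidate mutations on the synthetic
#' genome of [synthetic_phage_annotation()]; two D-promoter hotspot mutations
#' with incidence 0.78 and 0.40 sharing an exclusivity group with five rarer
#' D-promoter members (so roughly 90% of wells carry a group member but no
#' lineage carries two); six moderate-incidence mutations in and around the
#' D/E/J region, four of which carry planted background effects on the
#' log-odds scale; and 97 low-incidence mutations so that most mutations
#' appear in four or fewer wells. Reversion probability is heterogeneous:
#' 7/8 for background F416, zero for three backgrounds, 0.2 for the rest
#' (expected reverted wells = 15 of 72). The per-well mutation count is
#' truncated Poisson with mean 4.5 on [2, 9].
#'
#' @param seed Optional default seed stored in the config.
#' @return A [sim_config()].
#' @export
study_preset <- function(seed = NULL) {
  ann <- synthetic_phage_annotation()
  genome <- strsplit(ann$ancestral_seq, "")[[1]]
  key_at <- function(pos, to) mutation_key(pos, genome[pos], to)

  backgrounds <- c(F416 = 3846L, F421 = 3861L, F178 = 3132L, J15 = 2441L,
                   J20 = 2456L, G72 = 4154L, H57 = 4669L, A44 = 131L,
                   C8 = 1562L)
  bg_to <- vapply(backgrounds, function(pos) {
    setdiff(c("A", "C", "G", "T"), genome[pos])[1]
  }, "")
  background_catalog <- stats::setNames(
    mapply(key_at, backgrounds, bg_to), names(backgrounds))

  dpro <- c("1910aG", "1911cT", "1909tA", "1913gA", "1920aC", "1928cG",
            "1935gT")
  moderates <- c("2534gT", "2397aG", "2134tC", "2332aG", "2100tC", "2158aG")
  fixed_pos <- c(1909:1935, 2094, 2100, 2131, 2134, 2158, 2332, 2397, 2534,
                 2577, 2630, backgrounds)
  small_pos <- with_seed(417L, sample(setdiff(seq_len(ann$genome_length),
                                              fixed_pos), 97))
  smalls <- vapply(small_pos, function(pos)
    key_at(pos, setdiff(c("A", "C", "G", "T"), genome[pos])[1]), "")

  catalog <- c(dpro, moderates, smalls)
  p <- c(0.78, 0.40, rep(0.012, 5),            # D-promoter group
         0.10, 0.09, 0.08, 0.07, 0.06, 0.05,   # moderates
         rep(0.007, 97))

  delta <- matrix(0, length(catalog), length(backgrounds),
                  dimnames = list(catalog, names(backgrounds)))
  delta["2534gT", "F416"] <- 3
  delta["2397aG", "F421"] <- 2
  delta["2332aG", "J15"] <- 2
  delta["2100tC", "J20"] <- 2

  reversion_prob <- c(F416 = 7 / 8, F421 = 0.2, F178 = 0.2, J15 = 0.2,
                      J20 = 0.2, G72 = 0, H57 = 0.2, A44 = 0, C8 = 0)

  sim_config(
    background_catalog = background_catalog, catalog = catalog, p = p,
    delta = delta, exclusivity_groups = list(dpro),
    reversion_prob = reversion_prob, lambda = 4.5, m_range = c(2L, 9L),
    wells_per_background = 8L, isolates_per_well = 5L,
    annotation = ann, seed = seed)
}
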