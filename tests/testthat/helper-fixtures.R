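# Builders for small in-code fixtures shared across test files.

# Long-format calls table from a named list well -> list of isolate genotypes
# (character vectors of keys). Backgrounds taken from `bg_of` (well -> id).
make_calls <- function(wells, bg_of) {
  rows <- list()
  for (w in names(wells)) {
    for (i in seq_along(wells[[w]])) {
      g <- wells[[w]][[i]]
      rows[[length(rows) + 1]] <- data.frame(
        isolate_id = sprintf("%s_i%d", w, i), well_id = w,
        background_id = bg_of[[w]],
        mutation_key = if (length(g) == 0) NA_character_ else g,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# One-background toy dataset from a list of isolate genotypes for one well.
toy_well <- function(genotypes, bg_key = "5000cT", well = "w1", bg = "B1") {
  calls <- make_calls(stats::setNames(list(genotypes), well),
                      stats::setNames(list(bg), well))
  mut_dataset(calls, stats::setNames(bg_key, bg))
}

# Abstract keys: syntactically valid, positions spaced to avoid collisions.
abstract_keys <- function(n, offset = 100) sprintf("%daG", offset + seq_len(n) * 10)

# Null simulation config used for type-I calibration (frozen pilot values).
null_cfg <- function() {
  keys <- abstract_keys(25)
  bgs <- stats::setNames(sprintf("%dcT", 5000 + seq_len(4) * 10),
                         paste0("B", 1:4))
  sim_config(bgs, keys, p = rep(0.12, 25), lambda = 3.5, m_range = c(1L, 7L),
             wells_per_background = 4L, isolates_per_well = 4L)
}

# Planted-epistasis config used for power/recovery (frozen pilot values:
# one mutation at baseline incidence 0.01 with +8 log-odds on background B1).
planted_cfg <- function() {
  K <- 30L
  keys <- abstract_keys(K)
  bgs <- stats::setNames(sprintf("%dcT", 5000 + seq_len(6) * 10),
                         paste0("B", 1:6))
  p <- rep(0.04, K)
  p[1] <- 0.01
  delta <- matrix(0, K, 6)
  delta[1, 1] <- 8
  sim_config(bgs, keys, p = p, delta = delta, lambda = 5,
             m_range = c(3L, 8L), wells_per_background = 8L,
             isolates_per_well = 6L)
}

planted_key <- function() abstract_keys(1)

# Small annotated config (synthetic genome) for cluster-level properties:
# reuses the calibrated preset catalog but with a lighter design.
annotated_cfg <- function(wells_per_background = 3L) {
  cfg <- study_preset()
  sim_config(cfg$background_catalog, cfg$catalog, unname(cfg$p),
             delta = cfg$delta, exclusivity_groups = cfg$exclusivity_groups,
             reversion_prob = cfg$reversion_prob, lambda = cfg$lambda,
             m_range = cfg$m_range,
             wells_per_background = wells_per_background,
             isolates_per_well = cfg$isolates_per_well,
             annotation = cfg$annotation)
}
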