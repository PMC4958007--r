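#' Estimate a selection coefficient from competition trajectories
#'
#' Fits, for each replicate competition, an ordinary least-squares regression
#' of the natural log of mutant frequency on generation (generation =
#' passage x `generations_per_passage`); the slope estimates the
#' per-generation selection coefficient s. Replicate slopes are then
#' averaged, and the standard error is taken over replicates. Replicates
#' containing boundary frequencies (0 or 1) are excluded with a warning, as
#' the log transform is undefined there.
#'
#' @param trajectories `data.frame` with columns `replicate_id`, `passage`,
#'   `frequency` (mutant frequency in `(0, 1)`).
#' @param generations_per_passage Generations elapsing per passage
#'   (default 2).
#' @return Object of class `selection_estimate`: `s` (mean slope), `se`,
#'   `per_replicate` (`data.frame`: `replicate_id`, `slope`, `n_points`),
#'   `excluded` (replicate ids dropped at the boundary).
#' @export
estimate_selection <- function(trajectories, generations_per_passage = 2) {
  req <- c("replicate_id", "passage", "frequency")
  if (!all(req %in% names(trajectories)))
    stop("trajectories must have columns: ", paste(req, collapse = ", "))
  reps <- split(trajectories, trajectories$replicate_id)
  excluded <- character(0)
  rows <- list()
  for (rid in names(reps)) {
    tr <- reps[[rid]][order(reps[[rid]]$passage), ]
    if (anyDuplicated(tr$passage)) stop("replicate ", rid,
                                        " has duplicated passages")
    if (any(tr$frequency <= 0 | tr$frequency >= 1)) {
      excluded <- c(excluded, rid)
      next
    }
    if (nrow(tr) < 2) stop("replicate ", rid, " has fewer than 2 time points")
    gen <- tr$passage * generations_per_passage
    fit <- stats::lm(log(tr$frequency) ~ gen)
    rows[[rid]] <- data.frame(replicate_id = rid,
                              slope = unname(stats::coef(fit)[2]),
                              n_points = nrow(tr), stringsAsFactors = FALSE)
  }
  if (length(excluded) > 0)
    warning("excluded replicate(s) with boundary frequency (0 or 1): ",
            paste(excluded, collapse = ", "))
  if (length(rows) == 0) stop("no usable replicates")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(
    list(s = mean(per$slope),
         se = if (nrow(per) > 1) stats::sd(per$slope) / sqrt(nrow(per))
              else NA_real_,
         per_replicate = per, excluded = excluded,
         generations_per_passage = generations_per_passage),
    class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat("Selection coefficient: s =", signif(x$s, 4), "+/-", signif(x$se, 3),
      "per generation (", nrow(x$per_replicate), "replicates )\n")
  invisible(x)
}

#' Summarize time-to-lysis burst curves
#'
#' Averages observed burst counts over replicates for each genotype and time
#' point (standard errors require at least two replicates). The lysis time of
#' a genotype is the first time point opening a sustained run of means above
#' `threshold` times the pre-rise baseline, where the baseline is the mean of
#' the first `baseline_window` time-point means; the delay between two
#' genotypes assayed on the same time grid is the difference of their lysis
#' times.
#'
#' @param burst `data.frame` with columns `genotype`, `time_min`,
#'   `replicate`, `burst`.
#' @param threshold Rise multiple of baseline defining lysis (default 2).
#' @param baseline_window Number of initial time points averaged into the
#'   baseline (default 5).
#' @param sustain Number of consecutive time points that must exceed the
#'   threshold (default 2): an isolated count spike is not a rise, so
#'   requiring persistence makes the call robust to counting noise.
#'   Truncated at the end of the series.
#' @return Object of class `lysis_summary`: `curves` (`data.frame`:
#'   `genotype`, `time_min`, `mean`, `se`, `n`), `lysis_time` (named
#'   vector, `NA` when no point exceeds the threshold), `delay` (matrix of
#'   pairwise lysis-time differences, row minus column), `threshold`.
#' @export
summarize_lysis <- function(burst, threshold = 2, baseline_window = 5,
                            sustain = 2) {
  req <- c("genotype", "time_min", "replicate", "burst")
  if (!all(req %in% names(burst)))
    stop("burst must have columns: ", paste(req, collapse = ", "))
  agg <- aggregate(burst$burst,
                   by = list(genotype = burst$genotype,
                             time_min = burst$time_min),
                   FUN = function(v) c(mean = mean(v),
                                       se = if (length(v) > 1)
                                         stats::sd(v) / sqrt(length(v))
                                       else NA_real_,
                                       n = length(v)))
  curves <- data.frame(genotype = agg$genotype, time_min = agg$time_min,
                       mean = agg$x[, "mean"], se = agg$x[, "se"],
                       n = as.integer(agg$x[, "n"]),
                       stringsAsFactors = FALSE)
  curves <- curves[order(curves$genotype, curves$time_min), ]
  rownames(curves) <- NULL

  lysis_time <- vapply(split(curves, curves$genotype), function(cv) {
    cv <- cv[order(cv$time_min), ]
    base <- mean(utils::head(cv$mean, baseline_window))
    over <- cv$mean > threshold * base
    n <- length(over)
    for (i in which(over)) {
      run <- over[i:min(n, i + sustain - 1L)]
      if (all(run)) return(cv$time_min[i])
    }
    NA_real_
  }, 0)

  gts <- names(lysis_time)
  delay <- outer(lysis_time, lysis_time, `-`)
  dimnames(delay) <- list(gts, gts)
  structure(
    list(curves = curves, lysis_time = lysis_time, delay = delay,
         threshold = threshold, baseline_window = baseline_window,
         sustain = sustain),
    class = "lysis_summary")
}

#' @export
print.lysis_summary <- function(x, ...) {
  cat("Lysis curves for", length(x$lysis_time), "genotypes; lysis times (",
      x$threshold, "x baseline ):\n", sep = "")
  print(round(x$lysis_time, 1))
  invisible(x)
}
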