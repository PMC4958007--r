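#' Construct a mutation-by-isolate dataset
#'
#' The central container for a replicate-adaptation experiment: each sequenced
#' isolate belongs to one well (a replicate evolving population) founded from
#' one ancestral genetic background, and carries a set of de novo mutations
#' called relative to that well's ancestor. Most users will build a dataset
#' with [read_mutation_table()] or [simulate_dataset()] rather than calling
#' this constructor directly.
#'
#' @param calls Long-format `data.frame` with columns `isolate_id`, `well_id`,
#'   `background_id`, `mutation_key` (one row per isolate x mutation;
#'   `NA`/`"."` key marks an isolate with no de novo mutations).
#' @param background_catalog Named character vector mapping each
#'   `background_id` to the mutation key of its founding first-step mutation.
#' @param annotation Optional [genome_annotation()]; required for
#'   regulatory/codon-level analyses.
#' @return An object of class `mut_dataset` with components `isolates`,
#'   `genotypes` (named list of key sets), `wells`, `catalog` (sorted keys
#'   observed in at least one isolate), `background_catalog`, `annotation`.
#' @export
mut_dataset <- function(calls, background_catalog, annotation = NULL) {
  req <- c("isolate_id", "well_id", "background_id", "mutation_key")
  if (!all(req %in% names(calls)))
    stop("calls must have columns: ", paste(req, collapse = ", "))
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  calls$mutation_key[calls$mutation_key %in% c(".", "")] <- NA_character_

  iso <- unique(calls[, c("isolate_id", "well_id", "background_id")])
  dup <- unique(iso$isolate_id[duplicated(iso$isolate_id)])
  if (length(dup) > 0)
    stop("isolate(s) assigned to more than one well/background: ",
         paste(utils::head(dup, 5), collapse = ", "))

  real <- calls[!is.na(calls$mutation_key), , drop = FALSE]
  if (nrow(real) > 0) {
    parse_mutation_key(unique(real$mutation_key))  # validates key syntax
    pair <- paste(real$isolate_id, real$mutation_key)
    if (anyDuplicated(pair))
      stop("duplicated isolate x mutation row(s), e.g.: ",
           pair[duplicated(pair)][1])
  }

  if (is.null(names(background_catalog)) || any(names(background_catalog) == ""))
    stop("background_catalog must be a named character vector")
  parse_mutation_key(unname(background_catalog))
  unknown <- setdiff(iso$background_id, names(background_catalog))
  if (length(unknown) > 0)
    stop("well(s) reference unknown background_id: ",
         paste(unknown, collapse = ", "))
  if (!is.null(annotation)) stopifnot(inherits(annotation, "genome_annotation"))

  iso <- iso[order(iso$well_id, iso$isolate_id), , drop = FALSE]
  rownames(iso) <- NULL
  by_iso <- split(real$mutation_key, real$isolate_id)
  genotypes <- lapply(iso$isolate_id, function(id) {
    g <- by_iso[[id]]
    if (is.null(g)) character(0) else sort(unique(g))
  })
  names(genotypes) <- iso$isolate_id

  wtab <- unique(iso[, c("well_id", "background_id")])
  wells <- data.frame(
    well_id = wtab$well_id, background_id = wtab$background_id,
    n_isolates = as.integer(table(iso$well_id)[wtab$well_id]),
    stringsAsFactors = FALSE)
  wells <- wells[order(wells$well_id), , drop = FALSE]
  rownames(wells) <- NULL

  structure(
    list(isolates = iso, genotypes = genotypes, wells = wells,
         catalog = sort(unique(real$mutation_key)),
         background_catalog = background_catalog, annotation = annotation),
    class = "mut_dataset")
}

#' @export
print.mut_dataset <- function(x, ...) {
  cat("Mutation-by-isolate dataset:",
      nrow(x$wells), "wells,", nrow(x$isolates), "isolates,",
      length(x$catalog), "unique mutations,",
      length(unique(x$wells$background_id)), "backgrounds\n")
  invisible(x)
}

#' Read a mutation-by-isolate table
#'
#' Canonical dialect: UTF-8 TSV with header
#' `isolate_id  well_id  background_id  mutation_key`, one row per isolate x
#' mutation. An isolate with no de novo mutations appears once with the
#' sentinel key `"."`.
#'
#' @param path Path to the TSV file.
#' @param background_catalog Named character vector, background id to founding
#'   mutation key.
#' @param annotation Optional [genome_annotation()].
#' @return A [mut_dataset()].
#' @export
read_mutation_table <- function(path, background_catalog, annotation = NULL) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  mut_dataset(calls, background_catalog, annotation)
}

#' Write a dataset back to the canonical TSV dialect
#'
#' @param dataset A [mut_dataset()].
#' @param path Output path.
#' @return Invisibly, `dataset`.
#' @export
write_mutation_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mut_dataset"))
  rows <- lapply(seq_len(nrow(dataset$isolates)), function(i) {
    iso <- dataset$isolates[i, ]
    keys <- dataset$genotypes[[iso$isolate_id]]
    if (length(keys) == 0) keys <- "."
    data.frame(isolate_id = iso$isolate_id, well_id = iso$well_id,
               background_id = iso$background_id, mutation_key = keys,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

subset_wells <- function(dataset, keep_wells) {
  keep_iso <- dataset$isolates$well_id %in% keep_wells
  iso <- dataset$isolates[keep_iso, , drop = FALSE]
  rownames(iso) <- NULL
  genotypes <- dataset$genotypes[iso$isolate_id]
  wells <- dataset$wells[dataset$wells$well_id %in% keep_wells, , drop = FALSE]
  rownames(wells) <- NULL
  out <- dataset
  out$isolates <- iso
  out$genotypes <- genotypes
  out$wells <- wells
  out$catalog <- sort(unique(unlist(genotypes, use.names = FALSE)))
  out
}

#' Drop wells with too few sequenced isolates
#'
#' Wells with fewer than `min_isolates` successfully sequenced isolates are
#' removed to avoid strong sample-size effects; all downstream counts refer to
#' the retained wells. The operation is idempotent and `min_isolates = 1` is
#' the identity on any dataset with nonempty wells.
#'
#' @param dataset A [mut_dataset()].
#' @param min_isolates Minimum isolate count a well must have (default 4).
#' @return The filtered [mut_dataset()]; dropped well ids are recorded in the
#'   `"dropped_wells"` attribute.
#' @export
apply_well_qc <- function(dataset, min_isolates = 4) {
  stopifnot(inherits(dataset, "mut_dataset"), min_isolates >= 1)
  keep <- dataset$wells$well_id[dataset$wells$n_isolates >= min_isolates]
  out <- subset_wells(dataset, keep)
  attr(out, "dropped_wells") <- setdiff(dataset$wells$well_id, keep)
  out
}

#' Reversion key implied by a background's founding mutation
#'
#' The founding mutation fixes a derived base in the well's ancestor; a
#' reversion is the de novo back-mutation restoring the wild-type base, so its
#' key swaps the founding key's bases.
#'
#' @param background_key Mutation key(s) of founding mutations.
#' @return Character vector of reversion keys.
#' @export
reversion_key <- function(background_key) {
  p <- parse_mutation_key(background_key)
  mutation_key(p$position, p$to_base, p$from_base)
}

#' Is a key the reversion of a given background mutation?
#'
#' @param keys Character vector of mutation keys.
#' @param background_key A single founding-mutation key.
#' @return Logical vector.
#' @export
is_reversion_key <- function(keys, background_key) {
  keys %in% reversion_key(background_key)
}

# Reversion key for each well's own background, named by well_id.
well_reversion_keys <- function(dataset) {
  bg_keys <- dataset$background_catalog[dataset$wells$background_id]
  stats::setNames(reversion_key(unname(bg_keys)), dataset$wells$well_id)
}

# All reversion keys implied by the background catalog.
all_reversion_keys <- function(dataset) {
  unique(reversion_key(unname(dataset$background_catalog)))
}

#' Flag wells containing reversions
#'
#' A well is flagged when at least one of its isolates carries the
#' back-mutation restoring the wild-type base at the site of the well's own
#' founding mutation.
#'
#' @param dataset A [mut_dataset()].
#' @return Named logical vector over wells.
#' @export
classify_reversions <- function(dataset) {
  stopifnot(inherits(dataset, "mut_dataset"))
  rev_keys <- well_reversion_keys(dataset)
  out <- vapply(dataset$wells$well_id, function(w) {
    iso <- dataset$isolates$isolate_id[dataset$isolates$well_id == w]
    any(vapply(dataset$genotypes[iso],
               function(g) rev_keys[[w]] %in% g, TRUE))
  }, TRUE)
  stats::setNames(out, dataset$wells$well_id)
}

#' Union of de novo mutations observed in a well
#'
#' Parallelism between wells compares well-level mutation sets, i.e. the
#' union over the well's sequenced isolates.
#'
#' @param dataset A [mut_dataset()].
#' @param well_id A single well id.
#' @param include_reversions Keep the well's own reversion key (default TRUE)?
#' @return Sorted character vector of mutation keys.
#' @export
well_mutation_set <- function(dataset, well_id, include_reversions = TRUE) {
  stopifnot(inherits(dataset, "mut_dataset"))
  if (!well_id %in% dataset$wells$well_id) stop("unknown well: ", well_id)
  iso <- dataset$isolates$isolate_id[dataset$isolates$well_id == well_id]
  keys <- sort(unique(unlist(dataset$genotypes[iso], use.names = FALSE)))
  if (!include_reversions)
    keys <- setdiff(keys, well_reversion_keys(dataset)[[well_id]])
  keys
}

# All well sets at once (named list).
well_mutation_sets <- function(dataset, include_reversions = TRUE) {
  stats::setNames(
    lapply(dataset$wells$well_id, well_mutation_set, dataset = dataset,
           include_reversions = include_reversions),
    dataset$wells$well_id)
}

#' Count unique mutations and mutational events
#'
#' A mutational event is one occurrence of a mutation in one well, so a
#' mutation found in k wells contributes k events. Events always exceed or
#' equal unique mutations, with equality only when every mutation is private
#' to one well.
#'
#' @param dataset A [mut_dataset()] (apply QC first).
#' @param include_reversions Count each well's own reversion as an ordinary
#'   mutation (default TRUE)?
#' @return List with `unique_mutations`, `events` and `per_mutation_well_counts`
#'   (named integer vector).
#' @export
count_mutations_and_events <- function(dataset, include_reversions = TRUE) {
  sets <- well_mutation_sets(dataset, include_reversions)
  tab <- table(unlist(sets, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(unique_mutations = length(counts),
       events = sum(counts),
       per_mutation_well_counts = counts)
}

#' Flag candidate cross-well contamination
#'
#' Implements the two sequence-internal red flags for contamination: an
#' isolate (1) lacks its own well's founding mutation (i.e. carries the
#' back-mutation at that site) and (2) carries the founding mutation of a
#' different background. Forensic criteria that require cross-well haplotype
#' comparison are out of scope.
#'
#' @param dataset A [mut_dataset()].
#' @return `data.frame` with one row per well: `well_id`, `flagged`,
#'   `n_flagged_isolates`, `foreign_backgrounds` (comma-separated), and an
#'   `isolates` attribute listing the implicated isolate ids per well.
#' @export
flag_contamination <- function(dataset) {
  stopifnot(inherits(dataset, "mut_dataset"))
  rev_keys <- well_reversion_keys(dataset)
  bg_of_key <- stats::setNames(names(dataset$background_catalog),
                               unname(dataset$background_catalog))
  detail <- list()
  rows <- lapply(seq_len(nrow(dataset$wells)), function(i) {
    w <- dataset$wells$well_id[i]
    own_bg <- dataset$wells$background_id[i]
    foreign_keys <- unname(dataset$background_catalog[
      setdiff(names(dataset$background_catalog), own_bg)])
    iso <- dataset$isolates$isolate_id[dataset$isolates$well_id == w]
    hits <- vapply(iso, function(id) {
      g <- dataset$genotypes[[id]]
      (rev_keys[[w]] %in% g) && any(foreign_keys %in% g)
    }, TRUE)
    fb <- unique(unlist(lapply(iso[hits], function(id)
      bg_of_key[intersect(dataset$genotypes[[id]], foreign_keys)])))
    detail[[w]] <<- iso[hits]
    data.frame(well_id = w, flagged = any(hits),
               n_flagged_isolates = sum(hits),
               foreign_backgrounds = paste(fb, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "isolates") <- detail
  out
}
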