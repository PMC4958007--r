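#' Genome annotation for a small viral genome
#'
#' Bundles the genome length, a feature table (genes, promoters, terminators)
#' and the ancestral sequence. Coordinates are 1-based and inclusive, matching
#' mutation names such as `"1910aG"` (position 1910, ancestral `a`, derived
#' `G`). Gene intervals may overlap (overlapping reading frames are common in
#' microviruses); features may not wrap the origin.
#'
#' @param genome_length Positive integer, genome size in nucleotides.
#' @param features `data.frame` with columns `feature_id`, `class` (one of
#'   `"gene"`, `"promoter"`, `"terminator"`), `start`, `end` (1-based
#'   inclusive) and `frame_offset` (0-2; ignored for non-genes).
#' @param ancestral_seq Single character string of length `genome_length`
#'   giving the ancestral genome (case-insensitive A/C/G/T).
#' @return An object of class `genome_annotation`.
#' @seealso [read_annotation()], [synthetic_phage_annotation()],
#'   [annotate_mutation()]
#' @export
genome_annotation <- function(genome_length, features, ancestral_seq = NULL) {
  stopifnot(is.numeric(genome_length), genome_length >= 1)
  genome_length <- as.integer(genome_length)
  req <- c("feature_id", "class", "start", "end", "frame_offset")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$frame_offset <- as.integer(features$frame_offset)
  bad <- !features$class %in% c("gene", "promoter", "terminator")
  if (any(bad))
    stop("unknown feature class: ", paste(unique(features$class[bad]), collapse = ", "))
  if (any(features$start < 1 | features$end > genome_length | features$start > features$end))
    stop("feature intervals must lie within [1, genome_length] with start <= end")
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id in annotation")
  if (!is.null(ancestral_seq)) {
    ancestral_seq <- toupper(as.character(ancestral_seq))
    if (nchar(ancestral_seq) != genome_length)
      stop("ancestral_seq length (", nchar(ancestral_seq),
           ") does not match genome_length (", genome_length, ")")
  }
  structure(
    list(genome_length = genome_length, features = features,
         ancestral_seq = ancestral_seq),
    class = "genome_annotation")
}

#' Read a genome annotation from a feature TSV and a FASTA file
#'
#' The feature table is a BED-like TSV with columns
#' `feature_id, class, start, end, frame_offset` (1-based inclusive
#' coordinates). The ancestral genome is read from a single-record FASTA.
#'
#' @param features_path Path to the feature TSV.
#' @param fasta_path Optional path to the ancestral genome FASTA.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(features_path, fasta_path = NULL) {
  feats <- utils::read.delim(features_path, stringsAsFactors = FALSE)
  seq <- NULL
  len <- max(feats$end)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    if (length(ss) != 1)
      stop("expected a single-record FASTA, found ", length(ss), " records")
    seq <- as.character(ss[[1]])
    len <- nchar(seq)
  }
  genome_annotation(len, feats, seq)
}

#' Write a genome annotation to a feature TSV (and optionally a FASTA)
#'
#' @param annotation A [genome_annotation()] object.
#' @param features_path Output path for the feature TSV.
#' @param fasta_path Optional output path for the ancestral genome FASTA.
#' @return Invisibly, `annotation`.
#' @export
write_annotation <- function(annotation, features_path, fasta_path = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  utils::write.table(annotation$features, features_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    if (is.null(annotation$ancestral_seq))
      stop("annotation carries no ancestral sequence")
    ss <- Biostrings::DNAStringSet(annotation$ancestral_seq)
    names(ss) <- "ancestral"
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(annotation)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", x$genome_length, "nt;",
      nrow(x$features), "features (",
      sum(x$features$class == "gene"), "genes )\n")
  invisible(x)
}

#' Parse mutation keys of the form "1910aG"
#'
#' A mutation key concatenates the 1-based genome position, the ancestral base
#' in lower case and the derived base in upper case.
#'
#' @param keys Character vector of keys.
#' @return `data.frame` with columns `key`, `position`, `from_base`, `to_base`.
#' @export
parse_mutation_key <- function(keys) {
  ok <- grepl("^[0-9]+[acgt][ACGT]$", keys)
  if (any(!ok))
    stop("malformed mutation key(s): ", paste(utils::head(keys[!ok], 5), collapse = ", "))
  pos <- as.integer(sub("^([0-9]+).*$", "\\1", keys))
  from <- toupper(substr(keys, nchar(keys) - 1, nchar(keys) - 1))
  to <- substr(keys, nchar(keys), nchar(keys))
  if (any(from == to))
    stop("mutation key with identical ancestral and derived base: ",
         paste(keys[from == to], collapse = ", "))
  data.frame(key = keys, position = pos, from_base = from, to_base = to,
             stringsAsFactors = FALSE)
}

#' Build a mutation key from its parts
#' @param position 1-based position.
#' @param from_base Ancestral base.
#' @param to_base Derived base.
#' @return Character key, e.g. `"1910aG"`.
#' @export
mutation_key <- function(position, from_base, to_base) {
  paste0(position, tolower(from_base), toupper(to_base))
}

features_at <- function(annotation, position) {
  f <- annotation$features
  f[f$start <= position & f$end >= position, , drop = FALSE]
}

# Codon index/position of `position` within a gene row; NA when the position
# falls before the frame offset or in a trailing partial codon.
codon_of <- function(position, gene) {
  cp <- position - (gene$start + gene$frame_offset)
  if (cp < 0) return(NULL)
  idx <- cp %/% 3L
  codon_start <- gene$start + gene$frame_offset + 3L * idx
  if (codon_start + 2L > gene$end) return(NULL)
  list(codon_index = idx + 1L, codon_pos = cp %% 3L + 1L, codon_start = codon_start)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Annotate a single mutation against a genome annotation
#'
#' Finds all features overlapping the site and resolves the functional class
#' with precedence regulatory > nonsynonymous > silent. A mutation is
#' `regulatory` when the site falls in a promoter or terminator. For coding
#' sites the ancestral and mutant codons are translated in every containing
#' reading frame; the mutation is `nonsynonymous` if the amino acid changes in
#' at least one frame (relevant for overlapping genes). Sites in no feature
#' are reported `silent` with `coding = FALSE` so intergenic changes can be
#' counted separately from synonymous coding ones.
#'
#' @param position 1-based genome position.
#' @param from_base,to_base Ancestral and derived nucleotides.
#' @param annotation A [genome_annotation()] with an ancestral sequence when
#'   coding classification is required.
#' @return A list of class `mutation_record` with elements `key`, `position`,
#'   `from_base`, `to_base`, `features` (feature ids), `functional_class`,
#'   `coding`, `codons` (per-gene codon index/position) and `cluster_id`.
#' @export
annotate_mutation <- function(position, from_base, to_base, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  position <- as.integer(position)
  if (position < 1 || position > annotation$genome_length)
    stop("position ", position, " outside genome [1, ",
         annotation$genome_length, "]")
  from_base <- toupper(from_base); to_base <- toupper(to_base)
  if (from_base == to_base) stop("from_base and to_base are identical")
  hits <- features_at(annotation, position)
  regulatory <- any(hits$class %in% c("promoter", "terminator"))
  genes <- hits[hits$class == "gene", , drop = FALSE]
  codons <- list()
  nonsyn <- FALSE
  if (nrow(genes) > 0 && !is.null(annotation$ancestral_seq)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      co <- codon_of(position, g)
      if (is.null(co)) next
      anc <- substr(annotation$ancestral_seq, co$codon_start, co$codon_start + 2L)
      # trust the key's ancestral base at the mutated site itself
      substr(anc, co$codon_pos, co$codon_pos) <- from_base
      mut <- anc
      substr(mut, co$codon_pos, co$codon_pos) <- to_base
      aa_anc <- translate_codon(anc)
      aa_mut <- translate_codon(mut)
      codons[[g$feature_id]] <- list(codon_index = co$codon_index,
                                     codon_pos = co$codon_pos,
                                     aa_from = aa_anc, aa_to = aa_mut)
      if (!identical(aa_anc, aa_mut)) nonsyn <- TRUE
    }
  }
  functional_class <-
    if (regulatory) "regulatory" else if (nonsyn) "nonsynonymous" else "silent"
  rec <- list(key = mutation_key(position, from_base, to_base),
              position = position, from_base = from_base, to_base = to_base,
              features = hits$feature_id, functional_class = functional_class,
              coding = nrow(genes) > 0, codons = codons)
  rec$cluster_id <- cluster_id_of(rec, hits, genes)
  class(rec) <- "mutation_record"
  rec
}

cluster_id_of <- function(rec, hits, genes) {
  regs <- hits[hits$class %in% c("promoter", "terminator"), , drop = FALSE]
  if (nrow(regs) > 0) return(regs$feature_id[order(regs$start)][1])
  if (nrow(genes) > 0 && length(rec$codons) > 0) {
    g <- genes[order(genes$start), , drop = FALSE]
    g <- g[g$feature_id %in% names(rec$codons), , drop = FALSE]
    if (nrow(g) > 0) {
      gid <- g$feature_id[1]
      return(paste0(gid, ":", rec$codons[[gid]]$codon_index))
    }
  }
  rec$key
}

#' Annotate a catalog of mutation keys
#'
#' Vectorized wrapper around [annotate_mutation()].
#'
#' @param keys Character vector of mutation keys.
#' @param annotation A [genome_annotation()].
#' @return `data.frame` with one row per key: `key`, `position`, `from_base`,
#'   `to_base`, `functional_class`, `coding`, `cluster_id`, and a
#'   comma-separated `features` column.
#' @export
annotate_catalog <- function(keys, annotation) {
  parsed <- parse_mutation_key(keys)
  recs <- lapply(seq_len(nrow(parsed)), function(i)
    annotate_mutation(parsed$position[i], parsed$from_base[i],
                      parsed$to_base[i], annotation))
  data.frame(
    key = parsed$key, position = parsed$position,
    from_base = parsed$from_base, to_base = parsed$to_base,
    functional_class = vapply(recs, `[[`, "", "functional_class"),
    coding = vapply(recs, `[[`, TRUE, "coding"),
    cluster_id = vapply(recs, `[[`, "", "cluster_id"),
    features = vapply(recs, function(r) paste(r$features, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Cluster identity of mutations at the regulatory/codon level
#'
#' Coarsens mutation identity for the broader definition of parallel change:
#' mutations in the same promoter or terminator share that feature's id,
#' coding mutations share `"gene:codon"` for the first (leftmost) gene whose
#' reading frame contains them, and anything else is its own singleton cluster
#' (its nucleotide key).
#'
#' @param keys Character vector of mutation keys.
#' @param annotation A [genome_annotation()].
#' @return Character vector of cluster ids, named by key.
#' @export
cluster_keys <- function(keys, annotation) {
  cat <- annotate_catalog(keys, annotation)
  stats::setNames(cat$cluster_id, cat$key)
}
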