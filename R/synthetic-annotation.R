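#' Synthetic annotation for a small microvirus-like genome
#'
#' Builds a fully synthetic 5,577 nt single-stranded DNA phage genome with a
#' plausible microvirus layout: nine genes (including an overlapping D/E
#' reading-frame pair), a D-promoter at sites 1909-1935 controlling the D/E
#' transcript, and a J-terminator. The ancestral sequence is drawn once from a
#' fixed internal seed, with a handful of sites pinned to specific bases so
#' that the mutation keys used by [study_preset()] are stable. The layout
#' is an invented stand-in for a real phage annotation: coordinates other than
#' the genome length and the D-promoter interval do not correspond to any
#' sequenced genome.
#'
#' @return A [genome_annotation()] object.
#' @export
synthetic_phage_annotation <- function() {
  features <- data.frame(
    feature_id = c("geneA", "geneB", "geneC", "geneD", "geneE", "geneJ",
                   "geneF", "geneG", "geneH", "D-promoter", "J-terminator"),
    class = c(rep("gene", 9), "promoter", "terminator"),
    start = c(1L, 999L, 1540L, 1940L, 2155L, 2398L, 2600L, 3940L, 4500L,
              1909L, 2525L),
    end = c(1536L, 1361L, 1800L, 2395L, 2430L, 2520L, 3880L, 4470L, 5480L,
            1935L, 2560L),
    frame_offset = 0L,
    stringsAsFactors = FALSE)
  len <- 5577L
  bases <- c("A", "C", "G", "T")
  seq <- with_seed(5577L, sample(bases, len, replace = TRUE))
  # Pin the ancestral base at sites referenced by the calibrated preset so the
  # familiar key spellings (e.g. 1910aG) are reproducible.
  pinned <- c(`1909` = "T", `1910` = "A", `1911` = "C", `1913` = "G",
              `1920` = "A", `1928` = "C", `1935` = "G",
              `2094` = "A", `2100` = "T", `2131` = "C", `2134` = "T",
              `2158` = "A", `2332` = "A", `2397` = "A", `2534` = "G",
              `2630` = "G", `2577` = "C")
  seq[as.integer(names(pinned))] <- pinned
  genome_annotation(len, features, paste(seq, collapse = ""))
}
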