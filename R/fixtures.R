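# Packaged reference data for the two published Senna matK mini-barcodes.

#' Published matK mini-barcode primer pairs for two Senna species
#'
#' The two primer pairs developed from the matK gene to discriminate
#' *Senna obtusifolia* from its common adulterant *S. occidentalis* in
#' processed seed mixtures, with their reported amplicon and insert sizes.
#'
#' @return data frame: `pair`, `fwd_seq`, `rev_seq`, `amplicon_size`,
#'   `insert_size`.
#' @export
senna_primers <- function() {
  data.frame(
    pair = c("647F-847R", "478F-629R"),
    fwd_seq = c("GTGAATACGAATCTATCT", "GTTCAAACCCTTCGATACTG"),
    rev_seq = c("GGATTTTCCTTGATATCT", "GGAACAGGAAAAATCTTGGA"),
    amplicon_size = c(200L, 151L),
    insert_size = c(164L, 111L))
}

#' Reported ASV read counts for the Senna mini-barcode mixtures
#'
#' Per-mixture sequencing read counts of the amplicon sequence variants
#' recovered from four experimental seed mixtures (JM1-JM4) of
#' *S. obtusifolia* and *S. occidentalis*, for each of the two matK
#' mini-barcode primer pairs; every ASV matched its species' barcode region
#' at 100% identity.
#'
#' @return data frame with columns `primer_pair`, `asv`, `taxon`,
#'   `JM1`...`JM4`, `identity_pct`.
#' @export
senna_asv_counts <- function() {
  path <- system.file("extdata", "senna_asv_counts.tsv", package = "minibar")
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reported Senna ASV counts as `asv_table` objects
#'
#' Rebuilds one [dereplicate()]-style ASV table plus matching taxon
#' assignments per primer pair from [senna_asv_counts()], so the published
#' counts can be pushed through the package's reporting path
#' ([species_proportions()] etc.). The published ASV sequences themselves
#' were not deposited; short synthetic stand-in sequences label the rows
#' and carry no biological meaning.
#'
#' @return named list (one element per primer pair), each a list with
#'   `table` (an `asv_table`) and `assignments` (as from [assign_taxa()]).
#' @export
senna_asv_tables <- function() {
  counts <- senna_asv_counts()
  stand_in <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")
  out <- list()
  for (p in unique(counts$primer_pair)) {
    sub <- counts[counts$primer_pair == p, , drop = FALSE]
    seqs <- stand_in[seq_len(nrow(sub))]
    mat <- as.matrix(sub[, c("JM1", "JM2", "JM3", "JM4")])
    rownames(mat) <- NULL
    tab <- new_asv_table(seqs, mat)
    taxon_of <- setNames(sub$taxon, seqs)
    out[[p]] <- list(
      table = tab,
      assignments = data.frame(
        asv_id = rownames(tab$counts),
        taxon = unname(taxon_of[tab$sequence]),
        identity = 100, status = "species", tie = FALSE))
  }
  out
}
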