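# Global pairwise alignment (Needleman-Wunsch with affine gaps, Gotoh).

#' Alignment scoring parameters
#'
#' Affine-gap scoring: a gap of length L costs `gap_open + gap_extend * L`.
#' Defaults follow a widely used DNA global-alignment convention.
#'
#' @param match match score (default +5).
#' @param mismatch mismatch score (default -4); any column involving a
#'   non-ACGT code also scores as a mismatch.
#' @param gap_open gap opening cost (default 10, applied once per gap).
#' @param gap_extend per-base gap extension cost (default 0.5).
#' @return a list of class `align_scoring`.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = 10, gap_extend = 0.5) {
  stopifnot(match > 0, mismatch < match, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Optimal global alignment of two DNA sequences
#'
#' Needleman-Wunsch alignment with affine gap penalties (Gotoh algorithm)
#' and deterministic traceback: on ties a diagonal move is preferred, then a
#' gap in `b`, then a gap in `a`. Columns where both bases are unambiguous
#' (ACGT) and ungapped are "compared" sites; compared columns that differ
#' are "variable" sites.
#'
#' @param a,b DNA strings (IUPAC codes allowed; ambiguity codes are retained
#'   but score as mismatches and are excluded from compared sites).
#' @param scoring an [align_scoring()] object.
#' @return object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `compared_sites`, `variable_sites`.
#' @export
#' @examples
#' global_align("ACGT", "ACGT")$score
global_align <- function(a, b, scoring = align_scoring()) {
  a <- check_dna(a, "sequence a")
  b <- check_dna(b, "sequence b")
  res <- .gotoh_align(a, b, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  as_pairwise_alignment(res$aligned_a, res$aligned_b, score = res$score)
}

#' Build a pairwise alignment object from aligned strings
#'
#' Used to assemble alignments constructed by hand (e.g. in tests) or by an
#' external aligner; recomputes compared/variable site counts.
#'
#' @param aligned_a,aligned_b equal-length aligned strings with `-` gaps.
#' @param score alignment score, or `NA` if unknown.
#' @return a `pairwise_alignment` object.
#' @export
as_pairwise_alignment <- function(aligned_a, aligned_b, score = NA_real_) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  compared <- ca %in% acgt & cb %in% acgt
  variable <- compared & ca != cb
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score,
                 compared_sites = sum(compared),
                 variable_sites = sum(variable)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> length ", nchar(x$aligned_a),
      ", score ", format(x$score), "\n",
      "  compared sites: ", x$compared_sites,
      "; variable sites: ", x$variable_sites, "\n", sep = "")
  invisible(x)
}

# column-level masks used by diversity/windows/design
alignment_columns <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  list(a = ca, b = cb,
       compared = ca %in% acgt & cb %in% acgt,
       gap = ca == "-" | cb == "-")
}
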