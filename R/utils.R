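# shared low-level helpers (not exported)

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over character vectors; IUPAC ambiguity
#' codes are complemented according to their standard pairing.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

check_dna <- function(x, what = "sequence", allow_ambiguity = TRUE,
                      allow_empty = FALSE) {
  if (length(x) != 1 || is.na(x) || !is.character(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(x) && !allow_empty)
    stop(what, " must be non-empty", call. = FALSE)
  x <- toupper(x)
  pattern <- if (allow_ambiguity) "^[ACGTRYSWKMBDHVN]*$" else "^[ACGT]*$"
  if (!grepl(pattern, x)) {
    bad <- setdiff(unique(strsplit(x, "")[[1]]),
                   if (allow_ambiguity) IUPAC_DNA else c("A", "C", "G", "T"))
    stop(what, " contains invalid character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

norm_gene_name <- function(x) tolower(trimws(x))

# random DNA, ACGT uniform
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
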