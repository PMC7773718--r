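# Primer physicochemistry: GC content, nearest-neighbor melting
# temperature, hairpin and primer-dimer screens.

#' GC content of a primer
#'
#' @param seq unambiguous DNA string (ACGT).
#' @return percent G+C, rounded to 1 decimal.
#' @export
#' @examples
#' gc_content("GTTCAAACCCTTCGATACTG")  # 45.0
gc_content <- function(seq) {
  seq <- check_dna(seq, "primer", allow_ambiguity = FALSE)
  chars <- strsplit(seq, "")[[1]]
  round(100 * sum(chars %in% c("G", "C")) / length(chars), 1)
}

# unified nearest-neighbor parameters (duplex propagation, 1 M NaCl):
# dH in kcal/mol, dS in cal/(mol K)
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Thermodynamic Tm of a primer against its perfect complement using the
#' unified nearest-neighbor parameter set (terminal A/T and G/C initiation
#' terms included), with the entropic salt correction
#' `dS + 0.368 (N-1) ln[Na+]` and duplex concentration `primer_nM / 4`
#' (primer in four-fold excess convention for non-self-complementary
#' oligos).
#'
#' @param seq unambiguous DNA string, 8-50 nt.
#' @param salt_mM monovalent cation concentration in mM (default 50).
#' @param primer_nM total primer concentration in nM (default 250).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, salt_mM = 50, primer_nM = 250) {
  seq <- check_dna(seq, "primer", allow_ambiguity = FALSE)
  n <- nchar(seq)
  if (n < 8 || n > 50) stop("primer length must be in [8, 50] nt, got ", n)
  chars <- strsplit(seq, "")[[1]]
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (terminal in chars[c(1, n)]) {
    if (terminal %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)
  r_gas <- 1.987  # cal/(mol K)
  ct <- primer_nM * 1e-9
  dh * 1000 / (ds + r_gas * log(ct / 4)) - 273.15
}

#' Hairpin screen
#'
#' Detects intramolecular stem-loop structures: an antiparallel
#' Watson-Crick stem of at least `min_stem` base pairs whose loop contains
#' at least `min_loop` unpaired bases. The longest admissible stem is
#' reported regardless of the verdict.
#'
#' @param seq unambiguous DNA string.
#' @param min_stem minimum stem length in base pairs (default 4).
#' @param min_loop minimum loop length in nt (default 3).
#' @return list: `hairpin` (logical), `stem_len`, `loop_len`,
#'   `arm5_start`, `arm3_start` (0-based arm starts, -1 when no stem).
#' @export
hairpin_check <- function(seq, min_stem = 4, min_loop = 3) {
  seq <- check_dna(seq, "primer", allow_ambiguity = FALSE)
  .hairpin_scan(seq, as.integer(min_stem), as.integer(min_loop))
}

#' Primer-dimer screen
#'
#' Scans all ungapped antiparallel offsets of one primer against another
#' (use `a = b` for a self-dimer check). The pair fails if the longest
#' contiguous Watson-Crick complementary run reaches `max_run` anywhere, or
#' a run anchored at either primer's 3' terminus reaches `max_3prime_run`.
#'
#' @param a,b unambiguous DNA strings, 5' to 3'.
#' @param max_run failing run length anywhere (default 8).
#' @param max_3prime_run failing run length at a 3' end (default 4).
#' @return list: `pass` (logical), `max_run`, `max_run_3prime_a`,
#'   `max_run_3prime_b`.
#' @export
dimer_check <- function(a, b, max_run = 8, max_3prime_run = 4) {
  a <- check_dna(a, "primer a", allow_ambiguity = FALSE)
  b <- check_dna(b, "primer b", allow_ambiguity = FALSE)
  sc <- .dimer_scan(a, b)
  list(pass = sc$max_run < max_run &&
         sc$max_run_3prime_a < max_3prime_run &&
         sc$max_run_3prime_b < max_3prime_run,
       max_run = sc$max_run,
       max_run_3prime_a = sc$max_run_3prime_a,
       max_run_3prime_b = sc$max_run_3prime_b)
}
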