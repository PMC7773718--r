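# Fixtures are built in code at test time; nothing binary is shipped.

BASES <- c("A", "C", "G", "T")

random_dna <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

# substitute k positions (or given positions) with a different base
mutate_dna <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

# hand-written GenBank flat file: 120 bp, a plus-strand CDS, a minus-strand
# CDS, and a spliced (join) CDS; coordinates are 1-based inclusive
toy_genbank_text <- function(seq120) {
  stopifnot(nchar(seq120) == 120)
  c("LOCUS       TOY0001 120 bp    DNA     circular PLN",
    "ACCESSION   TOY0001",
    "SOURCE      synthetic construct",
    "  ORGANISM  Toyus exampli",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..40",
    "                     /gene=\"matK\"",
    "     CDS             complement(61..90)",
    "                     /gene=\"rbcL\"",
    "     CDS             join(95..100,103..108)",
    "                     /gene=\"ndhF\"",
    "ORIGIN",
    paste0("        1 ", tolower(paste(substring(seq120, seq(1, 51, 10), seq(10, 60, 10)), collapse = " "))),
    paste0("       61 ", tolower(paste(substring(seq120, seq(61, 111, 10), seq(70, 120, 10)), collapse = " "))),
    "//")
}

write_toy_genbank <- function(seq120 = NULL) {
  if (is.null(seq120)) seq120 <- random_dna(120)
  path <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  writeLines(toy_genbank_text(seq120), path)
  list(path = path, sequence = seq120)
}

# a mini-barcode study fixture: the two published Senna matK primer pairs
# with synthetic inserts diverged at a known number of sites
make_barcode_fixture <- function(seed, pair_index = 1, n_variable = 7) {
  pr <- senna_primers()[pair_index, ]
  set.seed(seed)
  ins_a <- random_dna(pr$insert_size)
  ins_b <- mutate_dna(ins_a, sample(pr$insert_size, n_variable))
  amp <- setNames(paste0(pr$fwd_seq, c(ins_a, ins_b), revcomp(pr$rev_seq)),
                  c("obtusifolia", "occidentalis"))
  refs <- setNames(c(ins_a, ins_b), c("obtusifolia", "occidentalis"))
  list(pair = pr, inserts = refs, amplicons = amp)
}

four_mixture_scheme <- function() {
  tag_scheme(data.frame(
    sample = paste0("JM", 1:4),
    fwd_tag = c("ACGTACCA", "TGCATGCA", "CAGTCAGT", "GTACGTAC"),
    rev_tag = c("TTGACCGT", "AACTGGCA", "GGTACTGA", "CCATGACT")))
}

four_mixture_proportions <- function() {
  list(JM1 = c(obtusifolia = 0.05, occidentalis = 0.95),
       JM2 = c(obtusifolia = 0.35, occidentalis = 0.65),
       JM3 = c(obtusifolia = 0.65, occidentalis = 0.35),
       JM4 = c(obtusifolia = 0.95, occidentalis = 0.05))
}

# simulate the four-mixture study and quantify it end to end
run_four_mixture_study <- function(seed, n_reads = 20000, error_rate = 0.002) {
  fx <- make_barcode_fixture(seed)
  scheme <- four_mixture_scheme()
  props <- four_mixture_proportions()
  reads <- list()
  for (m in seq_along(props)) {
    cfg <- simulation_config(seed = seed + m, proportions = props[[m]],
                             n_reads = n_reads, error_rate = error_rate)
    reads[[m]] <- simulate_mixture_reads(fx$amplicons, names(props)[m],
                                         scheme, cfg)$pairs
  }
  biomass <- do.call(rbind, lapply(names(props), function(s)
    data.frame(sample = s, taxon = names(props[[s]]),
               proportion = unname(props[[s]]))))
  res <- run_quantification(do.call(rbind, reads), scheme, fx$pair,
                            fx$inserts, biomass = biomass)
  list(result = res, truth = biomass, fixture = fx)
}
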