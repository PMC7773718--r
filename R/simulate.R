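# Seeded generators: diverged genome pairs and tagged amplicon mixtures
# with known ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package targets: a pair of
#' plastome-like genomes whose coding genes differ only by substitutions,
#' and dual-tagged 2 x 150 bp mixture libraries.
#'
#' @param seed integer seed; generation is a pure function of the config.
#' @param gene_count number of coding genes per genome (default 8).
#' @param gene_length gene length in bp (default 900).
#' @param divergence per-site substitution probability outside the
#'   conserved flanks; scalar or one value per gene (default 0.02).
#' @param conserved_flank bases kept identical at each gene end
#'   (default 60).
#' @param proportions named taxon proportions summing to 1
#'   (default 0.5/0.5).
#' @param n_reads read pairs per mixture (default 20000).
#' @param error_rate uniform per-base substitution error rate in reads
#'   (default 0.002).
#' @param read_len read length in bp (default 150).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed, gene_count = 8, gene_length = 900,
                              divergence = 0.02, conserved_flank = 60,
                              proportions = c(taxon_a = 0.5, taxon_b = 0.5),
                              n_reads = 20000, error_rate = 0.002,
                              read_len = 150) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (any(divergence < 0 | divergence > 1))
    stop("divergence must be in [0, 1]")
  if (!length(divergence) %in% c(1L, gene_count))
    stop("divergence must be scalar or one value per gene")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (is.null(names(proportions))) stop("proportions must be named by taxon")
  if (n_reads <= 0) stop("n_reads must be positive")
  if (2 * conserved_flank >= gene_length)
    stop("conserved flanks exceed gene length")
  structure(list(seed = as.integer(seed), gene_count = gene_count,
                 gene_length = gene_length, divergence = divergence,
                 conserved_flank = conserved_flank, proportions = proportions,
                 n_reads = n_reads, error_rate = error_rate,
                 read_len = read_len),
            class = "simulation_config")
}

#' Simulate a diverged genome pair with known ground truth
#'
#' Genome A carries `gene_count` random coding genes separated by spacers;
#' genome B is derived by substituting each non-flank gene position
#' independently with probability `divergence` (per-gene when a vector),
#' keeping `conserved_flank` bases identical at each gene end. Genes
#' alternate between the plus and minus strand and are annotated as CDS
#' features, so the pair exercises strand handling downstream.
#'
#' @param config a [simulation_config()].
#' @return list: `genome_a`, `genome_b` ([genome_record()]s) and `truth`
#'   (per-gene 0-based variable positions in coding orientation, plus the
#'   flank width and divergence used).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  d <- rep(config$divergence, length.out = config$gene_count)
  gl <- config$gene_length; fl <- config$conserved_flank
  spacer_len <- 120
  genes_a <- character(config$gene_count)
  genes_b <- character(config$gene_count)
  var_sites <- vector("list", config$gene_count)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(config$gene_count)) {
    ga <- sample(bases, gl, replace = TRUE)
    gb <- ga
    core <- (fl + 1):(gl - fl)
    hit <- core[runif(length(core)) < d[i]]
    for (p in hit) gb[p] <- sample(setdiff(bases, ga[p]), 1)
    genes_a[i] <- paste(ga, collapse = "")
    genes_b[i] <- paste(gb, collapse = "")
    var_sites[[i]] <- hit - 1L
  }
  gene_names <- sprintf("g%02d", seq_len(config$gene_count))
  names(var_sites) <- gene_names
  strands <- rep(c("+", "-"), length.out = config$gene_count)

  # spacers are shared between the two genomes: only gene bodies diverge,
  # so divergence 0 yields byte-identical genomes
  spacers <- vapply(seq_len(config$gene_count + 1L), function(i)
    rand_dna(spacer_len), "")
  assemble <- function(genes, accession, organism) {
    parts <- character(0); feats <- list(); pos <- 0L
    for (i in seq_along(genes)) {
      parts <- c(parts, spacers[i]); pos <- pos + spacer_len
      gseq <- if (strands[i] == "+") genes[i] else revcomp(genes[i])
      parts <- c(parts, gseq)
      feats[[i]] <- data.frame(feature_id = i, gene = gene_names[i],
                               kind = "CDS", start = pos, end = pos + gl,
                               strand = strands[i])
      pos <- pos + gl
    }
    parts <- c(parts, spacers[config$gene_count + 1L])
    genome_record(accession, paste(parts, collapse = ""),
                  do.call(rbind, feats), organism)
  }
  genome_a <- assemble(genes_a, "SIMA000001", "Synthetica alpha")
  genome_b <- assemble(genes_b, "SIMB000001", "Synthetica beta")
  list(genome_a = genome_a, genome_b = genome_b,
       truth = list(variable_sites = var_sites,
                    conserved_flank = fl, divergence = d))
}

#' Simulate tagged paired-end mixture reads
#'
#' Each read pair is drawn from taxon `t` with probability
#' `config$proportions[t]`. Mate 1 is the sample's forward tag followed by
#' the amplicon prefix (forward primer included); mate 2 is the reverse tag
#' followed by the reverse complement of the amplicon suffix. Every base
#' (tags included) is substituted by a uniformly chosen other base with
#' probability `error_rate`; qualities are constant at the Phred value
#' implied by the error rate (Q40 when zero).
#'
#' @param refs named character vector: taxon -> full amplicon sequence
#'   (primer footprints included). Names must match
#'   `names(config$proportions)`.
#' @param sample_id sample to simulate; must be present in `scheme`.
#' @param scheme a [tag_scheme()].
#' @param config a [simulation_config()].
#' @param seed seed override; defaults to `config$seed` (pass distinct
#'   seeds to generate several mixtures from one config).
#' @return list: `pairs` (read-pair data frame) and `truth` (per-taxon
#'   read counts and the true proportions).
#' @export
simulate_mixture_reads <- function(refs, sample_id, scheme, config,
                                   seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  scheme <- tag_scheme(scheme)
  if (!sample_id %in% scheme$sample) stop("unknown sample: ", sample_id)
  if (!setequal(names(refs), names(config$proportions)))
    stop("refs and proportions must name the same taxa")
  set.seed(seed)
  tagL <- nchar(scheme$fwd_tag[1])
  take <- config$read_len - tagL
  if (any(nchar(refs) < take))
    stop("amplicons shorter than read_len - tag length cannot be simulated")
  row <- scheme[scheme$sample == sample_id, ]
  taxa <- names(config$proportions)
  assignment <- sample(taxa, config$n_reads, replace = TRUE,
                       prob = config$proportions)
  r1_tpl <- setNames(paste0(row$fwd_tag, substr(refs[taxa], 1, take)), taxa)
  r2_tpl <- setNames(paste0(row$rev_tag, substr(revcomp(refs[taxa]), 1, take)), taxa)
  seq1 <- unname(r1_tpl[assignment])
  seq2 <- unname(r2_tpl[assignment])
  if (config$error_rate > 0) {
    seq1 <- sprinkle_errors(seq1, config$error_rate)
    seq2 <- sprinkle_errors(seq2, config$error_rate)
  }
  q <- if (config$error_rate == 0) 40L else
    min(40L, as.integer(round(-10 * log10(config$error_rate))))
  qual <- strrep(rawToChar(as.raw(33L + q)), config$read_len)
  pairs <- data.frame(
    id = sprintf("%s_r%06d", sample_id, seq_len(config$n_reads)),
    seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual)
  list(pairs = pairs,
       truth = list(counts = table(factor(assignment, levels = taxa)),
                    proportions = config$proportions))
}

# uniform substitution errors: each base replaced by one of the other three
sprinkle_errors <- function(reads, rate) {
  L <- nchar(reads[1])
  k <- rbinom(length(reads), L, rate)
  idx <- which(k > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(L, k[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}
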