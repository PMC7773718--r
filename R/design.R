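# Mini-barcode primer-pair enumeration, in-silico PCR, and the end-to-end
# design pipeline.

#' Primer design constraints
#'
#' @param product_size amplicon size range in bp (default c(150, 300)).
#' @param primer_size primer length range in nt (default c(18, 30)).
#' @param tm melting temperature range in Celsius (default c(40, 70)).
#' @param gc GC content range in percent (default c(30, 70)).
#' @param max_pcr_mismatch substitution tolerance used when validating
#'   candidates by [in_silico_pcr()] (default 2).
#' @return a list of class `design_constraints`.
#' @export
design_constraints <- function(product_size = c(150, 300),
                               primer_size = c(18, 30),
                               tm = c(40, 70), gc = c(30, 70),
                               max_pcr_mismatch = 2) {
  for (rng in list(product_size, primer_size, tm, gc)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("constraint ranges must be positive c(min, max) with min <= max")
  }
  structure(list(product_size = product_size, primer_size = primer_size,
                 tm = tm, gc = gc, max_pcr_mismatch = max_pcr_mismatch),
            class = "design_constraints")
}

# screen a vector of candidate primer sequences; returns logical + metrics
screen_primers <- function(seqs, constraints) {
  n <- nchar(seqs)
  gc <- round(100 * (n - nchar(gsub("[GC]", "", seqs))) / n, 1)
  tm <- vapply(seqs, melting_temperature, 0, USE.NAMES = FALSE)
  ok <- gc >= constraints$gc[1] & gc <= constraints$gc[2] &
    tm >= constraints$tm[1] & tm <= constraints$tm[2]
  hp <- rep(FALSE, length(seqs))
  sd_ok <- rep(FALSE, length(seqs))
  idx <- which(ok)
  for (i in idx) {
    hp[i] <- .hairpin_scan(seqs[i], 4L, 3L)$hairpin
    if (!hp[i]) {
      sc <- .dimer_scan(seqs[i], seqs[i])
      sd_ok[i] <- sc$max_run < 8 && sc$max_run_3prime_a < 4 && sc$max_run_3prime_b < 4
    }
  }
  list(ok = ok & !hp & sd_ok, gc = gc, tm = tm,
       n_gc_tm_fail = sum(!ok), n_hairpin = sum(hp[idx]),
       n_self_dimer = sum(ok & !hp & !sd_ok))
}

#' Enumerate mini-barcode primer pairs on a pairwise alignment
#'
#' Primers are drawn exclusively from conserved blocks (alignment columns
#' identical, unambiguous and gap-free across both taxa) of the reference
#' (first) sequence; the reverse primer is the reverse complement of its
#' template footprint. Every returned pair satisfies the length, Tm, GC and
#' product-size constraints, passes the hairpin and dimer screens (self and
#' cross), and brackets at least one variable site. Pairs are ranked by
#' insert variable-site count (descending), then insert length (ascending),
#' then template coordinate.
#'
#' Cross-dimer screening walks the ranked pair list and stops after
#' `max_pairs` survivors; set `max_pairs = Inf` for a complete enumeration.
#'
#' @param alignment a `pairwise_alignment` of one candidate gene from two
#'   taxa (see [global_align()]).
#' @param constraints a [design_constraints()] object.
#' @param max_pairs maximum number of pairs returned (default 100).
#' @return data frame with one row per pair: `name`, `fwd_seq`, `rev_seq`,
#'   `fwd_start`, `rev_end` (0-based half-open on the reference template),
#'   `product_size`, `insert_len`, `insert_variable_sites`, `tm_f`, `tm_r`,
#'   `gc_f`, `gc_r`. Zero rows (with a `rejections` attribute naming the
#'   eliminating constraints) when nothing survives.
#' @export
enumerate_primer_pairs <- function(alignment, constraints = design_constraints(),
                                   max_pairs = 100) {
  cols <- alignment_columns(alignment)
  conserved <- cols$compared & cols$a == cols$b
  pos_a <- cumsum(cols$a != "-") - 1L  # template coordinate of each column
  template <- gsub("-", "", alignment$aligned_a)
  varpos <- sort(pos_a[cols$compared & cols$a != cols$b])

  empty <- data.frame(name = character(0), fwd_seq = character(0),
                      rev_seq = character(0), fwd_start = integer(0),
                      rev_end = integer(0), product_size = integer(0),
                      insert_len = integer(0), insert_variable_sites = integer(0),
                      tm_f = numeric(0), tm_r = numeric(0),
                      gc_f = numeric(0), gc_r = numeric(0))
  rej <- c()
  if (length(varpos) == 0) {
    attr(empty, "rejections") <- c(no_variable_sites = 1L)
    return(empty)
  }

  pmin_ <- constraints$primer_size[1]; pmax_ <- constraints$primer_size[2]
  r <- rle(conserved)
  run_end_col <- cumsum(r$lengths)
  run_start_col <- run_end_col - r$lengths + 1L
  runs <- which(r$values & r$lengths >= pmin_)
  if (length(runs) == 0) {
    attr(empty, "rejections") <- c(no_conserved_block = 1L)
    return(empty)
  }

  starts <- integer(0); lens <- integer(0)
  for (k in runs) {
    tstart <- pos_a[run_start_col[k]]
    rlen <- r$lengths[k]
    for (len in pmin_:min(pmax_, rlen)) {
      s <- tstart + 0:(rlen - len)
      starts <- c(starts, s); lens <- c(lens, rep(len, length(s)))
    }
  }
  wseq <- substring(template, starts + 1L, starts + lens)

  fwd <- screen_primers(wseq, constraints)
  rseq <- revcomp(wseq)
  rev_ <- screen_primers(rseq, constraints)

  fidx <- which(fwd$ok); ridx <- which(rev_$ok)
  if (length(fidx) == 0 || length(ridx) == 0) {
    attr(empty, "rejections") <-
      c(gc_or_tm = fwd$n_gc_tm_fail, hairpin = fwd$n_hairpin,
        self_dimer = fwd$n_self_dimer, no_surviving_primer = 1L)
    return(empty)
  }

  fs <- starts[fidx]; fl <- lens[fidx]
  rs <- starts[ridx]; rl <- lens[ridx]
  re_ <- rs + rl
  ord_r <- order(re_)
  re_s <- re_[ord_r]

  pr_min <- constraints$product_size[1]; pr_max <- constraints$product_size[2]
  acc_f <- vector("list", length(fs)); acc_r <- vector("list", length(fs))
  for (i in seq_along(fs)) {
    lo <- findInterval(fs[i] + pr_min - 1L, re_s) + 1L
    hi <- findInterval(fs[i] + pr_max, re_s)
    if (hi >= lo) {
      js <- ord_r[lo:hi]
      js <- js[rs[js] >= fs[i] + fl[i] + 1L]  # footprints must not touch
      acc_f[[i]] <- rep(i, length(js)); acc_r[[i]] <- js
    }
  }
  pi_f <- unlist(acc_f); pi_r <- unlist(acc_r)
  if (length(pi_f) == 0) {
    attr(empty, "rejections") <- c(product_size_infeasible = 1L)
    return(empty)
  }

  ins_lo <- fs[pi_f] + fl[pi_f]; ins_hi <- rs[pi_r]
  nvar <- findInterval(ins_hi - 1L + 0.5, varpos) - findInterval(ins_lo - 0.5, varpos)
  keep <- nvar >= 1
  if (!any(keep)) {
    attr(empty, "rejections") <- c(no_insert_variable_site = sum(!keep))
    return(empty)
  }
  pi_f <- pi_f[keep]; pi_r <- pi_r[keep]; nvar <- nvar[keep]
  insert_len <- rs[pi_r] - (fs[pi_f] + fl[pi_f])
  ord <- order(-nvar, insert_len, fs[pi_f], rs[pi_r] + rl[pi_r])

  out <- list(); taken <- 0L
  for (t in ord) {
    i <- pi_f[t]; j <- pi_r[t]
    cd <- .dimer_scan(wseq[fidx[i]], rseq[ridx[j]])
    if (cd$max_run >= 8 || cd$max_run_3prime_a >= 4 || cd$max_run_3prime_b >= 4) next
    taken <- taken + 1L
    out[[taken]] <- data.frame(
      name = paste0(fs[i] + 1L, "F-", rs[j] + rl[j], "R"),
      fwd_seq = wseq[fidx[i]], rev_seq = rseq[ridx[j]],
      fwd_start = fs[i], rev_end = rs[j] + rl[j],
      product_size = rs[j] + rl[j] - fs[i],
      insert_len = insert_len[t], insert_variable_sites = nvar[t],
      tm_f = fwd$tm[fidx[i]], tm_r = rev_$tm[ridx[j]],
      gc_f = fwd$gc[fidx[i]], gc_r = rev_$gc[ridx[j]])
    if (taken >= max_pairs) break
  }
  if (taken == 0L) {
    attr(empty, "rejections") <- c(cross_dimer = length(ord))
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' In-silico PCR
#'
#' Locates every site on both strands of the template where either primer
#' anneals with at most `max_mismatch` substitutions and an exactly
#' matching 3'-terminal trinucleotide, then emits every plus-oriented /
#' minus-oriented site combination whose product (both primer footprints
#' included) is at most `max_product` bp.
#'
#' @param pair primer pair: a list with elements `fwd` and `rev` (5'->3'
#'   sequences, optionally `name`), or a one-row data frame with `fwd_seq`
#'   and `rev_seq` columns as returned by [enumerate_primer_pairs()].
#' @param genome a [genome_record()] (or a plain DNA string).
#' @param max_mismatch substitution tolerance per primer (default 2).
#' @param max_product maximum product span in bp (default 2000).
#' @return data frame with one row per amplicon: `accession`, `start`,
#'   `end` (0-based half-open), `strand`, `fwd_primer`, `rev_primer`,
#'   `size`, `full_sequence`, `insert_sequence`, `fwd_mismatches`,
#'   `rev_mismatches`. Zero rows when nothing amplifies.
#' @export
in_silico_pcr <- function(pair, genome, max_mismatch = 2, max_product = 2000) {
  pr <- normalize_pair(pair)
  tmpl <- if (inherits(genome, "genome_record")) genome$sequence else
    check_dna(genome, "template")
  acc <- if (inherits(genome, "genome_record")) genome$accession else NA_character_

  plus <- list(); minus <- list()
  for (nm in c("fwd", "rev")) {
    p <- pr[[nm]]
    hits <- .scan_primer_sites(tmpl, p, as.integer(max_mismatch), TRUE)
    if (length(hits$start))
      plus[[nm]] <- data.frame(primer = nm, start = hits$start,
                               len = nchar(p), mm = hits$mismatches)
    hits <- .scan_primer_sites(tmpl, revcomp(p), as.integer(max_mismatch), FALSE)
    if (length(hits$start))
      minus[[nm]] <- data.frame(primer = nm, start = hits$start,
                                len = nchar(p), mm = hits$mismatches)
  }
  empty <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      fwd_primer = character(0), rev_primer = character(0),
                      size = integer(0), full_sequence = character(0),
                      insert_sequence = character(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0))
  if (length(plus) == 0 || length(minus) == 0) return(empty)
  plus <- do.call(rbind, plus); minus <- do.call(rbind, minus)

  rows <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      a0 <- plus$start[i]; a1 <- a0 + plus$len[i]
      b0 <- minus$start[j]; b1 <- b0 + minus$len[j]
      if (b0 < a1) next                    # footprints must not overlap
      if (b1 - a0 > max_product) next
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, start = a0, end = b1, strand = "+",
        fwd_primer = plus$primer[i], rev_primer = minus$primer[j],
        size = b1 - a0,
        full_sequence = substr(tmpl, a0 + 1L, b1),
        insert_sequence = if (b0 > a1) substr(tmpl, a1 + 1L, b0) else "",
        fwd_mismatches = plus$mm[i], rev_mismatches = minus$mm[j])
    }
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res[order(res$start, res$end), , drop = FALSE]
}

normalize_pair <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1)
    return(list(fwd = check_dna(pair$fwd_seq, "forward primer", allow_ambiguity = FALSE),
                rev = check_dna(pair$rev_seq, "reverse primer", allow_ambiguity = FALSE),
                name = pair$name %||% "pair"))
  }
  list(fwd = check_dna(pair$fwd, "forward primer", allow_ambiguity = FALSE),
       rev = check_dna(pair$rev, "reverse primer", allow_ambiguity = FALSE),
       name = pair$name %||% "pair")
}

#' Count variable sites among per-taxon amplicon inserts
#'
#' Globally aligns the insert sequences (primer footprints excluded) and
#' counts differing compared columns. Two inserts are aligned directly; for
#' more, a star alignment against the first insert is built by threading
#' the pairwise alignments.
#'
#' @param inserts named character vector of insert sequences, one per taxon.
#' @param scoring an [align_scoring()] object.
#' @return integer count of variable compared columns.
#' @export
count_variable_sites <- function(inserts, scoring = align_scoring()) {
  if (length(inserts) < 2) stop("need inserts from >= 2 taxa")
  if (is.null(names(inserts))) names(inserts) <- paste0("taxon", seq_along(inserts))
  bad <- names(inserts)[is.na(inserts) | !nzchar(inserts)]
  if (length(bad)) stop("missing amplicon insert for taxon: ",
                        paste(bad, collapse = ", "))
  if (length(inserts) == 2) {
    aln <- global_align(inserts[[1]], inserts[[2]], scoring)
    return(aln$variable_sites)
  }
  msa <- star_msa(unname(inserts), scoring)
  m <- do.call(rbind, strsplit(msa, ""))
  acgt <- c("A", "C", "G", "T")
  compared <- apply(m, 2, function(col) all(col %in% acgt))
  sum(apply(m[, compared, drop = FALSE], 2, function(col) length(unique(col)) > 1))
}

# star multiple alignment: thread pairwise alignments onto the first sequence
star_msa <- function(seqs, scoring = align_scoring()) {
  ref <- seqs[[1]]
  nref <- nchar(ref)
  alns <- lapply(seqs[-1], function(s) global_align(ref, s, scoring))
  # ins[[k]][p+1]: bases of s aligned to gaps in ref before ref base p (0-based),
  # position nref records trailing insertions
  parse_one <- function(aln) {
    ra <- strsplit(aln$aligned_a, "")[[1]]
    sa <- strsplit(aln$aligned_b, "")[[1]]
    ins <- vector("list", nref + 1L); chunk <- character(0)
    aligned <- character(nref)  # char of s aligned to each ref base
    p <- 0L
    for (k in seq_along(ra)) {
      if (ra[k] == "-") chunk <- c(chunk, sa[k])
      else {
        ins[[p + 1L]] <- chunk; chunk <- character(0)
        p <- p + 1L; aligned[p] <- sa[k]
      }
    }
    ins[[nref + 1L]] <- chunk
    list(ins = vapply(ins, function(x) length(x %||% character(0)), 0L),
         ins_chars = ins, aligned = aligned)
  }
  parsed <- lapply(alns, parse_one)
  master <- Reduce(pmax, lapply(parsed, `[[`, "ins"), rep(0L, nref + 1L))
  pad <- function(chars, width) {
    chars <- chars %||% character(0)
    paste(c(chars, rep("-", width - length(chars))), collapse = "")
  }
  refc <- strsplit(ref, "")[[1]]
  build <- function(ins_chars, aligned) {
    parts <- character(0)
    for (p in 0:(nref - 1L)) {
      parts <- c(parts, pad(ins_chars[[p + 1L]], master[p + 1L]), aligned[p + 1L])
    }
    c(parts, pad(ins_chars[[nref + 1L]], master[nref + 1L]))
  }
  ref_row <- build(vector("list", nref + 1L), refc)
  rows <- c(paste(ref_row, collapse = ""),
            vapply(parsed, function(pp)
              paste(build(pp$ins_chars, pp$aligned), collapse = ""), ""))
  rows
}

#' Design taxon-specific mini-barcodes from two genomes
#'
#' End-to-end pipeline: shared coding genes are ranked by nucleotide
#' diversity; for each of the `top_genes` most variable genes, primer pairs
#' are enumerated on conserved flanks ([enumerate_primer_pairs()]) and
#' validated by [in_silico_pcr()] against both genomes. A candidate is kept
#' only if it amplifies exactly one product from each genome ("specific");
#' its insert variable sites are then counted from the realized amplicons.
#' Candidates are ranked by insert variable-site count (descending), then
#' mean insert length (ascending), then gene name.
#'
#' @param genome_a,genome_b [genome_record()] objects with CDS features.
#' @param constraints a [design_constraints()] object.
#' @param top_genes number of top-diversity genes to try (default 4).
#' @param scoring an [align_scoring()] object.
#' @param max_pairs_per_gene primer pairs carried into in-silico PCR per
#'   gene (default 25).
#' @return data frame of barcode candidates: `rank`, `gene`, `name`,
#'   `fwd_seq`, `rev_seq`, `tm_f`, `tm_r`, `gc_f`, `gc_r`, `size_a`,
#'   `size_b`, `insert_variable_sites`. Zero rows (with a `rejections`
#'   attribute) when no candidate survives.
#' @export
design_minibarcodes <- function(genome_a, genome_b,
                                constraints = design_constraints(),
                                top_genes = 4, scoring = align_scoring(),
                                max_pairs_per_gene = 25) {
  empty <- data.frame(rank = integer(0), gene = character(0),
                      name = character(0), fwd_seq = character(0),
                      rev_seq = character(0), tm_f = numeric(0),
                      tm_r = numeric(0), gc_f = numeric(0), gc_r = numeric(0),
                      size_a = integer(0), size_b = integer(0),
                      insert_variable_sites = integer(0))
  tab <- shared_gene_table(genome_a, genome_b)
  if (nrow(tab) == 0) {
    attr(empty, "rejections") <- data.frame(gene = NA, reason = "no shared genes")
    return(empty)
  }
  ranks <- rank_gene_diversity(tab, scoring)
  cand_genes <- head(ranks$gene[!is.na(ranks$pi) & ranks$pi > 0], top_genes)
  rejections <- list(); rows <- list()
  for (g in cand_genes) {
    i <- match(norm_gene_name(g), norm_gene_name(tab$gene))
    aln <- global_align(tab$seq_a[i], tab$seq_b[i], scoring)
    pairs <- enumerate_primer_pairs(aln, constraints, max_pairs = max_pairs_per_gene)
    if (nrow(pairs) == 0) {
      rejections[[g]] <- data.frame(gene = g, reason = paste(
        names(attr(pairs, "rejections")), collapse = ";"))
      next
    }
    for (k in seq_len(nrow(pairs))) {
      amp_a <- in_silico_pcr(pairs[k, ], genome_a, constraints$max_pcr_mismatch)
      amp_b <- in_silico_pcr(pairs[k, ], genome_b, constraints$max_pcr_mismatch)
      if (nrow(amp_a) != 1 || nrow(amp_b) != 1) {
        rejections[[paste(g, pairs$name[k])]] <-
          data.frame(gene = g, reason = "not a unique amplicon in every genome")
        next
      }
      nv <- if (nzchar(amp_a$insert_sequence) && nzchar(amp_b$insert_sequence))
        count_variable_sites(
          c(a = amp_a$insert_sequence, b = amp_b$insert_sequence), scoring) else 0L
      if (nv < 1) {
        rejections[[paste(g, pairs$name[k])]] <-
          data.frame(gene = g, reason = "no variable site in realized insert")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, name = pairs$name[k],
        fwd_seq = pairs$fwd_seq[k], rev_seq = pairs$rev_seq[k],
        tm_f = pairs$tm_f[k], tm_r = pairs$tm_r[k],
        gc_f = pairs$gc_f[k], gc_r = pairs$gc_r[k],
        size_a = amp_a$size, size_b = amp_b$size,
        insert_len = nchar(amp_a$insert_sequence),
        insert_variable_sites = nv)
    }
  }
  if (length(rows) == 0) {
    attr(empty, "rejections") <-
      if (length(rejections)) do.call(rbind, unname(rejections)) else
        data.frame(gene = if (length(cand_genes)) cand_genes else NA_character_,
                   reason = if (length(cand_genes)) "no candidate" else
                     "no gene with pi > 0")
    return(empty)
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$insert_variable_sites, res$insert_len,
                   norm_gene_name(res$gene), res$name), , drop = FALSE]
  res$insert_len <- NULL
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  if (length(rejections))
    attr(res, "rejections") <- do.call(rbind, unname(rejections))
  res
}

#' Write a candidate report / primers FASTA
#'
#' @param candidates result of [design_minibarcodes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_report
#' @export
write_primers_fasta <- function(candidates, path) {
  seqs <- c(rbind(candidates$fwd_seq, candidates$rev_seq))
  nms <- c(rbind(paste0(candidates$gene, "_", candidates$name, "_F"),
                 paste0(candidates$gene, "_", candidates$name, "_R")))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
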