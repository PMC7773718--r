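# Tagged paired-end amplicon reads -> ASV tables -> taxon assignment ->
# species proportions and reads-vs-biomass regression.

#' Tag scheme (sample -> dual tags)
#'
#' @param x data frame with columns `sample`, `fwd_tag`, `rev_tag`, or a
#'   path to a TSV file with those columns.
#' @return validated data frame of class `tag_scheme`.
#' @export
tag_scheme <- function(x) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  needed <- c("sample", "fwd_tag", "rev_tag")
  if (!all(needed %in% names(df)))
    stop("tag scheme needs columns: ", paste(needed, collapse = ", "))
  df$fwd_tag <- toupper(df$fwd_tag); df$rev_tag <- toupper(df$rev_tag)
  lens <- unique(c(nchar(df$fwd_tag), nchar(df$rev_tag)))
  if (length(lens) != 1) stop("all tags must have one common length")
  if (lens < 6) stop("tag length must be >= 6 nt")
  if (anyDuplicated(df$sample)) stop("duplicate sample id in tag scheme")
  if (anyDuplicated(paste(df$fwd_tag, df$rev_tag)))
    stop("duplicate (forward, reverse) tag pair in tag scheme")
  structure(df, class = c("tag_scheme", "data.frame"))
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param fastq1,fastq2 paths to mate-1 and mate-2 FASTQ (Phred+33; gz
#'   accepted).
#' @return data frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  read_one <- function(path) {
    # Biostrings warns that FASTQ metadata columns are dropped; irrelevant here
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  r1 <- read_one(fastq1)
  r2 <- read_one(fastq2)
  if (length(r1) != length(r2))
    stop("mate files differ in read count (", length(r1), " vs ", length(r2), ")")
  data.frame(
    id = sub("[/ ].*$", "", names(r1)),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
    row.names = NULL)
}

#' Write a read-pair table as paired FASTQ
#'
#' @param pairs read-pair data frame (see [read_fastq_pairs()]).
#' @param fastq1,fastq2 output paths.
#' @return invisibly, `c(fastq1, fastq2)`.
#' @export
write_fastq_pairs <- function(pairs, fastq1, fastq2) {
  for (mate in 1:2) {
    set <- Biostrings::DNAStringSet(pairs[[paste0("seq", mate)]])
    names(set) <- paste0(pairs$id, "/", mate)
    Biostrings::writeXStringSet(set, if (mate == 1) fastq1 else fastq2,
                                format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  pairs[[paste0("qual", mate)]]))
  }
  invisible(c(fastq1, fastq2))
}

#' Demultiplex dual-tagged read pairs
#'
#' A pair is assigned to a sample only if mate 1 begins with the sample's
#' forward tag and mate 2 with its reverse tag, both matched exactly. Any
#' other combination -- including a valid forward tag of one sample paired
#' with a valid reverse tag of another (a tag jump) -- goes to the
#' unassigned set. Tags are removed from assigned reads.
#'
#' @param pairs read-pair data frame.
#' @param scheme a [tag_scheme()].
#' @return list with `samples` (named list of de-tagged read-pair data
#'   frames, one per scheme sample), `unassigned` (read-pair data frame)
#'   and `counts` (per-sample assigned counts).
#' @export
demultiplex <- function(pairs, scheme) {
  scheme <- tag_scheme(scheme)
  L <- nchar(scheme$fwd_tag[1])
  key <- paste(substr(pairs$seq1, 1, L), substr(pairs$seq2, 1, L))
  skey <- paste(scheme$fwd_tag, scheme$rev_tag)
  hit <- match(key, skey)
  samples <- setNames(vector("list", nrow(scheme)), scheme$sample)
  for (i in seq_len(nrow(scheme))) {
    sub <- pairs[which(hit == i), , drop = FALSE]
    sub$seq1 <- substring(sub$seq1, L + 1); sub$qual1 <- substring(sub$qual1, L + 1)
    sub$seq2 <- substring(sub$seq2, L + 1); sub$qual2 <- substring(sub$qual2, L + 1)
    rownames(sub) <- NULL
    samples[[i]] <- sub
  }
  unassigned <- pairs[is.na(hit), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(samples = samples, unassigned = unassigned,
       counts = setNames(tabulate(hit, nbins = nrow(scheme)), scheme$sample))
}

#' Merge overlapping read pairs
#'
#' Mate 2 is reverse-complemented, then the overlap maximizing the number
#' of matching bases is chosen among overlaps of at least `min_overlap`
#' bases with mismatch fraction at most `max_mismatch_frac` (ties go to the
#' longer overlap). At disagreeing positions the higher-quality base wins
#' (mate 1 on quality ties); merged length is `len1 + len2 - overlap`.
#'
#' @param pairs read-pair data frame.
#' @param min_overlap minimum admissible overlap (default 20).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return list with `merged` (data frame `id`, `sequence`, `quality`,
#'   `overlap`) and `rejected` (data frame `id`, `reason`).
#' @export
merge_pairs <- function(pairs, min_overlap = 20, max_mismatch_frac = 0.1) {
  if (nrow(pairs) == 0)
    return(list(merged = data.frame(id = character(0), sequence = character(0),
                                    quality = character(0), overlap = integer(0)),
                rejected = data.frame(id = character(0), reason = character(0))))
  res <- .merge_read_pairs(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                           as.integer(min_overlap), max_mismatch_frac)
  ok <- res$ok
  list(merged = data.frame(id = pairs$id[ok], sequence = res$sequence[ok],
                           quality = res$quality[ok], overlap = res$overlap[ok]),
       rejected = data.frame(id = pairs$id[!ok],
                             reason = rep("no_admissible_overlap", sum(!ok))))
}

#' Trim primer footprints from merged amplicons
#'
#' The forward primer is matched at the 5' end and the reverse-complemented
#' reverse primer at the 3' end, each allowing at most `max_mismatch`
#' substitutions and no indels; both footprints are removed.
#'
#' @param merged data frame from [merge_pairs()] (`$merged`), or a named
#'   character vector of merged sequences.
#' @param pair primer pair (list with `fwd`, `rev`, or one-row data frame
#'   with `fwd_seq`, `rev_seq`).
#' @param max_mismatch substitution tolerance per primer (default 2).
#' @return list with `inserts` (named character vector) and `rejected`
#'   (data frame `id`, `reason`).
#' @export
trim_primers <- function(merged, pair, max_mismatch = 2) {
  pr <- normalize_pair(pair)
  if (is.data.frame(merged)) {
    seqs <- setNames(merged$sequence, merged$id)
  } else seqs <- merged
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  fl <- nchar(pr$fwd); rl <- nchar(pr$rev)
  len <- nchar(seqs)
  long_enough <- len > fl + rl
  mm_f <- rep(NA_integer_, length(seqs)); mm_r <- rep(NA_integer_, length(seqs))
  idx <- which(long_enough)
  if (length(idx)) {
    mm_f[idx] <- .hamming_vec(substr(seqs[idx], 1, fl), rep(pr$fwd, length(idx)))
    mm_r[idx] <- .hamming_vec(substring(seqs[idx], len[idx] - rl + 1),
                              rep(revcomp(pr$rev), length(idx)))
  }
  ok <- long_enough & mm_f <= max_mismatch & mm_r <= max_mismatch
  ok[is.na(ok)] <- FALSE
  reason <- ifelse(!long_enough, "too_short",
                   ifelse(mm_f > max_mismatch, "fwd_primer_mismatch",
                          "rev_primer_mismatch"))
  inserts <- substr(seqs[ok], fl + 1, len[ok] - rl)
  list(inserts = inserts,
       rejected = data.frame(id = names(seqs)[!ok], reason = reason[!ok]))
}

#' Dereplicate inserts into an ASV table
#'
#' Identical sequences (case-normalized) are pooled per sample; sequences
#' containing any non-ACGT character are discarded and counted. Rows are
#' sorted by total abundance descending, ties by sequence lexicographic
#' order.
#'
#' @param inserts_by_sample named list: sample id -> character vector of
#'   insert sequences.
#' @return object of class `asv_table`: list with `sequence` (character),
#'   `counts` (integer matrix, ASVs x samples, rownames `ASV1...`), and
#'   `discarded` (per-sample count of discarded sequences).
#' @export
dereplicate <- function(inserts_by_sample) {
  stopifnot(is.list(inserts_by_sample), !is.null(names(inserts_by_sample)))
  samples <- names(inserts_by_sample)
  cleaned <- lapply(inserts_by_sample, function(v) {
    v <- toupper(as.character(v))
    v[grepl("^[ACGT]+$", v)]
  })
  discarded <- vapply(inserts_by_sample, length, 0L) - vapply(cleaned, length, 0L)
  seqs <- sort(unique(unlist(cleaned, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    tb <- table(cleaned[[s]])
    counts[match(names(tb), seqs), s] <- as.integer(tb)
  }
  new_asv_table(seqs, counts, discarded)
}

new_asv_table <- function(sequence, counts, discarded = NULL) {
  stopifnot(length(sequence) == nrow(counts), !anyDuplicated(sequence))
  total <- rowSums(counts)
  ord <- order(-total, sequence)
  sequence <- sequence[ord]
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- if (nrow(counts)) paste0("ASV", seq_len(nrow(counts))) else NULL
  structure(list(sequence = sequence, counts = counts,
                 discarded = discarded %||%
                   setNames(integer(ncol(counts)), colnames(counts))),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("<asv_table> ", nrow(x$counts), " ASVs x ", ncol(x$counts),
      " samples; total reads ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.asv_table <- function(x, ...) {
  data.frame(asv_id = rownames(x$counts) %||% character(0),
             sequence = x$sequence, x$counts, check.names = FALSE,
             row.names = NULL)
}

#' Write an ASV table as TSV
#'
#' @param table an `asv_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Abundance-based ASV denoising
#'
#' Per sample: (1) ASVs with count below `min_count` are removed; (2) in a
#' single pass over the remaining ASVs in descending abundance order (ties
#' by sequence lexicographic order), an ASV within Hamming distance 1 of a
#' more abundant ASV and with count at most `skew` times that parent's
#' current count is merged into the parent (the most abundant eligible
#' parent wins; ties by lexicographic order). ASVs with zero total count
#' afterwards are dropped.
#'
#' @param table an `asv_table`.
#' @param min_count minimum per-sample count (default 2).
#' @param skew maximum child/parent abundance ratio for merging
#'   (default 0.05).
#' @return a denoised `asv_table`.
#' @export
denoise <- function(table, min_count = 2, skew = 0.05) {
  counts <- table$counts
  seqs <- table$sequence
  lens <- nchar(seqs)
  for (s in seq_len(ncol(counts))) {
    cnt <- counts[, s]
    cnt[cnt > 0 & cnt < min_count] <- 0L
    ord <- order(-cnt, seqs)
    for (i in ord) {
      if (cnt[i] == 0) next
      cand <- which(cnt > cnt[i] & lens == lens[i])
      if (length(cand) == 0) next
      d1 <- cand[.hamming_vec(seqs[cand], rep(seqs[i], length(cand))) == 1]
      d1 <- d1[cnt[i] <= skew * cnt[d1]]
      if (length(d1) == 0) next
      parent <- d1[order(-cnt[d1], seqs[d1])][1]
      cnt[parent] <- cnt[parent] + cnt[i]
      cnt[i] <- 0L
    }
    counts[, s] <- cnt
  }
  keep <- rowSums(counts) > 0
  new_asv_table(seqs[keep], counts[keep, , drop = FALSE], table$discarded)
}

#' Assign ASVs to taxa by global identity against reference inserts
#'
#' Each ASV is globally aligned to every reference insert; identity is 100
#' times the number of identical columns over the alignment length. Status
#' is `species` at exactly 100% identity, `near` at or above
#' `near_threshold`, otherwise `unassigned`; an ASV tied between equally
#' best references is unassigned with the tie flag set.
#'
#' @param table an `asv_table`.
#' @param refs named character vector: taxon -> reference insert sequence.
#' @param scoring an [align_scoring()] object.
#' @param near_threshold identity (percent) for `near` status (default 97).
#' @return data frame: `asv_id`, `taxon` (`NA` when unassigned),
#'   `identity`, `status`, `tie`.
#' @export
assign_taxa <- function(table, refs, scoring = align_scoring(),
                        near_threshold = 97) {
  if (length(refs) == 0) stop("reference set is empty")
  if (is.null(names(refs)) || anyDuplicated(names(refs)))
    stop("refs must be uniquely named by taxon")
  n <- length(table$sequence)
  out <- data.frame(asv_id = rownames(table$counts) %||% character(0),
                    taxon = rep(NA_character_, n),
                    identity = rep(NA_real_, n),
                    status = rep("unassigned", n),
                    tie = rep(FALSE, n))
  for (i in seq_len(n)) {
    ident <- vapply(refs, function(r) {
      aln <- global_align(table$sequence[i], r, scoring)
      ca <- strsplit(aln$aligned_a, "")[[1]]
      cb <- strsplit(aln$aligned_b, "")[[1]]
      100 * sum(ca == cb) / length(ca)
    }, 0)
    best <- max(ident)
    winners <- names(refs)[ident == best]
    out$identity[i] <- best
    if (length(winners) > 1) {
      out$tie[i] <- TRUE
    } else {
      out$taxon[i] <- winners
      out$status[i] <- if (best == 100) "species"
      else if (best >= near_threshold) "near" else "unassigned"
      if (out$status[i] == "unassigned") out$taxon[i] <- NA_character_
    }
  }
  out
}

#' Per-sample species proportions from assigned reads
#'
#' For each sample, the proportion of a taxon is its species-assigned read
#' count divided by the sample's total species-assigned reads; reads from
#' `near` or `unassigned` ASVs are excluded from the denominator. Samples
#' with zero species-assigned reads are emitted flagged, with no
#' proportions.
#'
#' @param table an `asv_table`.
#' @param assignments result of [assign_taxa()] for the same table.
#' @return data frame: `sample`, `taxon`, `reads`, `proportion`, `flagged`.
#' @export
species_proportions <- function(table, assignments) {
  ids <- rownames(table$counts)
  if (!all(ids %in% assignments$asv_id))
    stop("assignments do not cover all ASVs in the table")
  sp <- assignments[assignments$status == "species", , drop = FALSE]
  rows <- list()
  for (s in colnames(table$counts)) {
    cnt <- table$counts[, s]
    reads <- if (nrow(sp)) tapply(cnt[match(sp$asv_id, ids)], sp$taxon, sum)
    else numeric(0)
    total <- sum(reads)
    if (is.na(total) || total == 0) {
      rows[[s]] <- data.frame(sample = s, taxon = NA_character_,
                              reads = 0L, proportion = NA_real_, flagged = TRUE)
    } else {
      rows[[s]] <- data.frame(sample = s, taxon = names(reads),
                              reads = as.integer(reads),
                              proportion = as.numeric(reads) / total,
                              flagged = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Reads-proportion vs biomass-proportion regression
#'
#' Ordinary least squares of reads proportion on biomass proportion, pooled
#' over taxa and mixtures; R-squared is the squared Pearson correlation of
#' the fitted points (defined as 0, with a warning, when the response is
#' constant).
#'
#' @param points data frame with columns `biomass_proportion` and
#'   `reads_proportion` (>= 2 rows, non-zero variance in x).
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
proportion_regression <- function(points) {
  x <- points$biomass_proportion; y <- points$reads_proportion
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("zero variance in biomass proportion")
  fit <- lm(y ~ x)
  r2 <- if (stats::var(y) == 0) {
    warning("constant reads proportion: degenerate fit, R-squared set to 0")
    0
  } else cor(x, y)^2
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_points = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.4f, intercept %.4f, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' End-to-end amplicon quantification
#'
#' Runs demultiplexing, pair merging, primer trimming, dereplication,
#' denoising, taxon assignment and proportion estimation; optionally fits
#' the reads-vs-biomass regression when a declared-biomass table is given.
#'
#' @param pairs read-pair data frame (see [read_fastq_pairs()]).
#' @param scheme a [tag_scheme()].
#' @param primer_pair primer pair (list `fwd`/`rev` or one-row data frame).
#' @param refs named character vector of per-taxon reference inserts.
#' @param biomass optional data frame `sample`, `taxon`, `proportion`.
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @param max_primer_mismatch see [trim_primers()].
#' @param min_count,skew see [denoise()].
#' @param scoring an [align_scoring()] object.
#' @return list: `asv_table`, `assignments`, `proportions`, `regression`
#'   (`NULL` without biomass), `log` (per-stage read counts).
#' @export
run_quantification <- function(pairs, scheme, primer_pair, refs,
                               biomass = NULL,
                               min_overlap = 20, max_mismatch_frac = 0.1,
                               max_primer_mismatch = 2,
                               min_count = 2, skew = 0.05,
                               scoring = align_scoring()) {
  dmx <- demultiplex(pairs, scheme)
  inserts <- list(); log <- list(input = nrow(pairs),
                                 unassigned = nrow(dmx$unassigned))
  for (s in names(dmx$samples)) {
    mg <- merge_pairs(dmx$samples[[s]], min_overlap, max_mismatch_frac)
    tr <- trim_primers(mg$merged, primer_pair, max_primer_mismatch)
    inserts[[s]] <- unname(tr$inserts)
    log[[paste0(s, "_merged")]] <- nrow(mg$merged)
    log[[paste0(s, "_trimmed")]] <- length(tr$inserts)
  }
  tab <- dereplicate(inserts)
  tab <- denoise(tab, min_count = min_count, skew = skew)
  assignments <- assign_taxa(tab, refs, scoring)
  proportions <- species_proportions(tab, assignments)
  regression <- NULL
  if (!is.null(biomass)) {
    merged <- merge(proportions[!proportions$flagged, ], biomass,
                    by = c("sample", "taxon"))
    regression <- proportion_regression(data.frame(
      biomass_proportion = merged$proportion.y,
      reads_proportion = merged$proportion.x))
  }
  list(asv_table = tab, assignments = assignments,
       proportions = proportions, regression = regression, log = log)
}
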