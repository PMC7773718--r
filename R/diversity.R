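# Per-gene nucleotide diversity (pi) and variable-site window scans.

#' Nucleotide diversity of aligned sequences
#'
#' Mean pairwise p-distance with complete deletion: any alignment column
#' containing a gap or a non-ACGT code is excluded from the compared sites.
#' For two sequences this is simply `variable_sites / compared_sites`; for
#' more than two, the mean over all unordered pairs of the proportion of
#' differing compared columns (columns compared across *all* sequences).
#'
#' @param x a `pairwise_alignment` from [global_align()], or a character
#'   vector of >= 2 equal-length aligned sequences.
#' @return list with `pi`, `compared_sites`, `variable_sites` (for > 2
#'   sequences `variable_sites` counts compared columns that are not
#'   monomorphic).
#' @export
nucleotide_diversity <- function(x) {
  if (inherits(x, "pairwise_alignment")) {
    if (x$compared_sites == 0)
      stop("pi is undefined: alignment has zero compared sites")
    return(list(pi = x$variable_sites / x$compared_sites,
                compared_sites = x$compared_sites,
                variable_sites = x$variable_sites))
  }
  if (!is.character(x) || length(x) < 2)
    stop("x must be a pairwise_alignment or >= 2 aligned sequences")
  if (length(unique(nchar(x))) != 1)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  acgt <- c("A", "C", "G", "T")
  compared <- apply(m, 2, function(col) all(col %in% acgt))
  if (!any(compared)) stop("pi is undefined: zero compared sites")
  mc <- m[, compared, drop = FALSE]
  n <- nrow(mc); npairs <- n * (n - 1) / 2
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) diffs <- diffs + sum(mc[i, ] != mc[j, ])
  }
  list(pi = diffs / (npairs * ncol(mc)),
       compared_sites = ncol(mc),
       variable_sites = sum(apply(mc, 2, function(col) length(unique(col)) > 1)))
}

#' Rank shared genes by nucleotide diversity
#'
#' Aligns each orthologous gene pair with [global_align()] and computes pi;
#' results are sorted by pi descending with ties broken by gene name. Genes
#' whose alignment has zero compared sites get `pi = NA` and sort last.
#'
#' @param table result of [shared_gene_table()].
#' @param scoring an [align_scoring()] object.
#' @return data frame: `gene`, `pi`, `compared_sites`, `variable_sites`.
#' @export
rank_gene_diversity <- function(table, scoring = align_scoring()) {
  if (nrow(table) == 0)
    return(data.frame(gene = character(0), pi = numeric(0),
                      compared_sites = integer(0), variable_sites = integer(0)))
  recs <- lapply(seq_len(nrow(table)), function(i) {
    aln <- global_align(table$seq_a[i], table$seq_b[i], scoring)
    if (aln$compared_sites == 0) {
      data.frame(gene = table$gene[i], pi = NA_real_,
                 compared_sites = 0L, variable_sites = 0L)
    } else {
      data.frame(gene = table$gene[i],
                 pi = aln$variable_sites / aln$compared_sites,
                 compared_sites = aln$compared_sites,
                 variable_sites = aln$variable_sites)
    }
  })
  out <- do.call(rbind, recs)
  out <- out[order(is.na(out$pi), -ifelse(is.na(out$pi), 0, out$pi),
                   norm_gene_name(out$gene)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-gene diversity report
#'
#' Pi is formatted to 5 decimal places.
#'
#' @param records result of [rank_gene_diversity()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(records, path) {
  records$pi <- ifelse(is.na(records$pi), "NA", sprintf("%.5f", records$pi))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sliding-window variable-site counts over an alignment
#'
#' Windows of `window` alignment columns tile `[0, length)` at the given
#' step (the last window may be shorter), counting variable compared
#' columns and gap-containing columns per window.
#'
#' @param alignment a `pairwise_alignment`.
#' @param window window length in alignment columns.
#' @param step step between window starts; `1 <= step <= window`.
#' @return data frame: `start`, `end` (0-based half-open), `variable_sites`,
#'   `gap_columns`.
#' @export
scan_windows <- function(alignment, window, step = window) {
  len <- nchar(alignment$aligned_a)
  if (!(step >= 1 && step <= window)) stop("need 1 <= step <= window")
  if (window > len) stop("window exceeds alignment length (", len, ")")
  cols <- alignment_columns(alignment)
  variable <- cols$compared & cols$a != cols$b
  starts <- seq(0L, len - window, by = step)
  if (starts[length(starts)] + window < len)
    starts <- c(starts, starts[length(starts)] + step)
  ends <- pmin(starts + window, len)
  data.frame(
    start = starts, end = ends,
    variable_sites = vapply(seq_along(starts), function(i)
      sum(variable[(starts[i] + 1):ends[i]]), 0L),
    gap_columns = vapply(seq_along(starts), function(i)
      sum(cols$gap[(starts[i] + 1):ends[i]]), 0L))
}
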