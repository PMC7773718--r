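# Genome records: reading GenBank/FASTA, coding-gene extraction, orthologs.
#
# Coordinates are 0-based half-open everywhere inside the package; GenBank's
# 1-based inclusive locations are converted at the parsing boundary only.

#' Construct a genome record
#'
#' Container for one organelle genome: its sequence plus typed gene features
#' (CDS, tRNA, rRNA). Features are held as one row per location segment,
#' grouped by `feature_id`, with 0-based half-open `start`/`end` on the plus
#' strand and `strand` giving the coding strand of the segment.
#'
#' @param accession accession string.
#' @param sequence genome sequence (uppercase IUPAC DNA).
#' @param features data frame with columns `feature_id`, `gene`, `kind`
#'   (`CDS`, `tRNA` or `rRNA`), `start`, `end`, `strand` (`+`/`-`), and
#'   optionally `ir_duplicate`. Zero rows allowed.
#' @param organism organism name, or `NA`.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(accession, sequence, features = NULL, organism = NA_character_) {
  sequence <- check_dna(sequence, "genome sequence")
  len <- nchar(sequence)
  if (is.null(features)) {
    features <- data.frame(feature_id = integer(0), gene = character(0),
                           kind = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           ir_duplicate = logical(0))
  }
  needed <- c("feature_id", "gene", "kind", "start", "end", "strand")
  if (!all(needed %in% names(features)))
    stop("features must have columns: ", paste(needed, collapse = ", "))
  if (is.null(features$ir_duplicate)) {
    # a gene name seen on an earlier distinct feature of the same kind marks
    # the later copies (inverted-repeat duplicates) for reporting
    key <- paste(norm_gene_name(features$gene), features$kind)
    first_fid <- tapply(features$feature_id, key, min)
    features$ir_duplicate <- features$feature_id != unname(first_fid[key])
  }
  if (nrow(features)) {
    if (any(features$start < 0L | features$end > len | features$start > features$end))
      stop("feature segment outside [0, genome length) or start > end")
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    if (!all(features$kind %in% c("CDS", "tRNA", "rRNA")))
      stop("feature kind must be CDS, tRNA or rRNA")
  }
  structure(list(accession = accession, organism = organism,
                 sequence = sequence, length = len, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  nfeat <- length(unique(x$features$feature_id))
  cat("<genome_record> ", x$accession,
      if (!is.na(x$organism)) paste0(" (", x$organism, ")"), "\n",
      "  length: ", format(x$length, big.mark = ","), " bp; ",
      nfeat, " features (",
      sum(!duplicated(x$features$feature_id) & x$features$kind == "CDS"),
      " CDS)\n", sep = "")
  invisible(x)
}

#' Read a genome from GenBank or FASTA
#'
#' GenBank flat files (LOCUS/FEATURES/ORIGIN) are parsed for sequence and
#' CDS/tRNA/rRNA features, converting 1-based inclusive locations (including
#' `complement()` and `join()` forms) to 0-based half-open coordinates.
#' FASTA input yields a record with zero features.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the first line), `"genbank"` or `"fasta"`.
#' @return a [genome_record()].
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "LOCUS")) "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0) stop("no sequence records in ", path)
    if (length(set) > 1)
      warning("multiple FASTA records in ", path, "; using the first")
    seqstr <- toupper(as.character(set[[1]]))
    if (!nzchar(seqstr)) stop("empty sequence in ", path)
    acc <- strsplit(names(set)[1], "\\s+")[[1]][1]
    return(genome_record(acc, seqstr))
  }
  parse_genbank(path)
}

# --- GenBank flat-file parsing ------------------------------------------

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- which(startsWith(lines, "LOCUS"))
  if (length(locus_i) == 0) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus_i <- locus_i[1]
  end_i <- which(trimws(lines) == "//")
  end_i <- if (length(end_i)) end_i[1] else length(lines)
  lines <- lines[locus_i:end_i]

  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  accession <- locus[2]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(acc_line[1]), "\\s+")[[1]]
    if (length(acc) >= 2) accession <- acc[2]
  }
  organism <- NA_character_
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^\\s*ORGANISM\\s*", "", org_line[1]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0) stop("GenBank record has no ORIGIN section: ", path)
  orig_i <- orig_i[1]

  seq_lines <- lines[(orig_i + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqstr <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seqstr)) stop("empty sequence in GenBank record: ", path)

  features <- empty_features()
  if (length(feat_i)) {
    ftab <- lines[(feat_i[1] + 1):(orig_i - 1)]
    features <- parse_genbank_features(ftab, path)
  }
  genome_record(accession, seqstr, features, organism)
}

empty_features <- function() {
  data.frame(feature_id = integer(0), gene = character(0), kind = character(0),
             start = integer(0), end = integer(0), strand = character(0))
}

parse_genbank_features <- function(ftab, path) {
  # feature lines: key at column 6, location/qualifiers at column 22
  is_key <- grepl("^\\s{5}\\S", ftab)
  key_idx <- which(is_key)
  rows <- list(); fid <- 0L
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    stop_i <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(ftab)
    parts <- strsplit(trimws(ftab[i]), "\\s+")[[1]]
    kind <- parts[1]
    block <- ftab[i:stop_i]
    # location may continue over lines until the first qualifier
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(c(sub("^\\s*\\S+\\s*", "", trimws(ftab[i])),
                   trimws(block[seq_len(loc_end)][-1])), collapse = "")
    loc <- gsub("\\s", "", loc)
    if (!kind %in% c("CDS", "tRNA", "rRNA")) next
    quals <- paste(block[-seq_len(loc_end)], collapse = " ")
    gene <- qualifier_value(quals, "gene") %||% qualifier_value(quals, "locus_tag")
    if (is.null(gene)) next
    segs <- tryCatch(parse_gb_location(loc),
                     error = function(e) stop("malformed location for feature '",
                                              gene, "' in ", path, ": ", loc,
                                              call. = FALSE))
    fid <- fid + 1L
    rows[[fid]] <- data.frame(feature_id = fid, gene = gene, kind = kind,
                              start = segs$start, end = segs$end,
                              strand = segs$strand)
  }
  if (length(rows) == 0) return(empty_features())
  do.call(rbind, rows)
}

qualifier_value <- function(quals, name) {
  m <- regmatches(quals, regexec(paste0("/", name, "=\"([^\"]*)\""), quals))[[1]]
  if (length(m) == 2) m[2] else NULL
}

# GenBank location string -> data.frame(start, end, strand), 0-based half-open
parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  parse_one <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse_one(inner, if (strand == "+") "-" else "+"))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_top_level(inner)
      out <- lapply(parts, parse_one, strand = strand)
      return(do.call(rbind, out))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
      return(data.frame(start = ab[1] - 1L, end = ab[2], strand = strand))
    }
    if (grepl("^[0-9]+$", s)) {
      p <- as.integer(s)
      return(data.frame(start = p - 1L, end = p, strand = strand))
    }
    stop("unsupported location element: ", s)
  }
  segs <- parse_one(loc, "+")
  if (any(segs$start > segs$end)) stop("inverted segment in location: ", loc)
  # order segments 5'->3' on the coding strand
  ord <- order(segs$start)
  segs[ord, , drop = FALSE]
}

split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends,
         SIMPLIFY = TRUE, USE.NAMES = FALSE)
}

# --- writers -------------------------------------------------------------

#' Write a genome record to FASTA
#'
#' @param record a [genome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(record, path) {
  set <- Biostrings::DNAStringSet(record$sequence)
  names(set) <- record$accession
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN sections with 1-based inclusive locations;
#' round-trips through [read_genome()].
#'
#' @inheritParams write_genome_fasta
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$accession, record$length), con)
  writeLines(sprintf("ACCESSION   %s", record$accession), con)
  if (!is.na(record$organism)) {
    writeLines("SOURCE      synthetic construct", con)
    writeLines(sprintf("  ORGANISM  %s", record$organism), con)
  }
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  feats <- record$features
  for (fid in unique(feats$feature_id)) {
    segs <- feats[feats$feature_id == fid, , drop = FALSE]
    locs <- sprintf("%d..%d", segs$start + 1L, segs$end)
    loc <- if (nrow(segs) > 1) paste0("join(", paste(locs, collapse = ","), ")") else locs
    if (all(segs$strand == "-")) loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-16s%s", segs$kind[1], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", segs$gene[1]), con)
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    starts <- seq(p, min(p + 59, nchar(s)), by = 10)
    chunk <- substring(s, starts, pmin(starts + 9, nchar(s)))
    writeLines(sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# --- coding-gene extraction ---------------------------------------------

#' Extract protein-coding genes from a genome record
#'
#' Returns one spliced, coding-orientation sequence per unique gene name
#' among CDS features. Minus-strand genes are reverse-complemented;
#' multi-segment (`join`) genes are spliced in genomic order before
#' orientation. For genes duplicated in the inverted repeats the copy with
#' the smaller start coordinate is kept. Features with a zero-length segment
#' or with segments on both strands (trans-spliced) are skipped with a
#' warning.
#'
#' @param record a [genome_record()].
#' @return data frame with columns `gene`, `sequence`, `length`,
#'   `accession`.
#' @export
extract_coding_genes <- function(record) {
  feats <- record$features
  cds <- feats[feats$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0)
    return(data.frame(gene = character(0), sequence = character(0),
                      length = integer(0), accession = character(0)))
  out <- list()
  # one candidate feature per normalized gene name: smallest start coordinate
  by_fid <- split(cds, cds$feature_id)
  info <- data.frame(
    fid = as.integer(names(by_fid)),
    gene = vapply(by_fid, function(s) s$gene[1], ""),
    min_start = vapply(by_fid, function(s) as.numeric(min(s$start)), 0)
  )
  info$norm <- norm_gene_name(info$gene)
  keep <- unlist(lapply(split(seq_len(nrow(info)), info$norm), function(idx) {
    idx[which.min(info$min_start[idx])]
  }))
  for (i in keep) {
    segs <- by_fid[[as.character(info$fid[i])]]
    if (any(segs$end == segs$start)) {
      warning("gene '", segs$gene[1], "': zero-length segment; skipped")
      next
    }
    if (length(unique(segs$strand)) > 1) {
      warning("gene '", segs$gene[1], "': segments on both strands (trans-spliced); skipped")
      next
    }
    segs <- segs[order(segs$start), , drop = FALSE]
    parts <- substring(record$sequence, segs$start + 1L, segs$end)
    seqstr <- paste(parts, collapse = "")
    if (segs$strand[1] == "-") seqstr <- revcomp(seqstr)
    out[[length(out) + 1L]] <- data.frame(
      gene = segs$gene[1], sequence = seqstr, length = nchar(seqstr),
      accession = record$accession)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), sequence = character(0),
                      length = integer(0), accession = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(norm_gene_name(res$gene)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Table of orthologous coding genes shared by two genomes
#'
#' Intersects the unique CDS gene sets of two genomes after name
#' normalization (whitespace-trimmed, case-insensitive); the spelling from
#' the first genome is reported. Genes private to one genome are dropped and
#' recorded in the `only_a`/`only_b` attributes.
#'
#' @param a,b [genome_record()] objects with CDS features.
#' @return data frame with columns `gene`, `seq_a`, `seq_b`, `length_a`,
#'   `length_b`, sorted by gene name; attributes `only_a` and `only_b` list
#'   private gene names.
#' @export
shared_gene_table <- function(a, b) {
  ga <- extract_coding_genes(a)
  gb <- extract_coding_genes(b)
  na <- norm_gene_name(ga$gene); nb <- norm_gene_name(gb$gene)
  common <- intersect(na, nb)
  if (length(common) == 0)
    warning("no shared protein-coding genes between ", a$accession,
            " and ", b$accession)
  ia <- match(common, na); ib <- match(common, nb)
  out <- data.frame(gene = ga$gene[ia],
                    seq_a = ga$sequence[ia], seq_b = gb$sequence[ib],
                    length_a = ga$length[ia], length_b = gb$length[ib])
  out <- out[order(norm_gene_name(out$gene)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "only_a") <- ga$gene[!na %in% common]
  attr(out, "only_b") <- gb$gene[!nb %in% common]
  out
}

#' Write the shared-gene report
#'
#' @param table result of [shared_gene_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_shared_gene_report <- function(table, path) {
  write.table(table[, c("gene", "length_a", "length_b")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
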