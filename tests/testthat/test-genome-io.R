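test_that("GenBank parsing yields correct coordinates, strands and splicing", {
  set.seed(11)
  gb <- write_toy_genbank()
  rec <- read_genome(gb$path)
  expect_s3_class(rec, "genome_record")
  expect_identical(rec$sequence, gb$sequence)
  expect_equal(rec$length, 120)
  expect_equal(rec$accession, "TOY0001")
  expect_equal(rec$organism, "Toyus exampli")

  feats <- rec$features
  expect_setequal(unique(feats$gene), c("matK", "rbcL", "ndhF"))
  # 1-based inclusive 11..40 -> 0-based half-open [10, 40)
  matk <- feats[feats$gene == "matK", ]
  expect_equal(c(matk$start, matk$end, matk$strand), c("10", "40", "+"))
  rbcl <- feats[feats$gene == "rbcL", ]
  expect_equal(rbcl$strand, "-")
  ndhf <- feats[feats$gene == "ndhF", ]
  expect_equal(nrow(ndhf), 2)
  expect_equal(ndhf$start, c(94L, 102L))

  genes <- extract_coding_genes(rec)
  expect_equal(nrow(genes), 3)
  expect_identical(genes$sequence[genes$gene == "matK"],
                   substr(gb$sequence, 11, 40))
  # minus strand: reverse complement of the genomic slice
  expect_identical(genes$sequence[genes$gene == "rbcL"],
                   revcomp(substr(gb$sequence, 61, 90)))
  # join: spliced in genomic order
  expect_identical(genes$sequence[genes$gene == "ndhF"],
                   paste0(substr(gb$sequence, 95, 100), substr(gb$sequence, 103, 108)))
})

test_that("FASTA records parse with zero features and round-trip exactly", {
  set.seed(12)
  seq100 <- random_dna(100)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr_test some description", seq100), fa)
  rec <- read_genome(fa, format = "fasta")
  expect_equal(rec$length, 100)
  expect_equal(nrow(rec$features), 0)
  expect_equal(rec$accession, "chr_test")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(rec, out)
  rec2 <- read_genome(out)
  expect_identical(rec2$sequence, rec$sequence)
})

test_that("GenBank writer round-trips sequence and features", {
  set.seed(13)
  gb <- write_toy_genbank()
  rec <- read_genome(gb$path)
  out <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, out)
  rec2 <- read_genome(out)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(extract_coding_genes(rec2), extract_coding_genes(rec))
})

test_that("inverted-repeat duplicates resolve to the lower-coordinate copy", {
  set.seed(14)
  seqstr <- random_dna(300)
  feats <- data.frame(feature_id = c(1L, 2L),
                      gene = c("psbA", "psbA"), kind = "CDS",
                      start = c(10L, 200L), end = c(40L, 230L), strand = "+")
  rec <- genome_record("DUP1", seqstr, feats)
  genes <- extract_coding_genes(rec)
  expect_equal(nrow(genes), 1)
  expect_identical(genes$sequence, substr(seqstr, 11, 40))
  expect_true(rec$features$ir_duplicate[rec$features$feature_id == 2])
  expect_false(rec$features$ir_duplicate[rec$features$feature_id == 1])
})

test_that("zero-length and trans-spliced features are skipped with warnings", {
  set.seed(15)
  seqstr <- random_dna(200)
  feats <- data.frame(
    feature_id = c(1L, 2L, 2L, 3L),
    gene = c("bad1", "rps12", "rps12", "good"),
    kind = "CDS",
    start = c(10L, 20L, 60L, 100L), end = c(10L, 40L, 80L, 130L),
    strand = c("+", "+", "-", "+"))
  rec <- genome_record("SKP1", seqstr, feats)
  expect_warning(expect_warning(genes <- extract_coding_genes(rec),
                                "zero-length"), "trans-spliced")
  expect_equal(genes$gene, "good")
})

test_that("shared gene tables intersect case-insensitively and symmetrically", {
  set.seed(16)
  mk_rec <- function(acc, genes) {
    len <- 60L * length(genes)
    feats <- data.frame(feature_id = seq_along(genes), gene = genes,
                        kind = "CDS", start = 60L * (seq_along(genes) - 1L) + 5L,
                        end = 60L * (seq_along(genes) - 1L) + 35L, strand = "+")
    genome_record(acc, random_dna(len), feats)
  }
  a <- mk_rec("A1", c("matK", "rbcL", "onlyA"))
  b <- mk_rec("B1", c("Matk ", "rbcL", "onlyB"))  # case/whitespace variant
  tab <- shared_gene_table(a, b)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$gene, c("matK", "rbcL"))  # spelling from the first genome
  expect_setequal(attr(tab, "only_a"), "onlyA")
  expect_setequal(attr(tab, "only_b"), "onlyB")

  tab_rev <- shared_gene_table(b, a)
  expect_setequal(tolower(trimws(tab_rev$gene)), tolower(trimws(tab$gene)))

  same <- shared_gene_table(a, a)
  expect_equal(nrow(same), 3)

  c_rec <- mk_rec("C1", c("ycf2"))
  expect_warning(empty <- shared_gene_table(a, c_rec), "no shared")
  expect_equal(nrow(empty), 0)
})

test_that("extracted single-segment genes are substrings of the source genome", {
  set.seed(17)
  cfg <- simulation_config(seed = 17, gene_count = 6, gene_length = 300,
                           conserved_flank = 20, n_reads = 10)
  sim <- simulate_genome_pair(cfg)
  genes <- extract_coding_genes(sim$genome_a)
  for (i in seq_len(nrow(genes))) {
    hit <- grepl(genes$sequence[i], sim$genome_a$sequence, fixed = TRUE) ||
      grepl(revcomp(genes$sequence[i]), sim$genome_a$sequence, fixed = TRUE)
    expect_true(hit)
  }
})
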