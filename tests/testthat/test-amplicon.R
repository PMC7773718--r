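scheme2 <- function() tag_scheme(data.frame(
  sample = c("s1", "s2"),
  fwd_tag = c("ACGTAC", "TGCATG"), rev_tag = c("GTACGT", "CATGCA")))

test_that("dual-tag demultiplexing is exact and tag jumps go unassigned", {
  sch <- scheme2()
  pairs <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    seq1 = c(paste0("ACGTAC", "AAAA"),  # s1 tags on both mates
             paste0("ACGTAC", "CCCC"),  # s1 fwd + s2 rev: tag jump
             paste0("TGCATG", "GGGG"),  # s2
             paste0("TTTTTT", "TTTT")), # unknown tag
    qual1 = "IIIIIIIIII",
    seq2 = c(paste0("GTACGT", "AAAA"), paste0("CATGCA", "CCCC"),
             paste0("CATGCA", "GGGG"), paste0("GTACGT", "TTTT")),
    qual2 = "IIIIIIIIII")
  dmx <- demultiplex(pairs, sch)
  expect_equal(dmx$samples$s1$id, "r1")
  expect_equal(dmx$samples$s1$seq1, "AAAA")  # tags stripped
  expect_equal(dmx$samples$s1$qual1, "IIII")
  expect_equal(dmx$samples$s2$id, "r3")
  expect_setequal(dmx$unassigned$id, c("r2", "r4"))
  # conservation
  expect_equal(sum(vapply(dmx$samples, nrow, 0L)) + nrow(dmx$unassigned),
               nrow(pairs))

  bad <- data.frame(sample = c("a", "b"),
                    fwd_tag = c("ACGTAC", "ACGTAC"),
                    rev_tag = c("GTACGT", "GTACGT"))
  expect_error(tag_scheme(bad), "duplicate")
  expect_error(tag_scheme(data.frame(sample = "a", fwd_tag = "ACGT",
                                     rev_tag = "ACGT")), ">= 6")
})

test_that("pair merging reconstructs the amplicon and respects quality", {
  set.seed(41)
  amp <- random_dna(200)
  pairs <- data.frame(id = "m1",
                      seq1 = substr(amp, 1, 150), qual1 = strrep("I", 150),
                      seq2 = revcomp(substr(amp, 51, 200)), qual2 = strrep("I", 150))
  mg <- merge_pairs(pairs)
  expect_equal(nrow(mg$merged), 1)
  expect_identical(mg$merged$sequence, amp)
  expect_equal(mg$merged$overlap, 100)
  expect_equal(nchar(mg$merged$quality), 200)

  # overlap of only 10 bases is rejected at min_overlap 20
  long_amp <- random_dna(290)
  short_ov <- data.frame(id = "m2",
                         seq1 = substr(long_amp, 1, 150), qual1 = strrep("I", 150),
                         seq2 = revcomp(substr(long_amp, 141, 290)),
                         qual2 = strrep("I", 150))
  mg2 <- merge_pairs(short_ov)
  expect_equal(nrow(mg2$merged), 0)
  expect_equal(mg2$rejected$reason, "no_admissible_overlap")

  # disagreement inside the overlap: the higher-quality mate wins
  err1 <- substr(amp, 1, 150)
  true_base <- substr(amp, 100, 100)
  substr(err1, 100, 100) <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  q1 <- strrep("I", 150); substr(q1, 100, 100) <- "+"  # Q10 at the error
  dis <- data.frame(id = "m3", seq1 = err1, qual1 = q1,
                    seq2 = revcomp(substr(amp, 51, 200)), qual2 = strrep("I", 150))
  mg3 <- merge_pairs(dis)
  expect_identical(substr(mg3$merged$sequence, 100, 100), true_base)
})

test_that("primer trimming removes footprints within the mismatch budget", {
  set.seed(42)
  fx <- make_barcode_fixture(42)
  pr <- fx$pair
  amp <- fx$amplicons[["obtusifolia"]]
  tr <- trim_primers(setNames(amp, "r1"), pr)
  expect_equal(unname(tr$inserts), fx$inserts[["obtusifolia"]])
  expect_equal(nchar(tr$inserts[[1]]), 164)

  # three substitutions in the forward footprint exceed the default budget
  bad <- mutate_dna(amp, c(2, 5, 9))
  tr2 <- trim_primers(setNames(bad, "r2"), pr)
  expect_equal(length(tr2$inserts), 0)
  expect_equal(tr2$rejected$reason, "fwd_primer_mismatch")

  # unrelated sequence rejects
  tr3 <- trim_primers(setNames(random_dna(200), "r3"), pr)
  expect_equal(length(tr3$inserts), 0)
})

test_that("dereplication pools identical inserts and discards N-containing reads", {
  s1 <- "ACGTACGTAA"; s2 <- "TTGCATTGCA"
  tab <- dereplicate(list(
    mixA = c(rep(s1, 10), rep(s2, 5), tolower(s1), "ACGTNCGTAA"),
    mixB = rep(s2, 3)))
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 2)
  # sorted by total abundance; mixed case collapses into one ASV
  expect_equal(df$sequence[1], s1)
  expect_equal(df$mixA, c(11L, 5L))
  expect_equal(df$mixB, c(0L, 3L))
  expect_equal(unname(tab$discarded["mixA"]), 1L)
  # table total equals retained inserts
  expect_equal(sum(tab$counts), 11 + 5 + 3)
})

test_that("denoising merges skewed 1-mismatch children and drops rare ASVs", {
  parent <- "ACGTACGTGG"
  child <- "ACCTACGTGG"   # Hamming 1
  far <- "TTTTACGTGG"     # Hamming >= 2 from parent
  single <- "GGGGGGGGGG"
  tab <- dereplicate(list(s = c(rep(parent, 100), rep(child, 2),
                                rep(far, 90), single)))
  dn <- denoise(tab)
  df <- as.data.frame(dn)
  expect_setequal(df$sequence, c(parent, far))
  expect_equal(df$s[df$sequence == parent], 102L)  # child merged in
  expect_equal(df$s[df$sequence == far], 90L)      # too abundant to merge
  # denoising never increases the total
  expect_lte(sum(dn$counts), sum(tab$counts))

  # no rule fires: table unchanged
  quiet <- dereplicate(list(s = c(rep(parent, 50), rep(far, 40))))
  expect_equal(as.data.frame(denoise(quiet)), as.data.frame(quiet))
})

test_that("taxon assignment requires full-length identity for species calls", {
  set.seed(43)
  ref_a <- random_dna(164)
  ref_b <- mutate_dna(ref_a, sample(164, 7))
  refs <- c(taxA = ref_a, taxB = ref_b)
  one_off <- mutate_dna(ref_a, 1)
  tab <- dereplicate(list(s = c(rep(ref_a, 30), rep(one_off, 20))))
  asn <- assign_taxa(tab, refs)
  exact <- asn[match(ref_a, tab$sequence), ]
  expect_equal(exact$status, "species")
  expect_equal(exact$identity, 100)
  expect_equal(exact$taxon, "taxA")
  near <- asn[match(one_off, tab$sequence), ]
  expect_equal(near$status, "near")
  expect_equal(near$identity, 100 * 163 / 164, tolerance = 1e-9)

  # equally near to two references -> unassigned with tie flag
  tie_refs <- c(t1 = "AAAAAAAACC", t2 = "AAAAAAAAGG")
  tie_tab <- dereplicate(list(s = rep("AAAAAAAATT", 5)))
  tie_asn <- assign_taxa(tie_tab, tie_refs)
  expect_true(tie_asn$tie)
  expect_equal(tie_asn$status, "unassigned")

  expect_error(assign_taxa(tab, character(0)), "empty")
})

test_that("species proportions use species-assigned reads only", {
  # two ASVs with published JM1-style counts
  tab <- new_asv_table(c("AAAA", "CCCC"),
                       matrix(c(56065L, 57978L), ncol = 1,
                              dimnames = list(NULL, "JM1")))
  asn <- data.frame(asv_id = rownames(tab$counts),
                    taxon = c("occidentalis", "obtusifolia")[
                      match(tab$sequence, c("AAAA", "CCCC"))],
                    identity = 100, status = "species", tie = FALSE)
  prop <- species_proportions(tab, asn)
  expect_equal(round(prop$proportion[prop$taxon == "occidentalis"], 4), 0.4916)
  expect_equal(round(prop$proportion[prop$taxon == "obtusifolia"], 4), 0.5084)
  expect_equal(sum(prop$proportion), 1)

  # single-species sample
  solo <- new_asv_table("ACGT", matrix(10L, dimnames = list(NULL, "m")))
  asn1 <- data.frame(asv_id = "ASV1", taxon = "t", identity = 100,
                     status = "species", tie = FALSE)
  expect_equal(species_proportions(solo, asn1)$proportion, 1)

  # all reads unassigned -> flagged row without proportions
  asn0 <- data.frame(asv_id = "ASV1", taxon = NA, identity = 95,
                     status = "unassigned", tie = FALSE)
  flagged <- species_proportions(solo, asn0)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$proportion))
})

test_that("the reads-vs-biomass regression is ordinary least squares", {
  pts <- data.frame(biomass_proportion = c(0.1, 0.3, 0.6, 0.9),
                    reads_proportion = c(0.1, 0.3, 0.6, 0.9))
  fit <- proportion_regression(pts)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 4)

  const <- data.frame(biomass_proportion = c(0.2, 0.8),
                      reads_proportion = c(0.5, 0.5))
  expect_warning(fit0 <- proportion_regression(const), "degenerate")
  expect_equal(fit0$r_squared, 0)

  expect_error(proportion_regression(pts[1, ]), "2 points")
  expect_error(proportion_regression(data.frame(
    biomass_proportion = c(0.5, 0.5), reads_proportion = c(0.1, 0.9))),
    "variance")
})

test_that("read counts are conserved at every pipeline stage on fuzzed input", {
  set.seed(44)
  fx <- make_barcode_fixture(44)
  sch <- scheme2()
  n <- 300
  # a fuzzed mix: valid reads, tag-jumped reads, garbage, short overlaps
  mk_read <- function(i) {
    kind <- sample(c("good", "jump", "garbage"), 1)
    amp <- fx$amplicons[[sample(2, 1)]]
    row <- sch[sample(nrow(sch), 1), ]
    if (kind == "garbage") {
      data.frame(id = paste0("f", i), seq1 = random_dna(80), qual1 = strrep("I", 80),
                 seq2 = random_dna(80), qual2 = strrep("I", 80))
    } else {
      rev_tag <- if (kind == "jump") sch$rev_tag[sch$sample != row$sample][1] else row$rev_tag
      data.frame(id = paste0("f", i),
                 seq1 = paste0(row$fwd_tag, substr(amp, 1, 144)),
                 qual1 = strrep("I", 150),
                 seq2 = paste0(rev_tag, substr(revcomp(amp), 1, 144)),
                 qual2 = strrep("I", 150))
    }
  }
  pairs <- do.call(rbind, lapply(seq_len(n), mk_read))
  dmx <- demultiplex(pairs, sch)
  expect_equal(sum(vapply(dmx$samples, nrow, 0L)) + nrow(dmx$unassigned), n)
  retained <- 0L
  for (s in names(dmx$samples)) {
    mg <- merge_pairs(dmx$samples[[s]])
    expect_equal(nrow(mg$merged) + nrow(mg$rejected), nrow(dmx$samples[[s]]))
    tr <- trim_primers(mg$merged, fx$pair)
    expect_equal(length(tr$inserts) + nrow(tr$rejected), nrow(mg$merged))
    retained <- retained + length(tr$inserts)
  }
  inserts <- lapply(dmx$samples, function(df) {
    unname(trim_primers(merge_pairs(df)$merged, fx$pair)$inserts)
  })
  tab <- dereplicate(inserts)
  expect_equal(sum(tab$counts) + sum(tab$discarded), retained)
  dn <- denoise(tab)
  expect_lte(sum(dn$counts), sum(tab$counts))
})
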