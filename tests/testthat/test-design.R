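test_that("primer enumeration recovers a planted hypervariable insert", {
  set.seed(808)
  # 40 nt conserved flank + 160 nt core with 7 substitutions + 40 nt flank
  left <- random_dna(40); core <- random_dna(160); right <- random_dna(40)
  var_at <- sort(sample(160, 7))
  a <- paste0(left, core, right)
  b <- paste0(left, mutate_dna(core, var_at), right)
  aln <- global_align(a, b)
  pairs <- enumerate_primer_pairs(aln, design_constraints(product_size = c(150, 240)))
  expect_gt(nrow(pairs), 0)
  expect_equal(max(pairs$insert_variable_sites), 7)

  # every reported pair satisfies every constraint bound
  cons <- design_constraints(product_size = c(150, 240))
  for (k in seq_len(nrow(pairs))) {
    expect_gte(nchar(pairs$fwd_seq[k]), cons$primer_size[1])
    expect_lte(nchar(pairs$fwd_seq[k]), cons$primer_size[2])
    expect_gte(nchar(pairs$rev_seq[k]), cons$primer_size[1])
    expect_lte(nchar(pairs$rev_seq[k]), cons$primer_size[2])
    expect_gte(pairs$product_size[k], cons$product_size[1])
    expect_lte(pairs$product_size[k], cons$product_size[2])
    for (tm in c(pairs$tm_f[k], pairs$tm_r[k])) {
      expect_gte(tm, cons$tm[1]); expect_lte(tm, cons$tm[2])
    }
    for (gc in c(pairs$gc_f[k], pairs$gc_r[k])) {
      expect_gte(gc, cons$gc[1]); expect_lte(gc, cons$gc[2])
    }
    expect_false(hairpin_check(pairs$fwd_seq[k])$hairpin)
    expect_false(hairpin_check(pairs$rev_seq[k])$hairpin)
    expect_true(dimer_check(pairs$fwd_seq[k], pairs$rev_seq[k])$pass)
    expect_gte(pairs$insert_variable_sites[k], 1)
  }
  # ranked by variable sites desc, then insert length asc
  expect_true(all(diff(pairs$insert_variable_sites) <= 0))
})

test_that("enumeration returns nothing without variable sites or feasible products", {
  set.seed(809)
  s <- random_dna(400)
  expect_equal(nrow(enumerate_primer_pairs(global_align(s, s))), 0)

  a <- random_dna(400); b <- mutate_dna(a, c(200, 210))
  infeasible <- design_constraints(product_size = c(10, 20))
  expect_equal(nrow(enumerate_primer_pairs(global_align(a, b), infeasible)), 0)
})

test_that("enumerated primer sequences are invariant to taxon order", {
  set.seed(810)
  left <- random_dna(60); core <- random_dna(120); right <- random_dna(60)
  a <- paste0(left, core, right)
  b <- paste0(left, mutate_dna(core, sample(120, 5)), right)
  cons <- design_constraints(product_size = c(150, 240))
  p_ab <- enumerate_primer_pairs(global_align(a, b), cons, max_pairs = Inf)
  p_ba <- enumerate_primer_pairs(global_align(b, a), cons, max_pairs = Inf)
  expect_setequal(paste(p_ab$fwd_seq, p_ab$rev_seq),
                  paste(p_ba$fwd_seq, p_ba$rev_seq))
})

test_that("in-silico PCR finds a planted amplicon exactly once", {
  set.seed(811)
  fx <- make_barcode_fixture(811)
  pr <- fx$pair
  tmpl <- paste0(random_dna(300), fx$amplicons[["obtusifolia"]], random_dna(250))
  amp <- in_silico_pcr(list(fwd = pr$fwd_seq, rev = pr$rev_seq), tmpl,
                       max_mismatch = 0)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 300)
  expect_equal(amp$end, 300 + 200)
  expect_equal(amp$size, 200)
  expect_equal(nchar(amp$insert_sequence), 164)
  # insert length + both primer lengths = amplicon length
  expect_equal(nchar(amp$insert_sequence) + nchar(pr$fwd_seq) + nchar(pr$rev_seq),
               amp$size)
  expect_identical(amp$full_sequence, fx$amplicons[["obtusifolia"]])

  none <- in_silico_pcr(list(fwd = pr$fwd_seq, rev = pr$rev_seq),
                        random_dna(500))
  expect_equal(nrow(none), 0)
})

test_that("in-silico PCR tolerates substitutions but anchors the 3' end", {
  set.seed(812)
  fx <- make_barcode_fixture(812)
  pr <- fx$pair
  amp_seq <- fx$amplicons[["obtusifolia"]]
  # two substitutions in the 5' half of the forward footprint: still found
  mutated <- mutate_dna(amp_seq, c(2, 5))
  tmpl <- paste0(random_dna(100), mutated, random_dna(100))
  expect_equal(nrow(in_silico_pcr(pr[1, ], tmpl, max_mismatch = 2)), 1)
  expect_equal(nrow(in_silico_pcr(pr[1, ], tmpl, max_mismatch = 1)), 0)
  # a mismatch in the 3'-terminal trinucleotide kills annealing
  bad3p <- mutate_dna(amp_seq, nchar(pr$fwd_seq))
  tmpl3p <- paste0(random_dna(100), bad3p, random_dna(100))
  expect_equal(nrow(in_silico_pcr(pr[1, ], tmpl3p, max_mismatch = 2)), 0)
})

test_that("variable-site counts over inserts use compared columns", {
  set.seed(813)
  s <- random_dna(120)
  expect_equal(count_variable_sites(c(a = s, b = s)), 0)
  expect_equal(count_variable_sites(c(a = s, b = mutate_dna(s, c(10, 50, 90)))), 3)
  expect_error(count_variable_sites(c(a = s, b = NA)), "taxon")
  # three taxa via star alignment
  expect_equal(count_variable_sites(
    c(x = "ACGTACGT", y = "ACGAACGT", z = "ACGTACCT")), 2)
})

test_that("the design pipeline recovers a planted barcode as rank 1", {
  cfg <- simulation_config(seed = 814, gene_count = 5, gene_length = 500,
                           divergence = c(0.06, 0.004, 0.004, 0.004, 0.004),
                           conserved_flank = 45, n_reads = 10)
  sim <- simulate_genome_pair(cfg)
  cand <- design_minibarcodes(sim$genome_a, sim$genome_b, top_genes = 3,
                              max_pairs_per_gene = 10)
  expect_gt(nrow(cand), 0)
  expect_equal(cand$gene[1], "g01")
  expect_equal(cand$rank, seq_len(nrow(cand)))
  expect_true(all(cand$size_a >= 150 & cand$size_a <= 300))

  # identical genomes admit no candidates
  none <- design_minibarcodes(sim$genome_a, sim$genome_a, top_genes = 2)
  expect_equal(nrow(none), 0)
})
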