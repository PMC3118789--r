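test_that("all generators are byte-reproducible under a fixed seed", {
  s1 <- simulate_genome(synthetic_spec(n_genes = 6), seed = 12)
  s2 <- simulate_genome(synthetic_spec(n_genes = 6), seed = 12)
  expect_identical(s1$record$sequence, s2$record$sequence)
  expect_identical(feature_table(s1$record), feature_table(s2$record))
  s3 <- simulate_genome(synthetic_spec(n_genes = 6), seed = 13)
  expect_false(identical(s1$record$sequence, s3$record$sequence))

  cds <- strrep("GGTATTAAA", 50)
  e1 <- evolve_pair(cds, 0.3, 0.2, seed = 5)
  e2 <- evolve_pair(cds, 0.3, 0.2, seed = 5)
  expect_identical(e1, e2)

  tr <- "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.1);"
  a1 <- simulate_alignment(tr, n_codons = 50, seed = 8)
  a2 <- simulate_alignment(tr, n_codons = 50, seed = 8)
  expect_identical(a1$alignment, a2$alignment)

  r1 <- simulate_strain_set(seed = 2)
  r2 <- simulate_strain_set(seed = 2)
  expect_identical(r1$sequences, r2$sequences)
})

test_that("generator randomness does not disturb the caller's RNG stream", {
  set.seed(1000)
  before <- .Random.seed
  invisible(simulate_genome(synthetic_spec(n_genes = 4), seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("simulated genomes honour their structural spec", {
  spec <- synthetic_spec(n_genes = 12, spacer_bp = c(0, 85))
  sim <- simulate_genome(spec, seed = 19)
  ft <- feature_table(sim$record)
  expect_equal(sum(ft$ftype == "CDS"), 12)
  expect_equal(sum(ft$ftype == "rRNA"), spec$n_rrna)
  expect_true(all(grepl("^ymf", ft$name[ft$gene_class == "orf"])))
  cs <- coding_summary(sim$record)
  expect_true(all(cs$spacer_lengths <= 85))
  # every CDS translates cleanly under the declared code
  for (f in Filter(function(x) x$ftype == "CDS", sim$record$features)) {
    cds <- extract_cds(sim$record, f, spec$code_id)
    expect_true(cds$trailing_stop)
  }
})

test_that("an in-frame repeat spec off the codon grid is rejected", {
  expect_error(synthetic_spec(repeat_unit_bp = 17), "multiple of 3")
})

test_that("evolve_pair degenerate settings behave exactly", {
  cds <- strrep("GGTATTAAA", 100)
  same <- evolve_pair(cds, t_syn = 0, omega = 1, seed = 4)
  expect_identical(same$a, same$b)
  expect_identical(same$a, cds)

  pure <- evolve_pair(cds, t_syn = 0.5, omega = 0, seed = 6)
  kk <- ng86_kaks(pure$a, pure$b)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  expect_equal(sum(pure$truth$nonsyn), 0)
  expect_error(evolve_pair(cds, 0.1, -0.5, seed = 1), "omega")
})

test_that("alignment simulation respects branch lengths and GC3 targets", {
  zero <- simulate_alignment("((A:0,B:0):0,(C:0,D:0):0);", n_codons = 40, seed = 9)
  expect_equal(length(unique(zero$alignment)), 1L)

  sim <- simulate_alignment("((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.1,(E:0.05,F:0.05):0.1);",
                            n_codons = 400, clade = c("A", "B"),
                            gc3_high = 48, gc3_background = 10, seed = 10)
  g <- gc3_by_taxon(sim$alignment)
  hi <- g$gc3[g$taxon %in% c("A", "B")]
  lo <- g$gc3[!g$taxon %in% c("A", "B")]
  se_hi <- 100 * sqrt(0.48 * 0.52 / 400)
  se_lo <- 100 * sqrt(0.10 * 0.90 / 400)
  expect_true(all(abs(hi - 48) < 4 * se_hi))
  expect_true(all(abs(lo - 10) < 4 * se_lo))
  # no in-frame stop codons anywhere
  for (s in sim$alignment)
    expect_false(grepl("*", translate_dna(s, 4), fixed = TRUE))

  expect_error(simulate_alignment("(A:1,B:1);", 10, gc3_high = 120, seed = 1),
               "percentages")
})

test_that("the shift edge is recovered from simulated data", {
  sim <- simulate_alignment("((A:0.04,B:0.04):0.15,(C:0.04,D:0.04):0.08,(E:0.04,F:0.04):0.08);",
                            n_codons = 300, clade = c("A", "B"),
                            gc3_high = 48, gc3_background = 10, seed = 14)
  tree <- neighbor_joining(dist_matrix(sim$alignment, "K2P"))
  g <- gc3_by_taxon(sim$alignment)
  ps <- place_shift(tree, stats::setNames(g$gc3, g$taxon), cut = 30)
  expect_true(ps$monophyletic)
  expect_setequal(ps$split, c("A", "B"))
})
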