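test_that("a stop-free frame yields one long stop_to_stop ORF", {
  set.seed(1)
  fam <- synonymous_families(4)
  sense <- setdiff(unlist(fam), stop_codons(4))
  nt <- paste0(sample(sense, 200, replace = TRUE), collapse = "")
  orfs <- find_orfs(nt, code_id = 4, min_aa = 60)
  f0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_equal(nrow(f0), 1)
  expect_gte(f0$length_aa, 200)
  expect_equal(f0$start, 0)
  expect_equal(f0$end, 600)
})

test_that("ORF calls match a brute-force six-frame scanner on random sequence", {
  set.seed(99)
  for (rep in 1:3) {
    nt <- random_dna(10000)
    got <- find_orfs(nt, code_id = 4, min_aa = 60)
    want <- oracle_orfs(nt, code_id = 4, min_aa = 60)
    expect_equal(got[, names(want)], want)
  }
})

test_that("find_orfs is strand-symmetric", {
  set.seed(3)
  nt <- random_dna(5000)
  a <- find_orfs(nt, min_aa = 30)
  b <- find_orfs(reverse_complement(nt), min_aa = 30)
  L <- nchar(nt)
  mapped <- data.frame(start = L - b$end, end = L - b$start,
                       strand = ifelse(b$strand == "+", "-", "+"),
                       length_aa = b$length_aa, stringsAsFactors = FALSE)
  mapped <- mapped[order(mapped$start, mapped$end, mapped$strand), ]
  rownames(mapped) <- NULL
  a2 <- a[, c("start", "end", "strand", "length_aa")]
  a2 <- a2[order(a2$start, a2$end, a2$strand), ]
  rownames(a2) <- NULL
  expect_equal(a2, mapped)
})

test_that("every ORF call translates without internal stops", {
  set.seed(8)
  nt <- random_dna(6000)
  orfs <- find_orfs(nt, code_id = 4, min_aa = 40)
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(nt, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-") sub <- reverse_complement(sub)
    expect_false(grepl("*", translate_dna(sub, 4), fixed = TRUE))
  }
})

test_that("start_required mode begins ORFs at the first start codon", {
  nt <- paste0("CCCCCC", "ATG", paste(rep("GGT", 70), collapse = ""), "TAA")
  st <- find_orfs(nt, min_aa = 60, mode = "start_required")
  hit <- st[st$strand == "+" & st$frame == 0, ]
  expect_equal(hit$start, 6)
  expect_equal(substr(nt, hit$start + 1, hit$start + 3), "ATG")
})

test_that("spacers are the maximal gaps between merged gene intervals", {
  rec <- genome_record("r", paste(rep("ACGT", 6), collapse = ""),
                       list(feature("g1", "CDS", 0, 9, partial = TRUE),
                            feature("g2", "CDS", 15, 24, partial = TRUE)))
  sp <- derive_spacers(rec)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$start, 9)
  expect_equal(sp[[1]]$end, 15)

  tiled <- genome_record("r2", "ACGTACGTA",
                         list(feature("g1", "CDS", 0, 9)))
  expect_length(derive_spacers(tiled), 0)
})

test_that("merged genes plus spacers tile the genome exactly", {
  sim <- simulate_genome(synthetic_spec(n_genes = 10), seed = 5)
  rec <- sim$record
  genes <- Filter(function(f) f$ftype != "spacer", rec$features)
  iv <- rbind(
    do.call(rbind, lapply(genes, function(f) c(f$start, f$end))),
    do.call(rbind, lapply(derive_spacers(rec), function(f) c(f$start, f$end))))
  iv <- iv[order(iv[, 1]), ]
  expect_equal(iv[1, 1], 0)
  expect_equal(iv[nrow(iv), 2], rec$length)
  expect_true(all(iv[-1, 1] <= iv[-nrow(iv), 2]))  # no gaps
  expect_equal(sum(iv[, 2] - iv[, 1]), rec$length) # no overlap (genes disjoint here)
})

test_that("coding_summary matches the generator's ground truth exactly", {
  sim <- simulate_genome(synthetic_spec(), seed = 17)
  cs <- coding_summary(sim$record)
  expect_equal(cs$total_bp, sim$truth$coding$total_bp)
  expect_equal(cs$coding_bp, sim$truth$coding$coding_bp)
  expect_equal(cs$protein_coding_bp, sim$truth$coding$protein_coding_bp)
  expect_equal(cs$coding_fraction, sim$truth$coding$coding_fraction)
})

test_that("a record without features has coding fraction zero", {
  rec <- genome_record("r", "ACGTACGT")
  cs <- coding_summary(rec)
  expect_equal(cs$coding_fraction, 0)
  expect_equal(cs$spacer_lengths, 8L)
})
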