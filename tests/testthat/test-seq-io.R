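test_that("GenBank coordinates convert to 0-based half-open and back", {
  path <- withr::local_tempfile(fileext = ".gb")
  write_mini_genbank(path, "mini", "ATGGGTTAAACC",
                     c("     CDS             1..6",
                       "                     /gene=\"g1\""))
  rec <- read_genbank(path)
  expect_equal(rec$length, 12)
  f <- rec$features[[1]]
  expect_equal(f$start, 0)
  expect_equal(f$end, 6)
  expect_equal(f$strand, "+")
  expect_equal(f$gene_class, "known")
})

test_that("GenBank write/read round-trips the feature table field by field", {
  sim <- simulate_genome(synthetic_spec(n_genes = 8), seed = 21)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$record, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, sim$record$sequence)
  expect_equal(back$topology, "linear")
  expect_equal(feature_table(back), feature_table(sim$record))
})

test_that("malformed locations and length mismatches are flagged", {
  path <- withr::local_tempfile(fileext = ".gb")
  write_mini_genbank(path, "bad", "ATGGGTTAA",
                     c("     CDS             1..x9",
                       "                     /gene=\"g1\""))
  expect_error(read_genbank(path), "malformed location.*g1")
  lines <- readLines(write_mini_genbank(path, "bad2", "ATGGGTTAA", character(0)))
  lines[1] <- sub("9 bp", "12 bp", lines[1])
  writeLines(lines, path)
  expect_error(read_genbank(path), "integrity")
})

test_that("FASTA reading preserves order, uppercases, and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), path)
  expect_equal(read_fasta(path), c(a = "ACGT"))

  writeLines(c(">a", "acgt", ">a", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(character(0), path)
  expect_warning(out <- read_fasta(path), "empty")
  expect_length(out, 0)
})

test_that("FASTA round-trips a cox1-like record set byte-identically", {
  set.seed(7)
  recs <- stats::setNames(
    vapply(1:13, function(i) random_dna(776), character(1)),
    sprintf("cox1_taxon%02d", 1:13))
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, p1, width = 60)
  back <- read_fasta(p1)
  expect_identical(back, recs)
  write_fasta(back, p2, width = 60)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("extract_cds translates, flags trailing stops, and respects strand", {
  rec <- genome_record("r", "ATGGGTTAA",
                       list(feature("g", "CDS", 0, 9)))
  cds <- extract_cds(rec, rec$features[[1]], code_id = 4)
  expect_equal(cds$protein, "MG")
  expect_true(cds$trailing_stop)

  # same CDS annotated on the minus strand of the reverse complement
  rc <- genome_record("r2", reverse_complement("ATGGGTTAA"),
                      list(feature("g", "CDS", 0, 9, strand = "-")))
  cds2 <- extract_cds(rc, rc$features[[1]], code_id = 4)
  expect_equal(cds2$protein, "MG")
  expect_equal(cds2$nucleotides, cds$nucleotides)
})

test_that("TGA is Trp under code 4 and an internal stop under code 1", {
  nt <- "ATGTGAGGTTAA"
  expect_equal(coding_sequence("g", nt, code_id = 4)$protein, "MWG")
  expect_error(coding_sequence("g", nt, code_id = 1),
               "internal stop codon at codon 2")
})

test_that("codes 4 and 1 differ exactly at TGA codons on random sequences", {
  set.seed(42)
  for (i in 1:20) {
    nt <- random_dna(3 * 50)
    cods <- substring(nt, 3 * (1:50) - 2, 3 * (1:50))
    aa4 <- strsplit(translate_dna(nt, 4), "")[[1]]
    aa1 <- strsplit(translate_dna(nt, 1), "")[[1]]
    expect_identical(which(aa4 != aa1), which(cods == "TGA"))
  }
})

test_that("non-N ambiguity codes are rejected, N tolerated", {
  expect_error(genome_record("r", "ACGRT"), "unsupported characters")
  rec <- genome_record("r", "ACGNT")
  expect_equal(rec$length, 5)
})

test_that("CDS features must be a multiple of 3 unless flagged partial", {
  expect_error(feature("g", "CDS", 0, 7), "not a multiple of 3")
  f <- feature("g", "CDS", 0, 7, partial = TRUE)
  expect_true(f$partial)
})
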