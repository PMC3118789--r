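test_that("codon counting is complete, order-invariant, and additive", {
  tab <- count_codons("ATGTAA")
  expect_equal(unname(tab$counts[c("ATG", "TAA")]), c(1L, 1L))
  expect_equal(sum(tab$counts), 2L)

  set.seed(6)
  genes <- lapply(1:4, function(i)
    paste0(sample(all_codons(), 30, TRUE), collapse = ""))
  expect_equal(count_codons(genes)$counts, count_codons(rev(genes))$counts)
  per_gene <- lapply(genes, count_codons)
  summed <- Reduce(`+`, lapply(per_gene, `[[`, "counts"))
  expect_equal(summed, count_codons(genes)$counts)
})

test_that("relative frequencies are per-family and invert to counts", {
  counts <- stats::setNames(integer(64), all_codons())
  counts["TTT"] <- 19L; counts["TTC"] <- 1L
  counts["GGT"] <- 5L; counts["GGC"] <- 5L
  tab <- structure(list(counts = counts, code_id = 4, scope = "toy",
                        n_skipped = 0L), class = "codon_count_table")
  prof <- relative_frequencies(tab)
  f <- stats::setNames(prof$table$frequency, prof$table$codon)
  expect_equal(unname(f["TTT"]), 0.95)
  expect_equal(unname(f["TTC"]), 0.05)
  expect_equal(unname(f["GGT"]), 0.5)

  # inversion: frequency x family total reproduces every count
  set.seed(9)
  cds <- paste0(sample(setdiff(all_codons(), stop_codons(4)), 500, TRUE),
                collapse = "")
  tab2 <- count_codons(cds)
  prof2 <- relative_frequencies(tab2)
  fam_tot <- tapply(prof2$table$count, prof2$table$amino_acid, sum)
  back <- prof2$table$frequency * fam_tot[prof2$table$amino_acid]
  defined <- !is.na(prof2$table$frequency)
  expect_equal(as.numeric(back[defined]), as.numeric(prof2$table$count[defined]))
})

test_that("rare-codon classification respects the threshold and boundaries", {
  f <- c(TTT = 0.95, TTC = 0.05)
  expect_equal(classify_rare(f, 0.085)$rare_count, 1L)
  expect_equal(classify_rare(f, 0)$rare_count, 0L)
  # non-increasing in threshold
  cu <- reference_codon_usage()
  col <- stats::setNames(cu$P_caudatum, cu$codon)
  counts <- vapply(c(0.02, 0.05, 0.085, 0.2),
                   function(th) classify_rare(col, th)$rare_count, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("Nc attains its one-codon-per-amino-acid minimum of 20", {
  counts <- stats::setNames(integer(64), all_codons())
  for (cods in synonymous_families(4)) counts[cods[1]] <- 50L
  tab <- structure(list(counts = counts, code_id = 4, scope = "min",
                        n_skipped = 0L), class = "codon_count_table")
  expect_equal(as.numeric(effective_number_of_codons(tab)), 20)
})

test_that("Nc attains the code-4 sense-codon maximum of 62 under uniform usage", {
  counts <- stats::setNames(integer(64), all_codons())
  counts[setdiff(all_codons(), stop_codons(4))] <- 500L
  tab <- structure(list(counts = counts, code_id = 4, scope = "max",
                        n_skipped = 0L), class = "codon_count_table")
  expect_equal(as.numeric(effective_number_of_codons(tab)), 62)
})

test_that("skewing one family never increases Nc", {
  base <- stats::setNames(integer(64), all_codons())
  base[setdiff(all_codons(), stop_codons(4))] <- 100L
  nc_at <- function(ttt) {
    cnt <- base
    cnt["TTT"] <- as.integer(ttt); cnt["TTC"] <- as.integer(200 - ttt)
    tab <- structure(list(counts = cnt, code_id = 4, scope = "x",
                          n_skipped = 0L), class = "codon_count_table")
    as.numeric(effective_number_of_codons(tab))
  }
  ncs <- vapply(seq(100, 195, by = 5), nc_at, numeric(1))
  expect_true(all(diff(ncs) <= 1e-12))
})

test_that("Nc from the genome equals the large-n value on heavy sampling", {
  # sample codons i.i.d. from a fixed usage profile and compare the two routes
  cu <- reference_codon_usage()
  col <- stats::setNames(cu$P_caudatum, cu$codon)
  spec <- synthetic_spec(n_genes = 30, gene_length_aa = c(200, 600), usage = col)
  sim <- simulate_genome(spec, seed = 71)
  cds <- lapply(Filter(function(f) f$ftype == "CDS", sim$record$features),
                function(f) extract_cds(sim$record, f))
  tab <- count_codons(cds)
  expect_gt(sum(tab$counts), 10000)
  nc_emp <- as.numeric(effective_number_of_codons(tab))
  nc_inf <- as.numeric(nc_from_frequencies(col))
  expect_lt(abs(nc_emp - nc_inf), 1.5)

  # and the recovered per-codon frequencies match the generator's profile
  # within multinomial sampling error
  prof <- relative_frequencies(tab)
  d <- prof$table[prof$table$amino_acid != "Stop" & !is.na(prof$table$frequency), ]
  fam_n <- tapply(d$count, d$amino_acid, sum)
  fam_col <- tapply(col[d$codon], d$amino_acid, sum)
  p_true <- col[d$codon] / fam_col[d$amino_acid]
  se <- sqrt(pmax(p_true * (1 - p_true), 1e-6) / fam_n[d$amino_acid])
  expect_true(all(abs(d$frequency - p_true) < 4 * se + 0.01))
})

test_that("degenerate tables are flagged rather than silently scored", {
  counts <- stats::setNames(integer(64), all_codons())
  tab <- structure(list(counts = counts, code_id = 4, scope = "empty",
                        n_skipped = 0L), class = "codon_count_table")
  expect_error(effective_number_of_codons(tab), "empty")
  # only 2-fold families observed: rescaling fallback kicks in with a warning
  counts2 <- counts
  counts2["TTT"] <- 10L; counts2["TTC"] <- 10L
  counts2["GAT"] <- 10L; counts2["GAC"] <- 10L
  tab2 <- structure(list(counts = counts2, code_id = 4, scope = "partial",
                         n_skipped = 0L), class = "codon_count_table")
  expect_warning(nc <- effective_number_of_codons(tab2), "rescaled")
  expect_true(is.finite(nc))
})
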