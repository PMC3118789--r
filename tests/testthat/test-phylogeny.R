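test_that("K2P distance matches its closed form and the reference implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)

  # constructed P = 0.1, Q = 0.05 over 100 sites
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  expect_equal(k2p_distance(a, b), 0.17018, tolerance = 1e-4)

  # pure-transition limit: Q = 0 reduces to -1/2 ln(1 - 2P)
  set.seed(18)
  for (i in 1:5) {
    n <- 400
    p <- runif(1, 0.02, 0.4)
    k <- round(p * n)
    x <- paste(rep("A", n), collapse = "")
    y <- paste(c(rep("G", k), rep("A", n - k)), collapse = "")
    expect_equal(k2p_distance(x, y), -0.5 * log(1 - 2 * k / n), tolerance = 1e-12)
  }

  # independent oracle: ape's K80 distance on mutated pairs
  for (i in 1:5) {
    a1 <- random_dna(600)
    ch <- strsplit(a1, "")[[1]]
    flip <- runif(600) < 0.2
    ch[flip] <- vapply(ch[flip], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    aln <- c(a = a1, b = paste0(ch, collapse = ""))
    mat <- do.call(rbind, strsplit(tolower(aln), ""))
    d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                      pairwise.deletion = TRUE))
    expect_equal(k2p_distance(aln[1], aln[2]), d_ape, tolerance = 1e-9)
  }
})

test_that("K2P is monotone nondecreasing in P at fixed Q", {
  n <- 1000; qk <- 50
  d <- vapply(seq(10, 300, by = 10), function(pk) {
    x <- paste(rep("A", n), collapse = "")
    y <- paste(c(rep("G", pk), rep("C", qk), rep("A", n - pk - qk)), collapse = "")
    k2p_distance(x, y)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("neighbor joining is exact on the four-taxon additive example", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tree <- neighbor_joining(d)
  # AB|CD split with internal edge length 1, additive distances reproduced
  expect_equal(unname(as.matrix(stats::cophenetic(tree))[LETTERS[1:4], LETTERS[1:4]]),
               unname(d), tolerance = 1e-12)
  internal <- tree$edge[, 2] > length(tree$tip.label)
  expect_equal(sum(internal), 1L)
  expect_equal(tree$edge.length[internal], 1, tolerance = 1e-12)
})

test_that("neighbor joining reconstructs random additive trees exactly", {
  set.seed(23)
  for (n in 4:6) for (rep in 1:5) {
    true <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    d <- stats::cophenetic(true)
    got <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(true), got), 0,
                 ignore_attr = TRUE)
    expect_equal(unname(as.matrix(stats::cophenetic(got))[true$tip.label, true$tip.label]),
                 unname(d[true$tip.label, true$tip.label]), tolerance = 1e-8)
  }
})

test_that("three taxa solve the three-point equations; label order is irrelevant", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$edge.length), c(2, 3, 7))

  set.seed(24)
  true <- ape::rtree(5, rooted = FALSE)
  d5 <- stats::cophenetic(true)
  perm <- sample(rownames(d5))
  t1 <- neighbor_joining(d5)
  t2 <- neighbor_joining(d5[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap support is seed-reproducible and flags unresolvable input", {
  sim <- simulate_alignment("((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.05,(E:0.1,F:0.1):0.2);",
                            n_codons = 200, seed = 41)
  b1 <- bootstrap_nj(sim$alignment, n_reps = 50, seed = 9)
  b2 <- bootstrap_nj(sim$alignment, n_reps = 50, seed = 9)
  expect_identical(b1$node.label, b2$node.label)

  same <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "ACGTACGT")
  expect_warning(bootstrap_nj(same, n_reps = 10, seed = 1), "identical")
  expect_error(bootstrap_nj(same[1:3], 10, 1), "at least 4 taxa")
})

test_that("support for true bipartitions is high on a well-separated tree", {
  sim <- simulate_alignment("((A:0.05,B:0.05):0.25,(C:0.05,D:0.05):0.25,(E:0.05,F:0.05):0.05);",
                            n_codons = 300, seed = 55)
  bt <- bootstrap_nj(sim$alignment, n_reps = 200, seed = 7)
  support <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(support[-1] >= 90, na.rm = TRUE))
})

test_that("bipartition support is invariant under taxon reordering", {
  sim <- simulate_alignment("((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.1,(E:0.1,F:0.1):0.2);",
                            n_codons = 150, seed = 77)
  aln <- sim$alignment
  b1 <- bootstrap_nj(aln, n_reps = 40, seed = 3)
  b2 <- bootstrap_nj(aln[rev(names(aln))], n_reps = 40, seed = 3)
  # support keyed by canonical bipartition label
  key <- function(tr) {
    nt <- length(tr$tip.label)
    internal <- which(tr$edge[, 2] > nt)
    sets <- mitocomp:::edge_tip_sets(tr)
    out <- character(0)
    for (k in internal) {
      side <- sort(tr$tip.label[sets[[k]]])
      other <- sort(setdiff(tr$tip.label, side))
      parts <- sort(c(paste(side, collapse = ","), paste(other, collapse = ",")))
      lbl <- tr$node.label[tr$edge[k, 2] - nt]
      out <- c(out, paste(parts[1], parts[2], lbl, sep = "|"))
    }
    sort(out)
  }
  expect_identical(key(b1), key(b2))
})

test_that("per-taxon positional GC and shift placement behave on constructions", {
  aln <- c(hi = "AAGTTGCCC", lo = "AATTTACCC")
  g <- gc3_by_taxon(aln)
  expect_equal(g$gc3[g$taxon == "hi"], 100)
  expect_equal(g$gc3[g$taxon == "lo"], 100 / 3)
  expect_error(gc3_by_taxon(c(x = "ACGT")), "multiple of 3")

  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ps <- place_shift(tree, c(A = 50, B = 47, C = 10, D = 5), cut = 30)
  expect_true(ps$monophyletic)
  expect_setequal(ps$split, c("A", "B"))

  ps2 <- place_shift(tree, c(A = 50, B = 10, C = 47, D = 5), cut = 30)
  expect_false(ps2$monophyletic)
  expect_error(place_shift(tree, c(A = 50, B = 10, C = 47, D = 5), cut = 0),
               "inside")
})
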