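# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans and direct recomputations.

random_dna <- function(n, freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste0(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

# Brute-force six-frame ORF scan: translate every frame with the Biostrings
# code table and split on stops (codons with N break runs too).
oracle_orfs <- function(sequence, code_id = 4, min_aa = 60) {
  code <- Biostrings::getGeneticCode(as.character(code_id))
  names(code) <- chartr("U", "T", names(code))
  revcomp <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  L <- nchar(sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3
      if (n_cod == 0) next
      cods <- substring(s, frame + 3 * seq_len(n_cod) - 2, frame + 3 * seq_len(n_cod))
      aa <- code[cods]
      breaker <- is.na(aa) | aa == "*"
      run <- 0L
      for (i in seq_len(n_cod + 1)) {
        if (i <= n_cod && !breaker[i]) { run <- run + 1L; next }
        if (run >= min_aa) {
          a <- i - 1L - run  # 0-based codon index of run start
          i0 <- frame + 3L * a
          i1 <- frame + 3L * (i - 1L)
          g0 <- if (strand == "+") i0 else L - i1
          g1 <- if (strand == "+") i1 else L - i0
          rows[[length(rows) + 1L]] <- data.frame(
            start = g0, end = g1, strand = strand, frame = frame,
            length_aa = run, stringsAsFactors = FALSE)
        }
        run <- 0L
      }
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0), frame = integer(0),
                                       length_aa = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand, out$frame), ]
  rownames(out) <- NULL
  out
}

# Exhaustive all-(period, offset) tandem-array scanner with the same
# thresholds and reporting rules as the detector, but no seeding: every offset
# of every period is tried.
oracle_tandem <- function(sequence, min_unit = 6, max_unit = 100,
                          min_copies = 3, min_identity = 0.8) {
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(s)
  grow <- function(p, a) {
    b <- a + 2L * p
    idf <- function(x, y) mean(s[(x + 1):(x + p)] == s[(y + 1):(y + p)])
    while (b + p <= L && idf(b - p, b) >= min_identity) b <- b + p
    while (b < L && s[b + 1] == s[b + 1 - p]) b <- b + 1L
    while (a - p >= 0 && idf(a - p, a) >= min_identity) a <- a - p
    while (a > 0 && s[a] == s[a + p]) a <- a - 1L
    c(a, b)
  }
  prim <- function(u) {
    d <- length(u)
    for (p in seq_len(d - 1)) if (d %% p == 0 && all(u == rep(u[1:p], d / p))) return(p)
    d
  }
  cons <- function(p, a, b) {
    k <- (b - a) %/% p
    m <- matrix(s[a + seq_len(k * p)], nrow = p)
    apply(m, 1, function(col) names(which.max(table(col))))
  }
  rows <- list()
  for (p in seq.int(min_unit, min(max_unit, L %/% 2))) {
    m <- s[seq_len(L - p)] == s[(p + 1):L]
    cs <- c(0, cumsum(m))
    max_a <- L - 2L * p
    cand <- which((cs[(0:max_a) + p + 1L] - cs[(0:max_a) + 1L]) / p >= min_identity) - 1L
    done <- c(-1L, -1L)
    for (a in cand) {
      if (a >= done[1] && a + 2L * p <= done[2] && (a - done[1]) %% p == 0L) next
      sp <- grow(p, a)
      done <- sp
      d <- p
      u <- cons(d, sp[1], sp[2])
      p0 <- prim(u)
      if (p0 < d) {
        d <- p0
        sp <- grow(d, sp[1])
      }
      if (d < min_unit) next
      copy <- (sp[2] - sp[1]) / d
      if (copy < min_copies) next
      rows[[length(rows) + 1L]] <- data.frame(start = sp[1], end = sp[2],
                                              unit_length = d,
                                              copy_number = copy,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       unit_length = integer(0),
                                       copy_number = numeric(0)))
  out <- unique(do.call(rbind, rows))
  # same cross-period merge rule: overlap > half the shorter span keeps the
  # smaller period (ties: the larger span)
  out <- out[order(out$start, out$unit_length), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[j]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
      shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
      if (ov > shorter / 2) {
        drop <- if (out$unit_length[i] != out$unit_length[j]) {
          if (out$unit_length[i] < out$unit_length[j]) j else i
        } else if (out$end[i] - out$start[i] >= out$end[j] - out$start[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

# Match two repeat-call tables: same calls up to one unit of boundary slack.
expect_same_calls <- function(calls, oracle) {
  expect_equal(nrow(calls), nrow(oracle))
  if (nrow(calls) == 0) return(invisible(TRUE))
  o1 <- calls[order(calls$start), ]
  o2 <- oracle[order(oracle$start), ]
  expect_equal(o1$unit_length, o2$unit_length)
  expect_true(all(abs(o1$start - o2$start) <= o1$unit_length))
  expect_true(all(abs(o1$end - o2$end) <= o1$unit_length))
  invisible(TRUE)
}

# A tiny in-memory GenBank flat file.
write_mini_genbank <- function(path, id, sequence, features_txt) {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                     id, nchar(sequence)),
             "FEATURES             Location/Qualifiers",
             features_txt, "ORIGIN")
  pos <- seq(1, nchar(sequence), by = 60)
  lines <- c(lines,
             vapply(pos, function(p) sprintf("%9d %s", p,
               tolower(substr(sequence, p, min(p + 59, nchar(sequence))))),
               character(1)),
             "//")
  writeLines(lines, path)
  path
}
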