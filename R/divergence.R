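#' Global protein alignment and percent identity
#'
#' `align_proteins()` is a thin wrapper around a Needleman-Wunsch global
#' alignment (match 1, mismatch -1, gap -2 by default). `pairwise_identity()`
#' scores identity as identical columns divided by columns with residues in
#' both sequences (gap columns excluded from the denominator).
#'
#' @param a,b amino-acid strings (aligned, with `-` gaps, when
#'   `aligned = TRUE`).
#' @param match,mismatch,gap alignment scores (gap is per residue, linear).
#' @return `align_proteins()`: character vector of the two aligned strings.
#' @export
align_proteins <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  letters <- unique(c(strsplit(paste0(a, b), "")[[1]],
                      strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]))
  letters <- setdiff(letters, "-")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = m, gapOpening = 0, gapExtension = -gap)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' @rdname align_proteins
#' @param aligned if TRUE, `a` and `b` are already aligned (equal length);
#'   otherwise they are globally aligned first.
#' @return `pairwise_identity()`: fraction in \[0,1\].
#' @export
pairwise_identity <- function(a, b, aligned = TRUE, match = 1, mismatch = -1,
                              gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (!aligned) {
    al <- align_proteins(a, b, match, mismatch, gap)
    a <- al[1]; b <- al[2]
  }
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no aligned residue columns", call. = FALSE)
  sum(ca[both] == cb[both]) / sum(both)
}

#' Codon-align two coding sequences
#'
#' Aligns the proteins globally, then back-threads the nucleotides, dropping
#' gap-containing codon columns pairwise. Trailing stop codons are removed
#' before alignment.
#'
#' @param cds_a,cds_b [coding_sequence()] objects.
#' @return list with in-frame, equal-length `a` and `b` nucleotide strings,
#'   `n_codons`, and the protein `identity` of the alignment.
#' @export
codon_align <- function(cds_a, cds_b) {
  strip <- function(x) substr(x$nucleotides, 1L,
                              3L * nchar(x$protein))
  al <- align_proteins(cds_a$protein, cds_b$protein)
  ca <- strsplit(al[1], "")[[1]]; cb <- strsplit(al[2], "")[[1]]
  cod_a <- split_codons(strip(cds_a)); cod_b <- split_codons(strip(cds_b))
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  list(a = paste0(cod_a[ia[keep]], collapse = ""),
       b = paste0(cod_b[ib[keep]], collapse = ""),
       n_codons = sum(keep),
       identity = sum(ca[keep] == cb[keep]) / sum(keep))
}

# --- NG86 machinery --------------------------------------------------------

.ng86_cache <- new.env(parent = emptyenv())

# Synonymous site count of one codon: per position, the fraction of the three
# single-nucleotide changes that are synonymous, among changes that do not
# create a stop codon (standard NG86 convention).
ng86_codon_sites <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (code[[alt]] == "*") next
      nonstop <- nonstop + 1L
      if (code[[alt]] == code[[codon]]) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  s
}

# Synonymous/nonsynonymous differences between two codons, averaging over all
# orderings of the substitutions; paths through stop codons are excluded
# (unless every path is blocked, in which case all paths count).
ng86_codon_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else {
    idx <- if (d == 2L) list(pos, rev(pos)) else {
      p <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) p[[length(p) + 1L]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      p
    }
    idx
  }
  score_path <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- vapply(perms, score_path, numeric(3))
  ok <- res[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res[1, ok]), nd = mean(res[2, ok]))
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Counts synonymous and nonsynonymous sites and differences per the NG86
#' method under the active genetic code (sites averaged across the two
#' sequences; multi-difference codons average over all substitution orderings
#' with equal weights, excluding paths through stop codons), then applies the
#' Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p) to both proportions.
#'
#' @param a,b codon-aligned, equal-length, in-frame DNA strings without
#'   internal stops, or two [coding_sequence()] objects (which are
#'   codon-aligned first via [codon_align()]).
#' @inheritParams genetic_code
#' @return list of class `kaks_estimate`: `ka`, `ks`, `ratio` (NA when both
#'   are 0, Inf when ks = 0 with ka > 0), `s_sites`, `n_sites`, `sd`, `nd`,
#'   `n_codons`.
#' @export
ng86_kaks <- function(a, b, code_id = 4) {
  if (inherits(a, "coding_sequence")) {
    stopifnot(inherits(b, "coding_sequence"))
    code_id <- a$code_id
    al <- codon_align(a, b)
    a <- al$a; b <- al$b
  }
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be codon-aligned to equal length", call. = FALSE)
  code <- genetic_code(code_id)
  ca <- split_codons(a); cb <- split_codons(b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  # trailing/stray stop codons are dropped pairwise
  ok <- code[ca] != "*" & code[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop("no scorable codons", call. = FALSE)

  key <- paste0("S", as.character(code_id))
  if (is.null(.ng86_cache[[key]])) {
    .ng86_cache[[key]] <- vapply(all_codons(), ng86_codon_sites, numeric(1),
                                 code = code)
  }
  site_tab <- .ng86_cache[[key]]
  S <- (sum(site_tab[ca]) + sum(site_tab[cb])) / 2
  N <- 3 * length(ca) - S

  sd <- 0; nd <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    pk <- paste(as.character(code_id), ca[i], cb[i], sep = ":")
    val <- .ng86_cache[[pk]]
    if (is.null(val)) {
      val <- ng86_codon_diffs(ca[i], cb[i], code)
      .ng86_cache[[pk]] <- val
    }
    sd <- sd + val[["sd"]]; nd <- nd + val[["nd"]]
  }
  jc <- function(p) {
    if (p >= 0.75) stop("substitution proportion >= 3/4: distance saturated", call. = FALSE)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(if (S > 0) sd / S else 0)
  ka <- jc(if (N > 0) nd / N else 0)
  ratio <- if (ks == 0 && ka == 0) NA_real_
    else if (ks == 0) Inf
    else ka / ks
  structure(list(ka = ka, ks = ks, ratio = ratio, s_sites = S, n_sites = N,
                 sd = sd, nd = nd, n_codons = length(ca)),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("Ka %.4f  Ks %.4f  Ka/Ks %s  (S %.1f, N %.1f over %d codons)\n",
              x$ka, x$ks, format(x$ratio, digits = 3), x$s_sites, x$n_sites,
              x$n_codons))
  invisible(x)
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Computes the U statistic with midranks for ties and the tie-corrected
#' normal approximation z = (U - n1 n2 / 2) / sigma without continuity
#' correction. The sign convention follows group `a`: a negative z means
#' group `a` ranks lower than group `b`. For n1 + n2 <= `exact_max` an exact
#' permutation p-value is also computed by complete enumeration.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact_max enumerate the exact permutation p when n1 + n2 is at most
#'   this size.
#' @return list of class `rank_test`: `u`, `z`, `p_two_sided`, `p_exact`
#'   (NA when not enumerated), `n1`, `n2`.
#' @export
mann_whitney <- function(a, b, exact_max = 20) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  x <- c(a, b)
  r <- rank(x)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
  p <- 2 * stats::pnorm(-abs(z))
  p_exact <- NA_real_
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u_all - n1 * n2 / 2)
    p_exact <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-9)
  }
  structure(list(u = u, z = z, p_two_sided = p, p_exact = p_exact,
                 n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, z = %.2f, p = %.2g (n1 = %d, n2 = %d)%s\n",
              x$u, x$z, x$p_two_sided, x$n1, x$n2,
              if (!is.na(x$p_exact)) sprintf("; exact p = %.3g", x$p_exact) else ""))
  invisible(x)
}

#' Summarise Ka/Ks by gene class
#'
#' Arithmetic means of the Ka/Ks ratio per gene class (known genes vs unknown
#' ORFs) plus the Mann-Whitney contrast between the two ratio samples.
#' Undefined (NA/Inf) ratios are excluded and counted.
#'
#' @param records data.frame with at least columns `gene_class` ("known" /
#'   "orf") and `ratio`.
#' @return list: `means` (named numeric), `n` (named integer), `n_excluded`,
#'   `test` (a [mann_whitney()] result; NULL unless both classes present).
#' @export
class_summary <- function(records) {
  if (!all(c("gene_class", "ratio") %in% names(records)))
    stop("records must have gene_class and ratio columns", call. = FALSE)
  ok <- is.finite(records$ratio)
  n_excl <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no finite ratios", call. = FALSE)
  means <- tapply(rec$ratio, rec$gene_class, mean)
  ns <- tapply(rec$ratio, rec$gene_class, length)
  test <- NULL
  if (all(c("known", "orf") %in% names(means))) {
    test <- mann_whitney(rec$ratio[rec$gene_class == "known"],
                         rec$ratio[rec$gene_class == "orf"])
  }
  list(means = means, n = ns, n_excluded = n_excl, test = test)
}
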