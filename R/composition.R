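# Report-style rounding: 1 decimal place, half away from zero, as is usual in
# composition tables. Raw doubles are kept everywhere internally.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_percent <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Nucleotide composition of a sequence
#'
#' Percent G, A, T, C and G+C. `N` bases are excluded from the denominator and
#' their count reported.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @return list of class `composition_summary`: `g`, `a`, `t`, `c`, `gc`
#'   (percent, unrounded), `n_bases` (denominator), `n_excluded`.
#' @export
base_composition <- function(sequence) {
  sequence <- check_dna(sequence)
  counts <- table(factor(strsplit(sequence, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence has no unambiguous bases", call. = FALSE)
  pct <- 100 * counts / denom
  structure(list(g = unname(pct["G"]), a = unname(pct["A"]),
                 t = unname(pct["T"]), c = unname(pct["C"]),
                 gc = unname(pct["G"] + pct["C"]),
                 n_bases = as.integer(denom),
                 n_excluded = as.integer(counts["N"])),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("G %s  A %s  T %s  C %s  (G+C %s%%) over %d bases%s\n",
              format_percent(x$g), format_percent(x$a), format_percent(x$t),
              format_percent(x$c), format_percent(x$gc), x$n_bases,
              if (x$n_excluded > 0) sprintf(" (%d N excluded)", x$n_excluded) else ""))
  invisible(x)
}

#' Nucleotide composition by region class
#'
#' Concatenates, per class, the protein-coding genes (coding strand), the
#' intergenic spacers (derived with [derive_spacers()] if the record carries
#' none), and the rRNA genes, and also reports the whole genome. Empty classes
#' are omitted with a warning.
#'
#' @param record a [genome_record()].
#' @return data.frame with columns region_class, g, a, t, c, gc (percent,
#'   unrounded), n_bases.
#' @export
composition_by_region <- function(record) {
  spacers <- Filter(function(f) f$ftype == "spacer", record$features)
  if (length(spacers) == 0L) spacers <- derive_spacers(record)
  pull <- function(feats, use_strand = FALSE) {
    paste(vapply(feats, function(f) {
      nt <- paste(vapply(f$segments, function(s)
        substr(record$sequence, s[1] + 1L, s[2]), character(1)), collapse = "")
      if (use_strand && f$strand == "-") reverse_complement(nt) else nt
    }, character(1)), collapse = "")
  }
  classes <- list(
    protein_coding = pull(Filter(function(f) f$ftype == "CDS", record$features), TRUE),
    noncoding = pull(spacers),
    rRNA = pull(Filter(function(f) f$ftype == "rRNA", record$features), TRUE),
    whole = record$sequence)
  rows <- list()
  for (cls in names(classes)) {
    s <- classes[[cls]]
    if (!nzchar(s)) {
      warning("region class '", cls, "' is empty; omitted", call. = FALSE)
      next
    }
    b <- base_composition(s)
    rows[[cls]] <- data.frame(region_class = cls, g = b$g, a = b$a, t = b$t,
                              c = b$c, gc = b$gc, n_bases = b$n_bases,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Normalize a CDS set to a character vector of in-frame nucleotide strings.
as_cds_strings <- function(cds_set) {
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  vapply(seq_along(cds_set), function(i) {
    x <- cds_set[[i]]
    nt <- if (inherits(x, "coding_sequence")) x$nucleotides else toupper(x)
    nm <- if (inherits(x, "coding_sequence")) x$name
      else if (!is.null(names(cds_set))) names(cds_set)[i] else sprintf("seq %d", i)
    if (nchar(gsub("-", "", nt)) %% 3L != 0L)
      stop(sprintf("coding sequence '%s' length is not a multiple of 3", nm),
           call. = FALSE)
    nt
  }, character(1))
}

#' G+C content by codon position
#'
#' Pools codons across a set of in-frame coding sequences and reports percent
#' G+C at positions 1, 2 and 3. Stop codons are excluded by default (the usual
#' convention for GC3 over sense codons); codons containing N or gaps are
#' skipped.
#'
#' @param cds_set list of [coding_sequence()] objects and/or in-frame DNA
#'   strings, or a single such object/string.
#' @inheritParams genetic_code
#' @param include_stops count stop codons too (default FALSE).
#' @return list of class `positional_gc`: gc1, gc2, gc3 (percent, unrounded),
#'   n_codons.
#' @export
gc_by_codon_position <- function(cds_set, code_id = 4, include_stops = FALSE) {
  nts <- as_cds_strings(cds_set)
  cods <- unlist(lapply(nts, split_codons), use.names = FALSE)
  cods <- cods[!grepl("[^ACGT]", cods)]
  if (!include_stops) cods <- cods[!cods %in% stop_codons(code_id)]
  if (length(cods) == 0L) stop("no scorable codons", call. = FALSE)
  gc_at <- function(k) {
    b <- substr(cods, k, k)
    100 * mean(b %in% c("G", "C"))
  }
  structure(list(gc1 = gc_at(1), gc2 = gc_at(2), gc3 = gc_at(3),
                 n_codons = length(cods)),
            class = "positional_gc")
}

#' @export
print.positional_gc <- function(x, ...) {
  cat(sprintf("GC1 %s  GC2 %s  GC3 %s (%% over %d codons)\n",
              format_percent(x$gc1), format_percent(x$gc2),
              format_percent(x$gc3), x$n_codons))
  invisible(x)
}

#' Amino-acid composition
#'
#' Percent of each of the 20 amino acids over all residues of a protein set.
#' `*` and `X` residues are excluded from the denominator.
#'
#' @param proteins character vector of amino-acid strings.
#' @return named numeric vector (20 amino acids, one-letter, alphabetical)
#'   of percents; attribute `n_residues` carries the denominator.
#' @export
aa_composition <- function(proteins) {
  aas <- strsplit(paste(toupper(proteins), collapse = ""), "")[[1]]
  levels20 <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  aas <- aas[aas %in% levels20]
  if (length(aas) == 0L) stop("no residues to score", call. = FALSE)
  counts <- table(factor(aas, levels = levels20))
  out <- 100 * as.numeric(counts) / length(aas)
  names(out) <- levels20
  attr(out, "n_residues") <- length(aas)
  out
}
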