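#' Six-frame open-reading-frame scan
#'
#' Scans both strands in all three frames under the active genetic code. In
#' `stop_to_stop` mode an ORF is a maximal run of stop-free codons (no start
#' codon required -- ciliate mitochondrial start codons are nonstandard); in
#' `start_required` mode the call begins at the first start codon (from a
#' configurable start set) inside such a run. Calls are reported in genome
#' coordinates (0-based half-open, minus-strand calls on the forward axis),
#' sorted by start; overlapping calls in different frames or strands are all
#' reported.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @inheritParams genetic_code
#' @param min_aa minimum ORF length in amino acids (default 60, i.e. ">= 60").
#' @param mode `"stop_to_stop"` (default) or `"start_required"`.
#' @param starts start-codon set used in `start_required` mode.
#' @return data.frame with columns start, end, strand, frame (0-2), length_aa,
#'   mode. The stop codon itself is not part of the call.
#' @export
find_orfs <- function(sequence, code_id = 4, min_aa = 60,
                      mode = c("stop_to_stop", "start_required"),
                      starts = c("ATG", "ATA", "ATT", "TTG", "GTG")) {
  mode <- match.arg(mode)
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_aa = integer(0), mode = character(0),
                      stringsAsFactors = FALSE)
  if (L < 3L) {
    warning("sequence shorter than one codon; no ORFs", call. = FALSE)
    return(empty)
  }
  stops <- stop_codons(code_id)
  calls <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else reverse_complement(sequence)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3L
      if (n_cod == 0L) next
      cods <- substring(s, frame + 3L * seq_len(n_cod) - 2L, frame + 3L * seq_len(n_cod))
      is_stop <- cods %in% stops
      # codons containing N can hide a stop; treat them as run breakers
      is_stop <- is_stop | grepl("N", cods, fixed = TRUE)
      r <- rle(!is_stop)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      for (k in which(r$values)) {
        a <- run_start[k]; b <- run_end[k]
        if (mode == "start_required") {
          hit <- which(cods[a:b] %in% starts)
          if (length(hit) == 0L) next
          a <- a + hit[1] - 1L
        }
        len_aa <- b - a + 1L
        if (len_aa < min_aa) next
        # coordinates on the scanned strand
        i0 <- frame + 3L * (a - 1L)      # 0-based start on scanned strand
        i1 <- frame + 3L * b             # 0-based half-open end
        if (strand == "+") {
          g0 <- i0; g1 <- i1
        } else {
          g0 <- L - i1; g1 <- L - i0
        }
        calls[[length(calls) + 1L]] <- data.frame(
          start = g0, end = g1, strand = strand, frame = frame,
          length_aa = len_aa, mode = mode, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$start, out$end, out$strand, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge a set of [start, end) intervals (matrix with columns start, end).
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Derive intergenic spacers
#'
#' Merges all annotated gene intervals (overlaps collapsed: a spacer is
#' non-genic DNA) and reports the maximal gaps between them as spacer
#' features. Gaps flanking the first and last gene of a linear record are
#' included, so merged genes plus spacers tile the genome exactly.
#'
#' @param record a [genome_record()].
#' @return list of spacer [feature()]s (zero-length gaps omitted).
#' @export
derive_spacers <- function(record) {
  genes <- Filter(function(f) f$ftype != "spacer", record$features)
  iv <- merge_intervals(vapply(genes, function(f) f$start, integer(1)),
                        vapply(genes, function(f) f$end, integer(1)))
  bounds <- c(0L, as.vector(t(iv)), record$length)
  gaps_s <- bounds[seq(1L, length(bounds), by = 2L)]
  gaps_e <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- gaps_e > gaps_s
  mapply(function(s, e, i) feature(sprintf("spacer_%d", i), "spacer", s, e,
                                   gene_class = "noncoding"),
         gaps_s[keep], gaps_e[keep], seq_len(sum(keep)), SIMPLIFY = FALSE)
}

#' Coding-density bookkeeping
#'
#' Summarises how much of the genome is annotated: coding bases (all annotated
#' genes including RNA genes, overlaps merged), protein-coding bases (CDS
#' only), the corresponding fractions, and the derived spacer lengths.
#'
#' @param record a [genome_record()].
#' @return list of class `coding_summary`: total_bp, coding_bp,
#'   protein_coding_bp, coding_fraction, protein_coding_fraction (fractions in
#'   \[0,1\]), spacer_lengths (integer vector).
#' @export
coding_summary <- function(record) {
  genes <- Filter(function(f) f$ftype != "spacer", record$features)
  all_iv <- merge_intervals(vapply(genes, function(f) f$start, integer(1)),
                            vapply(genes, function(f) f$end, integer(1)))
  cds <- Filter(function(f) f$ftype == "CDS", genes)
  cds_iv <- merge_intervals(vapply(cds, function(f) f$start, integer(1)),
                            vapply(cds, function(f) f$end, integer(1)))
  coding_bp <- sum(all_iv[, "end"] - all_iv[, "start"])
  protein_bp <- sum(cds_iv[, "end"] - cds_iv[, "start"])
  spacers <- derive_spacers(record)
  structure(list(
    total_bp = record$length,
    coding_bp = as.integer(coding_bp),
    protein_coding_bp = as.integer(protein_bp),
    coding_fraction = coding_bp / record$length,
    protein_coding_fraction = protein_bp / record$length,
    spacer_lengths = vapply(spacers, function(f) f$end - f$start, integer(1))
  ), class = "coding_summary")
}

#' @export
print.coding_summary <- function(x, ...) {
  cat(sprintf("total %d bp; coding %d bp (%s%%); protein-coding %d bp (%s%%); %d spacers (%s bp)\n",
              x$total_bp, x$coding_bp, format_percent(100 * x$coding_fraction),
              x$protein_coding_bp, format_percent(100 * x$protein_coding_fraction),
              length(x$spacer_lengths),
              if (length(x$spacer_lengths)) paste0(min(x$spacer_lengths), "-", max(x$spacer_lengths)) else "0"))
  invisible(x)
}
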