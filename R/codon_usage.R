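#' Count codons over a set of coding sequences
#'
#' Counts all 64 codons of the in-frame sequences. Stop codons are counted
#' (they form their own family in the usage profile); codons containing N are
#' skipped and tallied.
#'
#' @inheritParams gc_by_codon_position
#' @param scope label for the table ("genome", or a gene name).
#' @return object of class `codon_count_table`: `counts` (named integer vector
#'   over the 64 codons), `code_id`, `scope`, `n_skipped`.
#' @export
count_codons <- function(cds_set, code_id = 4, scope = "genome") {
  nts <- as_cds_strings(cds_set)
  cods <- unlist(lapply(nts, split_codons), use.names = FALSE)
  skip <- grepl("[^ACGT]", cods)
  counts <- table(factor(cods[!skip], levels = all_codons()))
  structure(list(counts = stats::setNames(as.integer(counts), all_codons()),
                 code_id = code_id, scope = scope,
                 n_skipped = as.integer(sum(skip))),
            class = "codon_count_table")
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(sprintf("<codon_count_table> %s: %d codons scored (code %s%s)\n",
              x$scope, sum(x$counts), as.character(x$code_id),
              if (x$n_skipped > 0) sprintf(", %d skipped", x$n_skipped) else ""))
  invisible(x)
}

# Family membership for a code, with the stop codons as an extra "Stop" family.
families_with_stop <- function(code_id) {
  fam <- synonymous_families(code_id)
  st <- stop_codons(code_id)
  if (length(st)) fam$Stop <- st
  fam
}

#' Relative synonymous codon frequencies
#'
#' Within each amino-acid family of the active code (stop codons as their own
#' family), frequency = count / family total. Families with zero total have
#' undefined (NA) frequencies.
#'
#' @param table a [count_codons()] table.
#' @return object of class `usage_profile`: `table` (data.frame amino_acid,
#'   codon, count, frequency), `most_frequent` (named character vector, per
#'   amino acid), `code_id`, `scope`.
#' @export
relative_frequencies <- function(table) {
  if (!inherits(table, "codon_count_table")) stop("need a codon_count_table")
  if (sum(table$counts) == 0L) stop("empty codon count table", call. = FALSE)
  fam <- families_with_stop(table$code_id)
  rows <- lapply(names(fam), function(aa) {
    cods <- fam[[aa]]
    cnt <- table$counts[cods]
    tot <- sum(cnt)
    data.frame(amino_acid = aa, codon = cods, count = as.integer(cnt),
               frequency = if (tot > 0) as.numeric(cnt) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  mf <- vapply(split(tab, tab$amino_acid), function(d) {
    if (all(is.na(d$frequency))) NA_character_
    else d$codon[which.max(d$frequency)]
  }, character(1))
  structure(list(table = tab, most_frequent = mf,
                 code_id = table$code_id, scope = table$scope),
            class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> %s (code %s), %d amino-acid families\n",
              x$scope, as.character(x$code_id),
              length(unique(x$table$amino_acid))))
  invisible(x)
}

#' Classify rare codons
#'
#' Flags a codon as rare when its relative frequency within its synonymous
#' family is below `threshold`. Stop codons participate. The default threshold
#' (0.085 on the unrounded frequency, i.e. anything that prints as <= 0.08 at
#' two decimals) is a calibrated stand-in for the rare-codon convention used
#' in comparative codon-usage tables; it is a configuration value.
#'
#' @param profile a [relative_frequencies()] profile, or a named numeric
#'   vector of within-family relative frequencies keyed by codon (useful for
#'   published frequency columns).
#' @param threshold rare iff frequency < threshold.
#' @inheritParams genetic_code
#' @return list: `rare_codons` (character vector), `rare_count`, `threshold`.
#' @export
classify_rare <- function(profile, threshold = 0.085, code_id = 4) {
  if (inherits(profile, "usage_profile")) {
    freqs <- stats::setNames(profile$table$frequency, profile$table$codon)
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    freqs <- profile
  } else stop("profile must be a usage_profile or a named frequency vector")
  freqs <- freqs[!is.na(freqs)]
  rare <- names(freqs)[freqs < threshold]
  list(rare_codons = rare, rare_count = length(rare), threshold = threshold)
}

# Per-family codon homozygosity F-hat = (n * sum(p^2) - 1) / (n - 1).
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  if (f <= 0) NA_real_ else f
}

# Shared aggregation for the effective number of codons: given per-family
# F values (NA = unusable) and family sizes, apply Wright's averaging
# fallbacks and return Nc.
nc_aggregate <- function(f_by_family, sizes, code_id) {
  census <- degeneracy_census(code_id)
  ks <- as.integer(names(census))
  fbar <- stats::setNames(rep(NA_real_, length(ks)), names(census))
  for (k in ks[ks > 1]) {
    vals <- f_by_family[sizes == k & !is.na(f_by_family)]
    if (length(vals)) fbar[as.character(k)] <- mean(vals)
  }
  # Wright's rule: a missing 3-fold class borrows the mean of the 2- and
  # 4-fold classes.
  if ("3" %in% names(fbar) && is.na(fbar[["3"]]) &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  contrib <- numeric(0)
  codons_avail <- 0L
  total_sense <- sum(ks * census)
  absent <- character(0)
  for (i in seq_along(ks)) {
    k <- ks[i]; nk <- census[i]
    if (k == 1) {
      contrib <- c(contrib, nk)
      codons_avail <- codons_avail + nk
    } else if (!is.na(fbar[[as.character(k)]])) {
      contrib <- c(contrib, nk / fbar[[as.character(k)]])
      codons_avail <- codons_avail + k * nk
    } else {
      absent <- c(absent, as.character(k))
    }
  }
  if (codons_avail == 0L) stop("no usable codon families", call. = FALSE)
  nc <- sum(contrib)
  if (length(absent)) {
    # whole degeneracy class absent: rescale by the class's census share
    nc <- nc * total_sense / codons_avail
    warning("degeneracy class(es) ", paste(absent, collapse = ", "),
            " unobserved; Nc rescaled by census share", call. = FALSE)
  }
  nc <- min(nc, total_sense)  # cap at the code's sense-codon count
  attr(nc, "fallback_classes") <- absent
  nc
}

#' Wright's effective number of codons (Nc)
#'
#' Nc summarises codon-usage bias: it equals the number of amino-acid families
#' (20 under code 4) when exactly one codon is used per amino acid, and the
#' code's sense-codon count (62 under code 4, where Trp is a two-codon family)
#' when all synonymous codons are used equally. Per family the codon
#' homozygosity is F = (n * sum(p^2) - 1)/(n - 1); Nc sums, per
#' degeneracy-class k of the code's census, N_k / mean(F_k), with single-codon
#' families added directly. Families with n <= 1 or F <= 0 fall back to the
#' class mean; a fully absent class is handled by Wright's averaging rule (for
#' the 3-fold class) or by rescaling by the class's census share, with a
#' warning. The result is capped at the sense-codon count.
#'
#' @param table a [count_codons()] table.
#' @return Nc as a single numeric; attribute `fallback_classes` lists any
#'   degeneracy classes that required rescaling.
#' @export
effective_number_of_codons <- function(table) {
  if (!inherits(table, "codon_count_table")) stop("need a codon_count_table")
  fam <- synonymous_families(table$code_id)
  sizes <- vapply(fam, length, integer(1))
  f <- vapply(fam, function(cods) family_homozygosity(table$counts[cods]),
              numeric(1))
  if (sum(table$counts[unlist(fam)]) == 0L)
    stop("empty codon count table", call. = FALSE)
  nc_aggregate(f, sizes, table$code_id)
}

#' Nc from published relative frequencies (large-n limit)
#'
#' For a column of within-family relative frequencies (as printed in
#' comparative codon-usage tables), the large-n limit of the family
#' homozygosity is simply sum(p^2); frequencies are renormalised within each
#' family to absorb rounding. Stop codons are ignored.
#'
#' @param freqs named numeric vector: codon -> relative frequency within its
#'   amino-acid family. NA entries (unused families) are allowed.
#' @inheritParams genetic_code
#' @return Nc as a single numeric.
#' @export
nc_from_frequencies <- function(freqs, code_id = 4) {
  fam <- synonymous_families(code_id)
  sizes <- vapply(fam, length, integer(1))
  f <- vapply(fam, function(cods) {
    p <- freqs[cods]
    p <- p[!is.na(p)]
    if (length(p) == 0L || sum(p) <= 0) return(NA_real_)
    p <- p / sum(p)
    sum(p^2)
  }, numeric(1))
  if (all(is.na(f))) stop("no usable frequencies", call. = FALSE)
  nc_aggregate(f, sizes, code_id)
}
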