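#' Genetic-code utilities
#'
#' The pipeline works under NCBI translation tables, defaulting to table 4
#' (mold/protozoan mitochondrial: TGA = Trp, stops TAA/TAG), the code used by
#' ciliate mitochondria. The code id is always a parameter; nothing downstream
#' hard-codes a particular table.
#'
#' @param code_id NCBI translation table number (integer or string), e.g. 1
#'   (standard) or 4 (mold/protozoan mitochondrial).
#' @return `genetic_code()`: a named character vector mapping each of the 64
#'   codons (DNA alphabet) to a one-letter amino acid, with `"*"` for stops.
#' @examples
#' gc4 <- genetic_code(4)
#' gc4[["TGA"]]  # "W" under the mold/protozoan mitochondrial code
#' @export
genetic_code <- function(code_id = 4) {
  code <- Biostrings::getGeneticCode(as.character(code_id))
  # Biostrings returns RNA-alphabet names for some tables; normalize to DNA
  names(code) <- chartr("U", "T", names(code))
  code[order(names(code))]
}

#' @rdname genetic_code
#' @return `all_codons()`: the 64 codons in lexicographic order.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' @rdname genetic_code
#' @return `stop_codons()` / `sense_codons()`: character vectors of codons.
#' @export
stop_codons <- function(code_id = 4) {
  code <- genetic_code(code_id)
  names(code)[code == "*"]
}

#' @rdname genetic_code
#' @export
sense_codons <- function(code_id = 4) {
  code <- genetic_code(code_id)
  names(code)[code != "*"]
}

#' Synonymous codon families of a genetic code
#'
#' Groups the sense codons of a code by encoded amino acid. Under code 4 the
#' Trp family is {TGA, TGG}, so the code has 62 sense codons in families of
#' sizes 1, 2, 3, 4 and 6.
#'
#' @inheritParams genetic_code
#' @return Named list: amino acid -> character vector of its codons.
#' @export
synonymous_families <- function(code_id = 4) {
  code <- genetic_code(code_id)
  sense <- code[code != "*"]
  split(names(sense), unname(sense))
}

#' Degeneracy census of a genetic code
#'
#' Counts how many amino-acid families have each synonymous-family size. The
#' census drives the generalised effective-number-of-codons computation: under
#' code 4 it is N1=1, N2=10, N3=1, N4=5, N6=3 (62 sense codons), so the
#' theoretical Nc maximum is 62 rather than the standard-code 61.
#'
#' @inheritParams genetic_code
#' @return Named integer vector: family size (as name) -> number of families.
#' @export
degeneracy_census <- function(code_id = 4) {
  fam <- synonymous_families(code_id)
  sizes <- vapply(fam, length, integer(1))
  tab <- table(sizes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Split an in-frame DNA string into codons (trailing partial codon dropped).
split_codons <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate an in-frame DNA string
#'
#' Codons containing N translate to `X`; a trailing partial codon is dropped.
#'
#' @param nt in-frame DNA string.
#' @inheritParams genetic_code
#' @return amino-acid string with `*` for stop codons.
#' @export
translate_dna <- function(nt, code_id = 4) {
  cods <- split_codons(nt)
  if (length(cods) == 0L) return("")
  code <- genetic_code(code_id)
  aa <- code[cods]
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  paste0(aa, collapse = "")
}

# Validate a DNA string: A/C/G/T plus N allowed; anything else is an error.
check_dna <- function(sequence, what = "sequence") {
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("%s contains unsupported characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  sequence
}
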