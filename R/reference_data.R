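#' Bundled comparative reference tables
#'
#' Small published reference tables for the three-way ciliate mitochondrial
#' genome comparison (*T. pyriformis*, *P. caudatum*, *P. tetraurelia*),
#' shipped as plain TSV under `inst/extdata/` and used as inputs by tests and
#' the acceptance script.
#'
#' `reference_codon_usage()` returns the within-family relative synonymous
#' codon frequencies per species (columns `T_pyriformis`, `P_caudatum`,
#' `P_tetraurelia`), one row per codon including the stop family.
#'
#' `reference_gene_stats()` returns the per-gene comparison between
#' *P. caudatum* and *P. tetraurelia*: gene name, gene class (`known` gene vs
#' unknown `orf`), protein length in aa, pairwise protein identity, and the
#' Ka/Ks ratio (`NA` where the pair was not alignable).
#'
#' @return a data.frame (see above).
#' @export
reference_codon_usage <- function() {
  utils::read.delim(system.file("extdata", "ciliate_codon_usage.tsv",
                                package = "mitocomp"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_codon_usage
#' @export
reference_gene_stats <- function() {
  utils::read.delim(system.file("extdata", "paramecium_gene_stats.tsv",
                                package = "mitocomp"),
                    stringsAsFactors = FALSE)
}

#' Load GenBank accessions fetched by the helper script
#'
#' The package never touches the network; `scripts/fetch_accessions.R` can
#' download the study accessions into the package's `extdata/accessions/`
#' directory when network access is available. This accessor loads one of
#' them, or returns `NULL` when the record has not been fetched.
#'
#' @param accession accession string, e.g. `"FN424190"`.
#' @return a [genome_record()], or NULL when the flat file is absent.
#' @export
load_accession <- function(accession) {
  path <- system.file("extdata", "accessions", paste0(accession, ".gb"),
                      package = "mitocomp")
  if (!nzchar(path)) return(NULL)
  read_genbank(path)
}
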