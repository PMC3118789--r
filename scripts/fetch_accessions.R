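#!/usr/bin/env Rscript
# Optional network helper: download the study accessions as GenBank flat files
# into the installed package's extdata/accessions/ directory so that the
# accession-based tests can run. The package library itself never touches the
# network. Usage: Rscript scripts/fetch_accessions.R [dest_dir]

accs <- c("FN424190", "NC001324", "NC000862")
args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args)) args[1] else
  file.path(system.file("extdata", package = "mitocomp"), "accessions")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (acc in accs) {
  url <- sprintf("%s?db=nuccore&id=%s&rettype=gb&retmode=text", base, acc)
  out <- file.path(dest, paste0(acc, ".gb"))
  message("fetching ", acc, " -> ", out)
  utils::download.file(url, out, quiet = TRUE)
  Sys.sleep(0.4)  # NCBI rate limit
}
message("done; reinstall the package or point load_accession() at ", dest)
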