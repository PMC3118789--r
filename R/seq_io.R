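#' Genome features
#'
#' A `Feature` is a typed, stranded interval on a genome in 0-based half-open
#' coordinates (the GenBank reader converts from 1-based inclusive at the
#' boundary). Multi-segment (join) locations keep their segments; `start`/`end`
#' are the overall span. Each feature carries a `gene_class` used throughout
#' the pipeline: `known` (annotated gene of known function), `orf` (unknown
#' open reading frame, ymf-style), `rna` (rRNA/tRNA) or `noncoding` (spacers).
#'
#' @param name gene label, e.g. `"cox1"` or `"ymf64"`.
#' @param ftype one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"spacer"`.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param gene_class one of `"known"`, `"orf"`, `"rna"`, `"noncoding"`;
#'   `NULL` to infer from `name`/`ftype` (ymf* -> orf, rRNA/tRNA -> rna,
#'   other CDS -> known, spacer -> noncoding).
#' @param segments optional list of `c(start, end)` pairs (genome order) for
#'   join locations; defaults to the single `[start, end)` span.
#' @param partial logical; TRUE when the record marks the feature as partial
#'   at either boundary, which suspends the CDS length-multiple-of-3 check.
#' @return an object of class `mito_feature`.
#' @export
feature <- function(name, ftype, start, end, strand = "+", gene_class = NULL,
                    segments = NULL, partial = FALSE) {
  ftype <- match.arg(ftype, c("CDS", "rRNA", "tRNA", "spacer"))
  strand <- match.arg(strand, c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop(sprintf("feature '%s': invalid interval [%s, %s)", name, start, end),
         call. = FALSE)
  if (is.null(segments)) segments <- list(c(start, end))
  if (is.null(gene_class)) {
    gene_class <- if (ftype %in% c("rRNA", "tRNA")) "rna"
      else if (ftype == "spacer") "noncoding"
      else if (grepl("^ymf", name, ignore.case = TRUE)) "orf"
      else "known"
  }
  gene_class <- match.arg(gene_class, c("known", "orf", "rna", "noncoding"))
  seg_len <- sum(vapply(segments, function(s) s[2] - s[1], numeric(1)))
  if (ftype == "CDS" && !partial && seg_len %% 3L != 0L)
    stop(sprintf("CDS feature '%s' has length %d, not a multiple of 3 (and is not flagged partial)",
                 name, as.integer(seg_len)), call. = FALSE)
  structure(list(name = name, ftype = ftype, start = start, end = end,
                 strand = strand, gene_class = gene_class,
                 segments = segments, partial = partial),
            class = "mito_feature")
}

#' Genome records
#'
#' A `GenomeRecord` bundles a (typically linear) genome sequence with its
#' ordered feature table. Ciliate mitochondrial genomes are linear, 40-47 kb,
#' and densely gene-packed; the container itself is agnostic.
#'
#' @param id accession-like identifier.
#' @param sequence DNA string over A/C/G/T/N (uppercased on construction).
#' @param features list of [feature()] objects; sorted by start on construction.
#' @param topology `"linear"` or `"circular"`.
#' @return an object of class `genome_record` with fields `id`, `sequence`,
#'   `topology`, `length`, `features`.
#' @export
genome_record <- function(id, sequence, features = list(),
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence, sprintf("record '%s'", id))
  len <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "mito_feature")) stop("features must be built with feature()")
    if (f$end > len)
      stop(sprintf("feature '%s' end %d exceeds genome length %d (integrity error)",
                   f$name, f$end, len), call. = FALSE)
  }
  ord <- order(vapply(features, function(f) f$start, numeric(1)))
  structure(list(id = id, sequence = sequence, topology = topology,
                 length = len, features = features[ord]),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cls <- table(vapply(x$features, function(f) f$gene_class, character(1)))
  cat(sprintf("<genome_record> %s: %s, %d bp, %d features (%s)\n",
              x$id, x$topology, x$length, length(x$features),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Feature table as a data frame
#'
#' @param record a [genome_record()].
#' @return data.frame with columns name, ftype, start, end, strand, gene_class,
#'   partial (0-based half-open coordinates).
#' @export
feature_table <- function(record) {
  f <- record$features
  data.frame(
    name = vapply(f, `[[`, character(1), "name"),
    ftype = vapply(f, `[[`, character(1), "ftype"),
    start = vapply(f, function(x) x$start, integer(1)),
    end = vapply(f, function(x) x$end, integer(1)),
    strand = vapply(f, `[[`, character(1), "strand"),
    gene_class = vapply(f, `[[`, character(1), "gene_class"),
    partial = vapply(f, `[[`, logical(1), "partial"),
    stringsAsFactors = FALSE)
}

# ---- GenBank flat-file dialect -------------------------------------------
# Only LOCUS / FEATURES / ORIGIN blocks are required; of the qualifiers only
# /gene and /product are used. Locations: n, a..b, join(...), complement(...)
# and partiality markers < and >.

parse_location <- function(loc, fname) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  partial <- grepl("[<>]", loc)
  segs <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p); b <- a
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      a <- ab[1]; b <- ab[2]
    } else {
      stop(sprintf("malformed location '%s' in feature '%s'", p, fname),
           call. = FALSE)
    }
    c(a - 1L, b)  # 1-based inclusive -> 0-based half-open
  })
  list(strand = strand, segments = segs, partial = partial,
       start = min(vapply(segs, `[`, numeric(1), 1)),
       end = max(vapply(segs, `[`, numeric(1), 2)))
}

format_location <- function(f) {
  seg_str <- vapply(f$segments, function(s) {
    if (s[2] - s[1] == 1L) as.character(s[2]) else sprintf("%d..%d", s[1] + 1L, s[2])
  }, character(1))
  loc <- if (length(seg_str) > 1L) sprintf("join(%s)", paste(seg_str, collapse = ",")) else seg_str
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Read a GenBank flat file
#'
#' Parses the LOCUS line, the FEATURES table (CDS/rRNA/tRNA keys) and the
#' ORIGIN sequence block into a [genome_record()]. Coordinates are converted
#' from GenBank 1-based inclusive to internal 0-based half-open;
#' `join`/`complement` locations are resolved; gene classes are assigned
#' (ymf* names to `orf`, rRNA/tRNA to `rna`, remaining CDS to `known`).
#'
#' @param path file path.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  id <- toks[2]
  stated_len <- suppressWarnings(as.integer(toks[toks != "bp"][3]))
  topology <- if (any(grepl("circular", locus[1]))) "circular" else "linear"

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("not a GenBank flat file: no ORIGIN block", call. = FALSE)
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ostart[1] + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (length(fstart)) {
    tbl <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # a new feature starts with a key in columns 6-20
    is_key <- grepl("^ {5}\\S", tbl)
    idx <- which(is_key)
    for (i in seq_along(idx)) {
      block <- tbl[idx[i]:(if (i < length(idx)) idx[i + 1L] - 1L else length(tbl))]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (!key %in% c("CDS", "rRNA", "tRNA")) next
      # location may continue over lines until the first /qualifier
      rest <- c(sub("^ {5}\\S+\\s*", "", block[1]), trimws(block[-1]))
      qual_at <- grep("^/", rest)
      loc_str <- paste(rest[seq_len(if (length(qual_at)) qual_at[1] - 1L else length(rest))],
                       collapse = "")
      quals <- rest[grepl("^/", rest)]
      get_qual <- function(q) {
        hit <- grep(sprintf("^/%s=", q), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        gsub('"', "", sub(sprintf("^/%s=", q), "", hit[1]))
      }
      name <- get_qual("gene")
      if (is.na(name)) name <- get_qual("product")
      if (is.na(name)) name <- sprintf("%s_%d", key, i)
      loc <- parse_location(loc_str, name)
      features[[length(features) + 1L]] <-
        feature(name, ftype = key, start = loc$start, end = loc$end,
                strand = loc$strand, segments = loc$segments,
                partial = loc$partial)
    }
  }
  rec <- genome_record(id, sequence, features, topology)
  if (!is.na(stated_len) && stated_len != rec$length)
    stop(sprintf("record '%s': LOCUS length %d != sequence length %d (integrity error)",
                 id, stated_len, rec$length), call. = FALSE)
  rec
}

#' Write a GenBank flat file
#'
#' Emits the minimal LOCUS/FEATURES/ORIGIN dialect read by [read_genbank()];
#' the two functions round-trip a record's feature table field by field.
#'
#' @param record a [genome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                     record$id, record$length, record$topology), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in record$features) {
    if (f$ftype == "spacer") next
    writeLines(sprintf("     %-16s%s", f$ftype, format_location(f)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, record$length, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, record$length))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read and write FASTA
#'
#' `read_fasta()` returns sequences in file order, uppercased, as a named
#' character vector; duplicate ids are an error. `write_fasta()` writes a
#' named character vector (or the list returned by `read_fasta`) with a
#' configurable wrap width. Gap characters (`-`) are preserved, so aligned
#' FASTA round-trips.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    if (all(!nzchar(trimws(lines)))) {
      warning("empty FASTA file: ", path, call. = FALSE)
      return(stats::setNames(character(0), character(0)))
    }
    stop("not a FASTA file (no '>' header): ", path, call. = FALSE)
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    toupper(gsub("[[:space:]]", "", paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")))
  }, character(1))
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param records named character vector of sequences.
#' @param width line-wrap width in characters.
#' @export
write_fasta <- function(records, path, width = 70) {
  records <- unlist(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Extract and translate a coding sequence
#'
#' Concatenates the feature's segments (genome order), reverse-complements
#' minus-strand features, and translates under the given genetic code. A
#' trailing stop codon is detected and flagged; an internal stop is an error
#' (it signals a wrong frame or wrong code).
#'
#' @param record a [genome_record()].
#' @param feat a CDS [feature()] from that record.
#' @inheritParams genetic_code
#' @return object of class `coding_sequence`: list with `name`, `nucleotides`
#'   (in-frame, coding strand, stop retained if annotated), `protein`
#'   (stop excluded), `code_id`, `trailing_stop` flag.
#' @export
extract_cds <- function(record, feat, code_id = 4) {
  if (feat$ftype != "CDS") stop("extract_cds requires a CDS feature", call. = FALSE)
  nt <- paste(vapply(feat$segments, function(s)
    substr(record$sequence, s[1] + 1L, s[2]), character(1)), collapse = "")
  if (feat$strand == "-") nt <- reverse_complement(nt)
  coding_sequence(feat$name, nt, code_id)
}

#' @rdname extract_cds
#' @param name gene label.
#' @param nucleotides in-frame DNA string on the coding strand.
#' @export
coding_sequence <- function(name, nucleotides, code_id = 4) {
  nucleotides <- check_dna(nucleotides, sprintf("CDS '%s'", name))
  aa <- translate_dna(nucleotides, code_id)
  n_aa <- nchar(aa)
  trailing_stop <- n_aa > 0L && substr(aa, n_aa, n_aa) == "*"
  protein <- if (trailing_stop) substr(aa, 1L, n_aa - 1L) else aa
  internal <- regexpr("*", protein, fixed = TRUE)
  if (internal > 0L)
    stop(sprintf("CDS '%s': internal stop codon at codon %d under code %s (wrong frame or wrong genetic code?)",
                 name, as.integer(internal), as.character(code_id)), call. = FALSE)
  structure(list(name = name, nucleotides = nucleotides, protein = protein,
                 code_id = code_id, trailing_stop = trailing_stop),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt, %d aa (code %s%s)\n", x$name,
              nchar(x$nucleotides), nchar(x$protein), as.character(x$code_id),
              if (x$trailing_stop) ", trailing stop" else ""))
  invisible(x)
}
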