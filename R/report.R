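# Tiny stable checksum (FNV-1a, 32-bit) for provenance headers.
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # 32-bit FNV-1a in doubles (bitwXor cannot take values >= 2^31)
  mul32 <- function(a, b) {
    (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- mul32(h, 16777619)
  }
  sprintf("%08x", h)
}

default_config <- function() {
  list(code_id = 4, min_aa = 60, rare_threshold = 0.085,
       repeat_min_unit = 6, repeat_max_unit = 100, repeat_min_copies = 3,
       repeat_min_identity = 0.8, boot_reps = 2000, seed = 1)
}

write_tsv_report <- function(df, path, config, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mitocomp %s  config=%s",
                       as.character(utils::packageVersion("mitocomp")),
                       config_hash(config)),
               sprintf("# %s", extra)[length(extra) > 0]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare two annotated genomes end to end
#'
#' Orchestrates the pipeline for two annotated genomes: per-gene protein
#' identity and NG86 Ka/Ks for genes shared by name (case-insensitive, with an
#' optional alias map), the gene-class contrast (means + Mann-Whitney),
#' composition by region class for both genomes, and side-by-side codon usage
#' with rare-codon and Nc summary rows. With `out_dir` set, the three tables
#' are written as TSV (`table_divergence.tsv`, `table_composition.tsv`,
#' `table_codon_usage.tsv`) with provenance headers; reruns with equal config
#' are byte-identical.
#'
#' @param genome_a,genome_b [genome_record()] objects with named CDS features.
#' @param config list of thresholds (see `default_config()`); missing entries
#'   take defaults.
#' @param out_dir optional output directory for the TSV tables.
#' @param aliases optional named character vector mapping gene names in
#'   `genome_b` to names in `genome_a`.
#' @return list of class `compare_report`: `divergence` (data.frame),
#'   `class_summary`, `composition`, `usage` (data.frame), `nc`, `rare`,
#'   `config`.
#' @export
run_compare <- function(genome_a, genome_b, config = list(), out_dir = NULL,
                        aliases = NULL) {
  config <- utils::modifyList(default_config(), config)
  cds_of <- function(g) Filter(function(f) f$ftype == "CDS", g$features)
  fa <- cds_of(genome_a); fb <- cds_of(genome_b)
  names_a <- vapply(fa, `[[`, character(1), "name")
  names_b <- vapply(fb, `[[`, character(1), "name")
  key_b <- tolower(names_b)
  if (!is.null(aliases)) {
    hit <- match(key_b, tolower(names(aliases)))
    key_b[!is.na(hit)] <- tolower(aliases[hit[!is.na(hit)]])
  }
  shared <- intersect(tolower(names_a), key_b)
  if (length(shared) == 0L)
    stop("no shared gene names between genomes; A has {",
         paste(names_a, collapse = ", "), "}, B has {",
         paste(names_b, collapse = ", "), "}", call. = FALSE)

  rows <- lapply(shared, function(nm) {
    A <- extract_cds(genome_a, fa[[match(nm, tolower(names_a))]], config$code_id)
    B <- extract_cds(genome_b, fb[[match(nm, key_b)]], config$code_id)
    kk <- ng86_kaks(A, B)
    al <- codon_align(A, B)
    data.frame(gene = A$name, gene_class = fa[[match(nm, tolower(names_a))]]$gene_class,
               length_aa = nchar(A$protein), identity = al$identity,
               ka = kk$ka, ks = kk$ks, ratio = kk$ratio,
               aligned_codons = kk$n_codons, stringsAsFactors = FALSE)
  })
  div <- do.call(rbind, rows)
  div <- div[order(match(div$gene_class, c("known", "orf")), div$gene), ]
  rownames(div) <- NULL
  cls <- if (length(unique(div$gene_class)) > 1 &&
             sum(is.finite(div$ratio)) >= 2) class_summary(div) else NULL

  comp <- do.call(rbind, lapply(list(genome_a, genome_b), function(g) {
    d <- composition_by_region(g)
    d$genome <- g$id
    d
  }))

  usage_of <- function(g) {
    cds <- lapply(Filter(function(f) f$ftype == "CDS", g$features),
                  function(f) extract_cds(g, f, config$code_id))
    tab <- count_codons(cds, config$code_id, scope = g$id)
    prof <- relative_frequencies(tab)
    list(profile = prof,
         nc = as.numeric(effective_number_of_codons(tab)),
         rare = classify_rare(prof, config$rare_threshold)$rare_count)
  }
  ua <- usage_of(genome_a); ub <- usage_of(genome_b)
  usage <- ua$profile$table[, c("amino_acid", "codon")]
  usage[[genome_a$id]] <- ua$profile$table$frequency
  usage[[genome_b$id]] <- ub$profile$table$frequency

  out <- structure(list(
    divergence = div, class_summary = cls, composition = comp, usage = usage,
    nc = stats::setNames(c(ua$nc, ub$nc), c(genome_a$id, genome_b$id)),
    rare = stats::setNames(c(ua$rare, ub$rare), c(genome_a$id, genome_b$id)),
    config = config), class = "compare_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fmt <- function(x, d = 4) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = d))
    div_out <- div
    for (cc in c("identity", "ka", "ks", "ratio")) div_out[[cc]] <- fmt(div_out[[cc]])
    extra <- if (!is.null(cls))
      sprintf("class means: %s; Mann-Whitney z = %.2f (p = %.3g)",
              paste(sprintf("%s %.3f (n=%d)", names(cls$means), cls$means, cls$n),
                    collapse = ", "),
              cls$test$z, cls$test$p_two_sided) else character(0)
    write_tsv_report(div_out, file.path(out_dir, "table_divergence.tsv"),
                     config, extra)
    comp_out <- comp
    for (cc in c("g", "a", "t", "c", "gc")) comp_out[[cc]] <- fmt(comp_out[[cc]], 1)
    write_tsv_report(comp_out, file.path(out_dir, "table_composition.tsv"), config)
    usage_out <- usage
    for (cc in c(genome_a$id, genome_b$id)) usage_out[[cc]] <- fmt(usage_out[[cc]], 2)
    write_tsv_report(usage_out, file.path(out_dir, "table_codon_usage.tsv"), config,
                     sprintf("rare: %s=%d %s=%d; Nc: %s=%.1f %s=%.1f",
                             genome_a$id, out$rare[1], genome_b$id, out$rare[2],
                             genome_a$id, out$nc[1], genome_b$id, out$nc[2]))
  }
  out
}

#' @export
print.compare_report <- function(x, ...) {
  cat(sprintf("<compare_report> %d shared genes; Nc %s; rare %s\n",
              nrow(x$divergence),
              paste(sprintf("%s=%.1f", names(x$nc), x$nc), collapse = " "),
              paste(sprintf("%s=%d", names(x$rare), x$rare), collapse = " ")))
  if (!is.null(x$class_summary))
    cat(sprintf("  Ka/Ks means: %s; z = %.2f\n",
                paste(sprintf("%s %.3f", names(x$class_summary$means),
                              x$class_summary$means), collapse = ", "),
                x$class_summary$test$z))
  invisible(x)
}
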