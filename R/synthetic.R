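# Run `expr` under a local, seeded RNG stream; the caller's RNG state is
# untouched. All generators route their randomness through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for the generators", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Default amino-acid frequencies for simulated mitochondrial proteins:
# hydrophobic/AT-rich-proteome flavour typical of organellar genomes.
default_aa_freq <- function() {
  c(A = 0.05, C = 0.01, D = 0.03, E = 0.04, F = 0.08, G = 0.05, H = 0.02,
    I = 0.09, K = 0.08, L = 0.10, M = 0.03, N = 0.07, P = 0.04, Q = 0.03,
    R = 0.03, S = 0.08, T = 0.05, V = 0.06, W = 0.01, Y = 0.05)
}

#' Specification for the synthetic genome generator
#'
#' The defaults emulate a linear, densely gene-packed ciliate-style
#' mitochondrial genome: ~20 protein-coding genes (a quarter of them unknown
#' ymf-style ORFs), two rRNA genes, intergenic spacers of 0-85 bp, an AT-rich
#' noncoding composition, an AT-ending codon-usage profile (the bundled
#' *P. caudatum*-like reference column), and one imperfect 18-bp tandem repeat
#' of nine copies embedded mid-ORF.
#'
#' @param n_genes number of protein-coding genes.
#' @param orf_fraction fraction of protein-coding genes labelled as unknown
#'   ORFs (ymf-style names).
#' @param gene_length_aa range (min, max) of protein lengths in amino acids.
#' @param n_rrna number of rRNA genes.
#' @param rrna_length_bp range of rRNA gene lengths.
#' @param spacer_bp range (min, max) of intergenic spacer lengths.
#' @param noncoding_freq base frequencies (A, C, G, T) of noncoding DNA.
#' @param usage codon-usage profile: named numeric vector codon ->
#'   within-family relative frequency; defaults to the bundled P. caudatum-like
#'   column.
#' @param aa_freq amino-acid sampling frequencies for simulated proteins.
#' @param repeat_unit_bp,repeat_copies,repeat_sub_rate the embedded intragenic
#'   minisatellite: unit length (multiple of 3), copy number, per-base
#'   substitution rate between adjacent copies.
#' @param minus_strand_prob probability that a gene is placed on the minus
#'   strand.
#' @inheritParams genetic_code
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20, orf_fraction = 0.25,
                           gene_length_aa = c(60, 600),
                           n_rrna = 2, rrna_length_bp = c(900, 1500),
                           spacer_bp = c(0, 85),
                           noncoding_freq = c(A = 0.357, C = 0.073,
                                              G = 0.080, T = 0.490),
                           usage = NULL, aa_freq = default_aa_freq(),
                           repeat_unit_bp = 18, repeat_copies = 9,
                           repeat_sub_rate = 0.04,
                           minus_strand_prob = 0.3, code_id = 4) {
  if (is.null(usage)) {
    ref <- reference_codon_usage()
    usage <- stats::setNames(ref$P_caudatum, ref$codon)
  }
  if (repeat_unit_bp %% 3L != 0L)
    stop("repeat_unit_bp must be a multiple of 3 to stay in frame", call. = FALSE)
  structure(list(n_genes = n_genes, orf_fraction = orf_fraction,
                 gene_length_aa = gene_length_aa, n_rrna = n_rrna,
                 rrna_length_bp = rrna_length_bp, spacer_bp = spacer_bp,
                 noncoding_freq = noncoding_freq, usage = usage,
                 aa_freq = aa_freq, repeat_unit_bp = repeat_unit_bp,
                 repeat_copies = repeat_copies,
                 repeat_sub_rate = repeat_sub_rate,
                 minus_strand_prob = minus_strand_prob, code_id = code_id),
            class = "synthetic_spec")
}

# Sample one in-frame coding sequence (no internal stops, no trailing stop)
# from an amino-acid distribution and a within-family codon-usage profile.
sample_cds <- function(n_aa, aa_freq, usage, code_id) {
  fam <- synonymous_families(code_id)
  aa_freq <- aa_freq[names(aa_freq) %in% names(fam)]
  aas <- sample(names(aa_freq), n_aa, replace = TRUE, prob = aa_freq)
  cods <- vapply(aas, function(aa) {
    cands <- fam[[aa]]
    w <- usage[cands]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, length(cands))
    sample(cands, 1, prob = w)
  }, character(1))
  paste0(cods, collapse = "")
}

sample_noncoding <- function(n, freq) {
  if (n == 0L) return("")
  paste0(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

# Mutate a DNA string at a per-base rate, rejecting mutations that create an
# in-frame stop codon (frame anchored at position 1 of `nt`).
mutate_inframe <- function(nt, rate, code_id) {
  chars <- strsplit(nt, "")[[1]]
  stops <- stop_codons(code_id)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    cod_i <- (i - 1L) %/% 3L
    cod <- chars[(cod_i * 3L + 1L):(cod_i * 3L + 3L)]
    cod[(i - 1L) %% 3L + 1L] <- alt
    if (paste0(cod, collapse = "") %in% stops) next
    chars[i] <- alt
  }
  paste0(chars, collapse = "")
}

#' Simulate a genome with known ground truth
#'
#' Builds a linear genome from the spec: protein-coding genes sampled from the
#' codon-usage profile (stop-free, terminated by TAA), rRNA genes and spacers
#' sampled from the noncoding composition, and one designated ORF carrying an
#' imperfect in-frame tandem-repeat array near its middle. Every feature,
#' class and target is recorded in a machine-readable truth ledger.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (mandatory; same seed, byte-identical output).
#' @return list: `record` (a [genome_record()]) and `truth` (list with
#'   `features` data.frame, `coding` totals, `repeat_locus`, `spec`, `seed`).
#' @export
simulate_genome <- function(spec = synthetic_spec(), seed) {
  with_seed(seed, {
    n_orf <- max(1L, round(spec$n_genes * spec$orf_fraction))
    n_known <- spec$n_genes - n_orf
    known_names <- c("cox1", "cob", "cox2", "nad1", "nad2", "nad3", "nad4",
                     "nad5", "nad7", "rps3", "rps12", "rpl2", "rpl6", "atp9",
                     "nad6", "nad9", "rps13", "rps14", "rpl14", "rpl16",
                     "nad10", "nad4L", "yejR", "rps19", "cox3")
    gene_names <- c(known_names[seq_len(min(n_known, length(known_names)))],
                    if (n_known > length(known_names))
                      sprintf("gene%d", seq_len(n_known - length(known_names))),
                    sprintf("ymf%d", 55 + seq_len(n_orf)))
    repeat_host <- sprintf("ymf%d", 55 + n_orf)  # last ORF hosts the array

    # per-gene pieces
    pieces <- list()
    for (nm in gene_names) {
      n_aa <- sample(spec$gene_length_aa[1]:spec$gene_length_aa[2], 1)
      nt <- sample_cds(n_aa, spec$aa_freq, spec$usage, spec$code_id)
      pieces[[nm]] <- list(type = "CDS", nt = nt)
    }
    # embed the repeat mid-gene, at a codon boundary
    rep_truth <- NULL
    host <- pieces[[repeat_host]]$nt
    unit <- sample_cds(spec$repeat_unit_bp / 3L, spec$aa_freq, spec$usage,
                       spec$code_id)
    copies <- vapply(seq_len(spec$repeat_copies), function(i)
      if (i == 1) unit else mutate_inframe(unit, spec$repeat_sub_rate, spec$code_id),
      character(1))
    array_nt <- paste0(copies, collapse = "")
    at_codon <- (nchar(host) / 3L) %/% 2L
    pieces[[repeat_host]]$nt <- paste0(substr(host, 1, 3 * at_codon), array_nt,
                                       substr(host, 3 * at_codon + 1, nchar(host)))
    pieces[[repeat_host]]$repeat_offset <- 3L * at_codon
    for (i in seq_len(spec$n_rrna)) {
      n <- sample(spec$rrna_length_bp[1]:spec$rrna_length_bp[2], 1)
      pieces[[sprintf("rn%s", c("s", "l", "x")[min(i, 3)])]] <-
        list(type = "rRNA", nt = sample_noncoding(n, spec$noncoding_freq))
    }
    ord <- sample(names(pieces))

    seqs <- character(0)
    feats <- list()
    pos <- 0L
    truth_rows <- list()
    rep_genome <- NULL
    add_spacer <- function(pos) {
      n <- sample(spec$spacer_bp[1]:spec$spacer_bp[2], 1)
      if (n > 0) sample_noncoding(n, spec$noncoding_freq) else ""
    }
    for (nm in ord) {
      sp <- add_spacer(pos)
      seqs <- c(seqs, sp)
      pos <- pos + nchar(sp)
      p <- pieces[[nm]]
      nt <- if (p$type == "CDS") paste0(p$nt, "TAA") else p$nt
      strand <- if (p$type == "CDS" &&
                    stats::runif(1) < spec$minus_strand_prob) "-" else "+"
      genome_nt <- if (strand == "-") reverse_complement(nt) else nt
      start <- pos; end <- pos + nchar(nt)
      feats[[length(feats) + 1L]] <- feature(nm, p$type, start, end, strand)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        name = nm, ftype = p$type, start = start, end = end, strand = strand,
        stringsAsFactors = FALSE)
      if (!is.null(p$repeat_offset)) {
        # array coordinates on the genome axis
        a_local <- p$repeat_offset
        b_local <- a_local + nchar(array_nt)
        rep_genome <- if (strand == "+") c(start + a_local, start + b_local)
          else c(end - b_local, end - a_local)
      }
      seqs <- c(seqs, genome_nt)
      pos <- pos + nchar(nt)
    }
    sp <- add_spacer(pos)
    seqs <- c(seqs, sp)
    sequence <- paste0(seqs, collapse = "")

    record <- genome_record("synthetic_mt", sequence, feats, "linear")
    feats_df <- do.call(rbind, truth_rows)
    iv <- merge_intervals(feats_df$start, feats_df$end)
    coding_bp <- sum(iv[, "end"] - iv[, "start"])
    cds_df <- feats_df[feats_df$ftype == "CDS", ]
    list(record = record,
         truth = list(
           features = feats_df,
           coding = list(total_bp = nchar(sequence), coding_bp = coding_bp,
                         protein_coding_bp = sum(cds_df$end - cds_df$start),
                         coding_fraction = coding_bp / nchar(sequence)),
           repeat_locus = list(gene = repeat_host,
                               start = rep_genome[1], end = rep_genome[2],
                               unit_bp = spec$repeat_unit_bp,
                               copies = spec$repeat_copies),
           spec = spec, seed = seed))
  })
}

#' Evolve a codon sequence pair with a known omega
#'
#' From an ancestral coding sequence, evolves two lineages for an expected
#' `t_syn`/2 synonymous substitutions per synonymous site each. Candidate
#' substitutions arise uniformly per site (Poisson number of proposals);
#' a candidate is rejected if it creates a stop codon, accepted with
#' probability 1 if synonymous and `omega` otherwise — so the realised
#' nonsynonymous/synonymous rate ratio is `omega` by construction.
#'
#' @param cds a [coding_sequence()] or in-frame stop-free DNA string.
#' @param t_syn expected synonymous substitutions per synonymous site between
#'   the two resulting sequences.
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @inheritParams genetic_code
#' @param seed integer seed.
#' @return list: `a`, `b` (DNA strings), `truth` (realised synonymous /
#'   nonsynonymous substitution counts per lineage).
#' @export
evolve_pair <- function(cds, t_syn, omega, code_id = 4, seed) {
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  nt <- if (inherits(cds, "coding_sequence"))
    substr(cds$nucleotides, 1, 3 * nchar(cds$protein)) else toupper(cds)
  if (inherits(cds, "coding_sequence")) code_id <- cds$code_id
  code <- genetic_code(code_id)
  with_seed(seed, {
    evolve_one <- function(nt, t) {
      chars <- strsplit(nt, "")[[1]]
      L <- length(chars)
      n_prop <- stats::rpois(1, t * L)
      syn <- 0L; nonsyn <- 0L
      for (k in seq_len(n_prop)) {
        i <- sample.int(L, 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
        c0 <- (i - 1L) %/% 3L
        cod <- paste0(chars[(c0 * 3L + 1L):(c0 * 3L + 3L)], collapse = "")
        newcod <- cod
        substr(newcod, (i - 1L) %% 3L + 1L, (i - 1L) %% 3L + 1L) <- alt
        if (code[[newcod]] == "*") next
        if (code[[newcod]] == code[[cod]]) {
          chars[i] <- alt; syn <- syn + 1L
        } else if (stats::runif(1) < omega) {
          chars[i] <- alt; nonsyn <- nonsyn + 1L
        }
      }
      list(nt = paste0(chars, collapse = ""), syn = syn, nonsyn = nonsyn)
    }
    # proposals per lineage: Poisson(t_syn/2 * L); a fraction S/L of uniform
    # proposals is synonymous, giving ~t_syn/2 synonymous subs per syn site
    ea <- evolve_one(nt, t_syn / 2)
    eb <- evolve_one(nt, t_syn / 2)
    list(a = ea$nt, b = eb$nt,
         truth = list(omega = omega, t_syn = t_syn,
                      syn = c(ea$syn, eb$syn), nonsyn = c(ea$nonsyn, eb$nonsyn)))
  })
}

#' Simulate a coding alignment on a tree with a clade GC3 shift
#'
#' Evolves in-frame codon sequences site-independently down a tree under a
#' Jukes-Cantor process, except that third codon positions draw replacement
#' bases from a biased equilibrium: a background G+C share everywhere, and a
#' high G+C share inside the designated clade. On the clade's stem edge every
#' third position is redrawn from the high-GC equilibrium, modelling a
#' compositional shift on that edge. Substitutions creating in-frame stop
#' codons are rejected.
#'
#' @param tree a `phylo` tree or newick string, with branch lengths in
#'   expected substitutions/site.
#' @param n_codons alignment length in codons.
#' @param clade character vector of tip labels forming the high-GC3 clade
#'   (NULL for no shift).
#' @param gc3_high,gc3_background target third-position G+C percentages.
#' @inheritParams genetic_code
#' @param seed integer seed.
#' @return list: `alignment` (named character vector, in frame), `truth`
#'   (tree, clade, targets, seed).
#' @export
simulate_alignment <- function(tree, n_codons = 300, clade = NULL,
                               gc3_high = 48, gc3_background = 10,
                               code_id = 4, seed) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (gc3_high > 100 || gc3_background > 100 || gc3_high < 0 || gc3_background < 0)
    stop("GC3 targets must be percentages in [0, 100]", call. = FALSE)
  stops <- stop_codons(code_id)
  eq3 <- function(gc) c(A = (1 - gc / 100) / 2, C = gc / 100 / 2,
                        G = gc / 100 / 2, T = (1 - gc / 100) / 2)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    L <- 3L * n_codons
    third <- seq(3L, L, by = 3L)
    draw_codon <- function(freq3) {
      repeat {
        cod <- c(sample(bases, 2, replace = TRUE),
                 sample(bases, 1, prob = freq3))
        if (!paste0(cod, collapse = "") %in% stops) return(cod)
      }
    }
    root <- unlist(lapply(seq_len(n_codons), function(i)
      draw_codon(eq3(gc3_background))))

    in_clade_node <- rep(FALSE, max(tree$edge))
    stem_child <- NA_integer_
    if (!is.null(clade)) {
      if (!all(clade %in% tree$tip.label))
        stop("clade tips not in tree", call. = FALSE)
      mrca <- if (length(clade) == 1L) match(clade, tree$tip.label)
        else ape::getMRCA(tree, clade)
      stem_child <- mrca
      # nodes at/below the MRCA
      kids <- mrca
      repeat {
        more <- tree$edge[tree$edge[, 1] %in% kids, 2]
        new <- setdiff(more, kids)
        if (length(new) == 0L) break
        kids <- c(kids, new)
      }
      in_clade_node[kids] <- TRUE
    }

    mutate_seq <- function(chars, t, freq3) {
      n_events <- stats::rpois(length(chars), t)
      for (i in which(n_events > 0)) {
        for (k in seq_len(n_events[i])) {
          alt <- if (i %% 3L == 0L) sample(bases, 1, prob = freq3)
            else sample(bases, 1)
          if (alt == chars[i]) next
          c0 <- (i - 1L) %/% 3L
          cod <- chars[(c0 * 3L + 1L):(c0 * 3L + 3L)]
          cod[(i - 1L) %% 3L + 1L] <- alt
          if (paste0(cod, collapse = "") %in% stops) next
          chars[i] <- alt
        }
      }
      chars
    }

    nt_tips <- length(tree$tip.label)
    root_node <- nt_tips + 1L
    seqs <- vector("list", max(tree$edge))
    seqs[[root_node]] <- root
    out <- stats::setNames(vector("character", nt_tips), tree$tip.label)
    # preorder traversal
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (k in seq_len(nrow(edges))) {
      parent <- edges[k, 1]; child <- edges[k, 2]
      high <- in_clade_node[child]
      freq3 <- eq3(if (high) gc3_high else gc3_background)
      s <- seqs[[parent]]
      if (!is.na(stem_child) && child == stem_child) {
        # compositional shift: redraw third positions at the stem
        for (i in third) {
          c0 <- (i - 1L) %/% 3L
          repeat {
            alt <- sample(bases, 1, prob = freq3)
            cod <- s[(c0 * 3L + 1L):(c0 * 3L + 3L)]
            cod[3] <- alt
            if (!paste0(cod, collapse = "") %in% stops) break
          }
          s[i] <- alt
        }
      }
      s <- mutate_seq(s, lens[k], freq3)
      if (child <= nt_tips) out[tree$tip.label[child]] <- paste0(s, collapse = "")
      else seqs[[child]] <- s
    }
    list(alignment = out,
         truth = list(tree = tree, clade = clade, gc3_high = gc3_high,
                      gc3_background = gc3_background, seed = seed))
  })
}

#' Simulate a strain set sharing a repeat locus
#'
#' Builds one sequence per strain: shared flanking anchors around a tandem
#' array whose copy number varies by strain (default: the copy numbers
#' observed across P. caudatum strains at the ymf64 minisatellite).
#'
#' @param copy_numbers named or unnamed integer vector of per-strain copy
#'   numbers.
#' @param unit_bp repeat unit length.
#' @param flank_bp length of the shared flanking anchors.
#' @param sub_rate per-base substitution rate applied to each unit copy.
#' @param seed integer seed.
#' @return list: `sequences` (named character vector), `truth` (unit, copy
#'   numbers).
#' @export
simulate_strain_set <- function(copy_numbers = c(a = 18, b = 11, c = 11, d = 9,
                                                 e = 9, f = 14, g = 10),
                                unit_bp = 18, flank_bp = 150, sub_rate = 0.02,
                                seed = 1) {
  if (is.null(names(copy_numbers)))
    names(copy_numbers) <- paste0("strain", seq_along(copy_numbers))
  with_seed(seed, {
    freq <- c(A = 0.39, C = 0.11, G = 0.11, T = 0.39)
    unit <- sample_noncoding(unit_bp, freq)
    left <- sample_noncoding(flank_bp, freq)
    right <- sample_noncoding(flank_bp, freq)
    seqs <- vapply(copy_numbers, function(k) {
      arr <- paste0(vapply(seq_len(k), function(i)
        mutate_inframe(unit, sub_rate, 4), character(1)), collapse = "")
      paste0(left, arr, right)
    }, character(1))
    list(sequences = seqs,
         truth = list(unit = unit, copy_numbers = copy_numbers,
                      flank_bp = flank_bp, seed = seed))
  })
}
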