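#' Kimura two-parameter distance
#'
#' With transition proportion P and transversion proportion Q over the
#' pairwise-comparable sites (positions with gap or N in either sequence are
#' excluded, i.e. pairwise deletion): d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#'
#' @param a,b equal-length aligned DNA strings.
#' @return distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites", call. = FALSE)
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  p <- sum(transition) / n
  q <- sum(diff & !transition) / n
  if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0)
    stop("K2P distance saturated (log argument <= 0)", call. = FALSE)
  -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln named character vector of equal-length aligned DNA strings.
#' @param model `"K2P"` (default), `"JC"` or `"raw"` (p-distance); JC and raw
#'   use pairwise deletion as well.
#' @return symmetric numeric matrix with taxa as dimnames and zero diagonal.
#' @export
dist_matrix <- function(aln, model = c("K2P", "JC", "raw")) {
  model <- match.arg(model)
  n <- length(aln)
  taxa <- names(aln)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  pdist <- function(a, b) {
    ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
    ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    mean(ca[ok] != cb[ok])
  }
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- switch(model,
      K2P = k2p_distance(aln[[i]], aln[[j]]),
      JC = {
        p <- pdist(aln[[i]], aln[[j]])
        if (p >= 0.75) stop("JC distance saturated", call. = FALSE)
        -0.75 * log(1 - 4 * p / 3)
      },
      raw = pdist(aln[[i]], aln[[j]]))
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (exact on additive
#' distances). Negative branch lengths are clamped to zero and the clamped
#' total recorded in the `"clamped"` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  clamped <- sum(-tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree per replicate with the same distance model, and reports for each
#' internal bipartition of the full-data tree the percentage of replicates
#' containing it (stored in `node.label`).
#'
#' @inheritParams dist_matrix
#' @param n_reps number of pseudoreplicates.
#' @param seed integer seed; the run is reproducible per seed.
#' @param model distance model passed to [dist_matrix()].
#' @return the full-data `phylo` tree with `node.label` set to support
#'   percentages (NA for the root "bipartition").
#' @export
bootstrap_nj <- function(aln, n_reps = 2000, seed = 1, model = "K2P") {
  if (length(aln) < 4L) stop("bootstrap support needs at least 4 taxa", call. = FALSE)
  len <- unique(nchar(aln))
  if (length(len) != 1L) stop("alignment rows must have equal length", call. = FALSE)
  if (len < 1L) stop("alignment has no columns", call. = FALSE)
  full <- neighbor_joining(dist_matrix(aln, model))
  if (max(dist_matrix(aln, "raw")) == 0)
    warning("all sequences identical: no resolved bipartitions", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste0, collapse = "")
    names(rep_aln) <- names(aln)
    boots[[r]] <- neighbor_joining(dist_matrix(rep_aln, model))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  full$node.label <- round(100 * counts / n_reps, 1)
  attr(full, "n_reps") <- n_reps
  attr(full, "seed") <- seed
  full
}

#' Positional G+C per taxon of a coding alignment
#'
#' For each taxon of an in-frame coding alignment, percent G+C at codon
#' positions 1-3 over its gap-free codons. GC3 is the most neutrally evolving
#' signal and tracks compositional pressure across the tree.
#'
#' @param aln named character vector: in-frame aligned coding sequences
#'   (length a multiple of 3).
#' @inheritParams genetic_code
#' @return data.frame: taxon, gc1, gc2, gc3 (percent), n_codons.
#' @export
gc3_by_taxon <- function(aln, code_id = 4) {
  out <- lapply(names(aln), function(tx) {
    s <- aln[[tx]]
    if (nchar(s) %% 3L != 0L)
      stop(sprintf("taxon '%s': alignment length %d is not a multiple of 3",
                   tx, nchar(s)), call. = FALSE)
    cods <- split_codons(s)
    cods <- cods[!grepl("[^ACGT]", cods)]
    gc <- gc_by_codon_position(paste0(cods, collapse = ""), code_id)
    data.frame(taxon = tx, gc1 = gc$gc1, gc2 = gc$gc2, gc3 = gc$gc3,
               n_codons = gc$n_codons, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Tip sets below each edge of a phylo tree (list indexed by edge row).
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(nt)) desc[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k)
    sort(desc[[tree$edge[k, 2]]]))
}

#' Place a compositional (GC3) shift on a tree
#'
#' Taxa with GC3 at or above `cut` form the high set. If that set is exactly
#' one side of a single edge of the tree, that edge is the placement of the
#' shift; otherwise the high set is not monophyletic and a flag is returned.
#'
#' @param tree a `phylo` tree.
#' @param gc3 named numeric vector of per-taxon GC3 percents covering all tips.
#' @param cut GC3 threshold in (0, 100).
#' @return list: `high_taxa`, `monophyletic` (logical), `edge` (edge-matrix
#'   row index or NA), `split` (the tip labels on the high side, or NULL).
#' @export
place_shift <- function(tree, gc3, cut) {
  if (!is.numeric(cut) || cut <= 0 || cut >= 100)
    stop("cut must be inside (0, 100)", call. = FALSE)
  tips <- tree$tip.label
  if (!all(tips %in% names(gc3)))
    stop("gc3 values missing for: ",
         paste(setdiff(tips, names(gc3)), collapse = ", "), call. = FALSE)
  high <- tips[gc3[tips] >= cut]
  if (length(high) == 0L || length(high) == length(tips))
    return(list(high_taxa = high, monophyletic = FALSE, edge = NA_integer_,
                split = NULL))
  sets <- edge_tip_sets(tree)
  high_idx <- sort(match(high, tips))
  hit <- which(vapply(sets, function(s)
    identical(s, high_idx) || identical(sort(setdiff(seq_along(tips), s)), high_idx),
    logical(1)))
  if (length(hit) >= 1L) {
    list(high_taxa = high, monophyletic = TRUE, edge = hit[1], split = high)
  } else {
    list(high_taxa = high, monophyletic = FALSE, edge = NA_integer_, split = NULL)
  }
}
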