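# Ungapped identity between two equal-length character vectors.
hamming_identity <- function(u, v) mean(u == v)

# Grow a tandem array at period d anchored at position a (0-based): extend
# right/left unit-by-unit while adjacent full units keep identity >= min_id,
# then extend both boundaries base-by-base on exact lag-d matches (fractional
# head/tail copies). Returns c(start, end), 0-based half-open.
extend_array <- function(chars, d, a, min_id) {
  L <- length(chars)
  unit <- function(x) chars[(x + 1):(x + d)]
  b <- a + d
  while (b + d <= L && hamming_identity(unit(b), unit(b - d)) >= min_id) b <- b + d
  while (b < L && chars[b + 1] == chars[b + 1 - d]) b <- b + 1L
  while (a - d >= 0 && hamming_identity(unit(a - d), unit(a)) >= min_id) a <- a - d
  while (a > 0 && chars[a] == chars[a + d]) a <- a - 1L
  c(a, b)
}

# Majority consensus of the full units of an array.
consensus_unit <- function(chars, d, a, b) {
  k <- (b - a) %/% d
  m <- matrix(chars[a + seq_len(k * d)], nrow = d)
  apply(m, 1, function(col) names(which.max(table(col))))
}

# Smallest p such that `unit` is a perfect tandem repetition of its first p
# characters (p divides length(unit)); length(unit) if irreducible. Reported
# units are primitive: calls reducible below min_unit are suppressed.
primitive_period <- function(unit) {
  d <- length(unit)
  for (p in seq_len(d - 1)) {
    if (d %% p == 0L && all(unit == rep(unit[1:p], d %/% p))) return(p)
  }
  d
}

# Score an array: adjacent-unit identities and copy number.
score_array <- function(chars, d, a, b) {
  k <- (b - a) %/% d
  ids <- if (k >= 2) vapply(seq_len(k - 1), function(i)
    hamming_identity(chars[(a + (i - 1) * d + 1):(a + i * d)],
                     chars[(a + i * d + 1):(a + (i + 1) * d)]), numeric(1))
    else numeric(0)
  list(copy_number = (b - a) / d,
       mean_identity = if (length(ids)) mean(ids) else 1)
}

#' Detect intragenic tandem repeats (minisatellites)
#'
#' Seed-and-extend detector for tandem arrays with unit lengths in
#' `[min_unit, max_unit]`: exact matches at lag d (seed length chosen so that
#' any adjacent unit pair at `min_identity` must contain one) seed candidate
#' arrays, which are extended unit-by-unit while the ungapped identity between
#' adjacent units stays at or above `min_identity`, with fractional head/tail
#' copies taken on exact matches. Calls are reduced to their primitive period
#' (a unit that is itself a perfect tandem of a shorter unit is re-evaluated
#' at that shorter period); calls whose primitive unit falls below `min_unit`
#' (homopolymer and microsatellite runs) are suppressed, overlapping nested
#' calls are merged in favour of the smaller period, and calls with fewer
#' than `min_copies` copies are dropped.
#'
#' @param sequence DNA string.
#' @param min_unit,max_unit search range of unit lengths (bp).
#' @param min_copies minimum copy number of a reported call.
#' @param min_identity minimum ungapped identity between adjacent units.
#' @return data.frame with columns start, end (0-based half-open),
#'   unit_length, copy_number (fractional copies allowed), mean_identity,
#'   consensus, frame_preserving; sorted by start.
#' @export
find_tandem_repeats <- function(sequence, min_unit = 6, max_unit = 100,
                                min_copies = 3, min_identity = 0.8) {
  if (min_unit > max_unit) stop("min_unit > max_unit", call. = FALSE)
  if (min_unit < 1) stop("min_unit must be >= 1", call. = FALSE)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), copy_number = numeric(0),
                      mean_identity = numeric(0), consensus = character(0),
                      frame_preserving = logical(0), stringsAsFactors = FALSE)
  if (L < min_unit * min_copies) return(empty)

  spans <- list()  # per candidate: c(d, start, end)
  for (d in seq.int(min_unit, min(max_unit, L %/% 2))) {
    m <- chars[seq_len(L - d)] == chars[(d + 1):L]
    # any adjacent unit pair at min_identity must contain an exact match run
    # of this length (pigeonhole over its <= floor((1-id)*d) mismatches)
    mm <- floor((1 - min_identity) * d)
    k_seed <- max(1L, as.integer(ceiling((d - mm) / (mm + 1))))
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_at <- starts[r$values & r$lengths >= k_seed]
    if (length(seed_at) == 0L) next
    cs <- c(0, cumsum(m))
    pair_id <- function(a) (cs[a + d + 1L] - cs[a + 1L]) / d  # unit(a) vs unit(a+d)
    seen <- list()
    for (i in seed_at) {
      a0 <- i - 1L  # 0-based position of seed start
      # the seed sits inside some adjacent unit pair; try every phase anchor
      anchors <- max(0L, a0 - d + 1L):min(a0, L - 2L * d)
      for (a in anchors) {
        if (pair_id(a) < min_identity) next
        covered <- any(vapply(seen, function(sp)
          a >= sp[1] && a + 2L * d <= sp[2] && (a - sp[1]) %% d == 0L,
          logical(1)))
        if (covered) next
        sp <- extend_array(chars, d, a, min_identity)
        seen[[length(seen) + 1L]] <- sp
        spans[[length(spans) + 1L]] <- c(d, sp)
      }
    }
  }
  if (length(spans) == 0L) return(empty)

  # primitive-period reduction, re-extended at the reduced period
  calls <- list()
  for (sp in spans) {
    d <- sp[1]; a <- sp[2]; b <- sp[3]
    if ((b - a) %/% d >= 1L) {
      cons <- consensus_unit(chars, d, a, b)
      p <- primitive_period(cons)
      if (p < d) {
        d <- p
        sp2 <- extend_array(chars, d, a, min_identity)
        a <- sp2[1]; b <- sp2[2]
        cons <- consensus_unit(chars, d, a, b)
      }
    } else next
    # the unit range is a reporting contract: arrays whose primitive unit
    # falls below min_unit (homopolymer and microsatellite runs) are dropped
    if (d < min_unit) next
    sc <- score_array(chars, d, a, b)
    if (sc$copy_number < min_copies) next
    calls[[length(calls) + 1L]] <- data.frame(
      start = a, end = b, unit_length = d, copy_number = sc$copy_number,
      mean_identity = sc$mean_identity,
      consensus = paste0(cons, collapse = ""),
      frame_preserving = d %% 3L == 0L, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(empty)
  out <- unique(do.call(rbind, calls))
  out <- out[order(out$start, out$unit_length), , drop = FALSE]

  # merge overlapping calls: where two calls overlap by more than half the
  # shorter span, keep the smaller period (ties: larger span)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[j]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
      shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
      if (ov > shorter / 2) {
        drop <- if (out$unit_length[i] != out$unit_length[j]) {
          if (out$unit_length[i] < out$unit_length[j]) j else i
        } else {
          if (out$end[i] - out$start[i] >= out$end[j] - out$start[j]) j else i
        }
        keep[drop] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reading-frame preservation of a repeat unit
#'
#' A tandem array inside a coding sequence leaves the reading frame intact
#' under copy-number variation exactly when its unit length is a multiple of
#' three.
#'
#' @param call a row (or data.frame of rows) from [find_tandem_repeats()], or
#'   a numeric unit length.
#' @return logical vector.
#' @export
frame_preserving <- function(call) {
  u <- if (is.numeric(call)) call else call$unit_length
  u %% 3 == 0
}

#' Compare repeat copy numbers across strains
#'
#' Collates per-strain repeat calls at a homologous locus into a copy-number
#' table, with the range and the number of distinct length variants.
#'
#' @param calls named list: strain -> data.frame from [find_tandem_repeats()]
#'   (the first call is used; an empty data.frame marks the locus as absent).
#' @return list: `table` (data.frame strain, copy_number, unit_length; sorted
#'   by copy number, absent loci last with NA), `range`, `n_variants`.
#' @export
compare_strain_repeats <- function(calls) {
  rows <- lapply(names(calls), function(st) {
    d <- calls[[st]]
    if (is.null(d) || nrow(d) == 0L)
      return(data.frame(strain = st, copy_number = NA_real_,
                        unit_length = NA_integer_, stringsAsFactors = FALSE))
    data.frame(strain = st, copy_number = d$copy_number[1],
               unit_length = d$unit_length[1], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$copy_number, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  cn <- tab$copy_number[!is.na(tab$copy_number)]
  list(table = tab,
       range = if (length(cn)) range(cn) else c(NA_real_, NA_real_),
       n_variants = length(unique(round(cn))))
}
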