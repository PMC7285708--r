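# Seeded pairwise aligner for vOTU clustering and shared-content host links.
#
# The algorithm: exact k-mer anchors (default k = 15, unique in both
# sequences, N-free), grouped by diagonal; each anchored diagonal is scanned
# gaplessly with an x-drop rule (match +1, mismatch -2) to delimit
# high-scoring segments; segments from all diagonals are merged
# non-overlapping (highest score first, later segments trimmed on the first
# sequence). ANI is identities over aligned columns across merged segments;
# alignment fraction uses the shorter sequence as denominator. Ns never
# count as matches. Sequences shorter than k fall back to full dynamic
# programming, which is cheap at that size.

ANI_MATCH <- 1
ANI_MISMATCH <- -2

# x-drop segmentation of one diagonal. `m` is a logical match vector over
# the diagonal overlap; returns a matrix of [start, end] (1-based, inclusive,
# in overlap coordinates) of maximal high-scoring gapless segments.
xdrop_segments <- function(m, xdrop = 20) {
  sc <- ifelse(m, ANI_MATCH, ANI_MISMATCH)
  n <- length(sc)
  segs <- NULL
  i <- 1L
  while (i <= n) {
    # skip leading mismatches
    while (i <= n && !m[i]) i <- i + 1L
    if (i > n) break
    best <- 0; run <- 0; best_j <- i - 1L
    j <- i
    while (j <= n) {
      run <- run + sc[j]
      if (run > best) { best <- run; best_j <- j }
      if (run < best - xdrop) break
      j <- j + 1L
    }
    if (best > 0) segs <- rbind(segs, c(i, best_j))
    i <- best_j + 1L
    # after a drop, resume scanning beyond the failed extension
    if (j > best_j + 1L) i <- j + 1L
  }
  segs
}

# Gapless segments between two sequences in the given orientation.
# Returns a data.frame with a_start/a_end (1-based inclusive on `a`),
# diag, matches, len.
diagonal_segments <- function(a, b, k = 15, xdrop = 20) {
  na <- nchar(a); nb <- nchar(b)
  ka <- seq_kmers(a, k); kb <- seq_kmers(b, k)
  ok_a <- !grepl("N", ka, fixed = TRUE)
  ok_b <- !grepl("N", kb, fixed = TRUE)
  ua <- ok_a & !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- ok_b & !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  ia <- which(ua); ib <- which(ub)
  if (length(ia) == 0 || length(ib) == 0) return(NULL)
  hit <- match(kb[ib], ka[ia])
  keep <- !is.na(hit)
  if (!any(keep)) return(NULL)
  apos <- ia[hit[keep]]
  bpos <- ib[keep]
  diags <- apos - bpos
  out <- NULL
  for (d in unique(diags)) {
    # overlap of the two sequences along diagonal d (in a-coordinates)
    a_lo <- max(1L, 1L + d); a_hi <- min(na, nb + d)
    if (a_hi - a_lo + 1L < k) next
    m <- match_vector(substr(a, a_lo, a_hi), substr(b, a_lo - d, a_hi - d))
    segs <- xdrop_segments(m, xdrop)
    if (is.null(segs)) next
    anchors <- sort(apos[diags == d]) - a_lo + 1L   # anchor starts, overlap coords
    for (r in seq_len(nrow(segs))) {
      s <- segs[r, 1]; e <- segs[r, 2]
      # keep only segments supported by at least one anchor k-mer
      if (!any(anchors >= s - k + 1L & anchors <= e)) next
      out <- rbind(out, data.frame(
        a_start = a_lo + s - 1L, a_end = a_lo + e - 1L, diag = d,
        matches = sum(m[s:e]), len = e - s + 1L))
    }
  }
  out
}

# Merge segments non-overlapping on `a`: highest score first; overlapping
# parts of lower-scoring segments are trimmed away and their counts
# recomputed on the same diagonal.
merge_segments <- function(segs, a, b) {
  if (is.null(segs) || nrow(segs) == 0) return(NULL)
  segs$score <- segs$matches * ANI_MATCH + (segs$len - segs$matches) * ANI_MISMATCH
  segs <- segs[order(-segs$score, segs$a_start), , drop = FALSE]
  covered <- matrix(numeric(0), ncol = 2)
  kept <- NULL
  for (r in seq_len(nrow(segs))) {
    s <- segs$a_start[r]; e <- segs$a_end[r]; d <- segs$diag[r]
    # subtract already-covered intervals
    pieces <- list(c(s, e))
    if (nrow(covered) > 0) {
      for (cv in seq_len(nrow(covered))) {
        nxt <- list()
        for (p in pieces) {
          lo <- p[1]; hi <- p[2]
          clo <- covered[cv, 1]; chi <- covered[cv, 2]
          if (chi < lo || clo > hi) { nxt[[length(nxt) + 1]] <- p; next }
          if (clo > lo) nxt[[length(nxt) + 1]] <- c(lo, clo - 1)
          if (chi < hi) nxt[[length(nxt) + 1]] <- c(chi + 1, hi)
        }
        pieces <- nxt
        if (length(pieces) == 0) break
      }
    }
    for (p in pieces) {
      if (p[2] - p[1] + 1 < 15) next   # discard slivers below anchor size
      m <- match_vector(substr(a, p[1], p[2]), substr(b, p[1] - d, p[2] - d))
      kept <- rbind(kept, data.frame(a_start = p[1], a_end = p[2], diag = d,
                                     matches = sum(m), len = p[2] - p[1] + 1))
      covered <- rbind(covered, p)
    }
  }
  kept
}

# Full Needleman-Wunsch fallback for sequences shorter than the anchor size.
nw_stats <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sub <- ifelse(y == x[i] & x[i] != "N", match, mismatch)
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # traceback counting aligned (substitution) columns and identities
  i <- n; j <- m; cols <- 0L; ids <- 0L
  while (i > 0 && j > 0) {
    sub <- if (y[j] == x[i] && x[i] != "N") match else mismatch
    if (S[i + 1, j + 1] == S[i, j] + sub) {
      cols <- cols + 1L
      if (y[j] == x[i] && x[i] != "N") ids <- ids + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(matches = ids, len = cols)
}

#' Pairwise average nucleotide identity and alignment fraction
#'
#' Aligns two sequences with the package's seeded gapless aligner (see
#' Details) in both orientations and reports the statistics of the better
#' orientation: `ani`, identities over aligned columns across merged
#' segments; `af_small`, total aligned length over the length of the
#' shorter sequence; `aligned_len`; and the raw alignment `score`
#' (match +1, mismatch -2) used as the bit-score surrogate for
#' shared-content host links.
#'
#' @details Exact 15-mer anchors unique in both sequences seed gapless
#' diagonal scans delimited by an x-drop rule; segments are merged
#' non-overlapping, highest-scoring first. Ns never count as matches.
#' Sequences shorter than the anchor size are aligned by full dynamic
#' programming instead. The aligner is gapless by design: the package's
#' substitution-divergence model of sequence relatedness places homologous
#' regions on exact diagonals, and indel-containing pairs simply split into
#' several collinear segments.
#'
#' @param a,b DNA strings (A/C/G/T/N).
#' @param k Anchor k-mer size.
#' @param xdrop Score drop terminating a gapless extension.
#' @return One-row tibble: `ani`, `af_small`, `aligned_len`, `score`,
#'   `orientation` (`"+"` or `"-"`). When no anchored segment exists, `ani`
#'   and `af_small` are 0.
#' @examples
#' s <- paste(rep("ACGTTGCA", 40), collapse = "")
#' ani_pair(s, s)$ani
#' @export
ani_pair <- function(a, b, k = 15, xdrop = 20) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) abort("ani_pair: empty sequence")
  if (min(na, nb) < k) {
    fw <- nw_stats(a, b)
    rv <- nw_stats(a, revcomp(b))
    use <- if (rv$matches > fw$matches) list(st = rv, ori = "-") else list(st = fw, ori = "+")
    st <- use$st
    return(tibble(
      ani = if (st$len > 0) st$matches / st$len else 0,
      af_small = st$len / min(na, nb),
      aligned_len = st$len,
      score = st$matches * ANI_MATCH + (st$len - st$matches) * ANI_MISMATCH,
      orientation = use$ori))
  }
  stats_for <- function(bb) {
    segs <- merge_segments(diagonal_segments(a, bb, k, xdrop), a, bb)
    if (is.null(segs)) return(list(matches = 0, len = 0))
    list(matches = sum(segs$matches), len = sum(segs$len))
  }
  fw <- stats_for(b)
  rv <- stats_for(revcomp(b))
  sc <- function(st) st$matches * ANI_MATCH + (st$len - st$matches) * ANI_MISMATCH
  use <- if (sc(rv) > sc(fw)) list(st = rv, ori = "-") else list(st = fw, ori = "+")
  st <- use$st
  tibble(
    ani = if (st$len > 0) st$matches / st$len else 0,
    af_small = if (st$len > 0) st$len / min(na, nb) else 0,
    aligned_len = st$len,
    score = sc(st),
    orientation = use$ori)
}

# Cheap prefilter: count of distinct 15-mers shared in either orientation.
shared_kmer_count <- function(a, b, k = 15) {
  ka <- unique(seq_kmers(a, k))
  kb <- unique(c(seq_kmers(b, k), seq_kmers(revcomp(b), k)))
  sum(ka %in% kb)
}

#' All-pairs alignment statistics for a sequence catalogue
#'
#' Computes [ani_pair()] for every pair of sequences passing a shared
#' k-mer prefilter (pairs sharing fewer than `min_shared_kmers` distinct
#' 15-mers in either orientation are reported with `ani = 0` and skipped).
#'
#' @param scaffolds Tibble with columns `id`, `seq`.
#' @param min_shared_kmers Prefilter threshold.
#' @inheritParams ani_pair
#' @return Tibble with one row per unordered pair: `id_a`, `id_b`, `ani`,
#'   `af_small`, `aligned_len`, `score`.
#' @export
pairwise_ani <- function(scaffolds, min_shared_kmers = 5, k = 15, xdrop = 20) {
  n <- nrow(scaffolds)
  if (n < 2) {
    return(tibble(id_a = character(), id_b = character(), ani = numeric(),
                  af_small = numeric(), aligned_len = numeric(), score = numeric()))
  }
  rows <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (shared_kmer_count(scaffolds$seq[i], scaffolds$seq[j], k) < min_shared_kmers) {
        st <- tibble(ani = 0, af_small = 0, aligned_len = 0, score = 0,
                     orientation = "+")
      } else {
        st <- ani_pair(scaffolds$seq[i], scaffolds$seq[j], k, xdrop)
      }
      rows[[length(rows) + 1]] <- tibble(id_a = scaffolds$id[i],
                                         id_b = scaffolds$id[j]) |>
        dplyr::bind_cols(st |> select(-"orientation"))
    }
  }
  bind_rows(rows)
}
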