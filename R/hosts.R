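# In-silico virus-host linking: CRISPR protospacer matches, prophage
# containment, and shared genomic content.

CRISPR_REPEAT_RANGE <- c(23L, 47L)
CRISPR_SPACER_RANGE <- c(20L, 50L)
CRISPR_MIN_REPEATS <- 3L

# Split a chain of repeat start positions wherever the implied spacer
# length falls outside the allowed range; returns a list of sub-chains.
split_chain_by_spacers <- function(starts, rep_len) {
  if (length(starts) < 2) return(list(starts))
  sp <- diff(starts) - rep_len
  ok <- sp >= CRISPR_SPACER_RANGE[1] & sp <= CRISPR_SPACER_RANGE[2]
  out <- list()
  cur <- starts[1]
  for (i in seq_along(ok)) {
    if (ok[i]) cur <- c(cur, starts[i + 1])
    else { out[[length(out) + 1]] <- cur; cur <- starts[i + 1] }
  }
  out[[length(out) + 1]] <- cur
  out
}

#' Detect CRISPR arrays by exact direct repeats
#'
#' Finds maximal runs of at least three identical direct repeats with
#' repeat length 23-47 nt separated by spacers of 20-50 nt. Detection is
#' seeded on exact 23-mers occurring at least three times with compatible
#' spacing, then the repeat is extended in both directions while all
#' occurrences stay identical and the spacer constraints hold. Overlapping
#' candidate arrays are resolved by most repeats, then longest span. Only
#' exact repeats are considered (stricter than fuzzy repeat finders), which
#' keeps the downstream zero-mismatch spacer-matching contract free of
#' heuristics.
#'
#' @param scaffolds Scaffold tibble (`id`, `seq`), typically host
#'   metagenome scaffolds.
#' @return Tibble with one row per spacer: `host_scaffold_id`, `array_id`,
#'   `repeat_consensus`, `repeat_len`, `n_repeats`, `array_start`,
#'   `array_end` (0-based half-open), `spacer_index`, `spacer_start`
#'   (0-based), `spacer_seq`. Zero rows when nothing is found.
#' @export
detect_crispr <- function(scaffolds) {
  empty <- tibble(host_scaffold_id = character(), array_id = character(),
                  repeat_consensus = character(), repeat_len = integer(),
                  n_repeats = integer(), array_start = integer(),
                  array_end = integer(), spacer_index = integer(),
                  spacer_start = integer(), spacer_seq = character())
  out <- list()
  k <- CRISPR_REPEAT_RANGE[1]
  gap_range <- c(CRISPR_REPEAT_RANGE[1] + CRISPR_SPACER_RANGE[1],
                 CRISPR_REPEAT_RANGE[2] + CRISPR_SPACER_RANGE[2])
  for (r in seq_len(nrow(scaffolds))) {
    s <- scaffolds$seq[r]
    n <- nchar(s)
    if (n < 3 * k + 2 * CRISPR_SPACER_RANGE[1]) next
    km <- seq_kmers(s, k)
    dup_idx <- which(km %in% km[duplicated(km)] & !grepl("N", km, fixed = TRUE))
    if (length(dup_idx) == 0) next
    pos_list <- split(dup_idx, km[dup_idx])
    pos_list <- pos_list[lengths(pos_list) >= CRISPR_MIN_REPEATS]
    cands <- list()
    for (P in pos_list) {
      P <- sort(P)
      used <- rep(FALSE, length(P))
      for (st in seq_along(P)) {
        if (used[st]) next
        chain <- P[st]; used[st] <- TRUE
        repeat {
          nxt <- which(!used & P > chain[length(chain)] &
                         P - chain[length(chain)] >= gap_range[1] &
                         P - chain[length(chain)] <= gap_range[2])
          if (length(nxt) == 0) break
          chain <- c(chain, P[nxt[1]]); used[nxt[1]] <- TRUE
        }
        if (length(chain) < CRISPR_MIN_REPEATS) next
        # extend the repeat right, then left, across all occurrences
        L <- k
        min_gap <- min(diff(chain))
        while (L < CRISPR_REPEAT_RANGE[2] &&
               min_gap - L - 1 >= CRISPR_SPACER_RANGE[1] &&
               chain[length(chain)] + L <= n) {
          nxt_ch <- substring(s, chain + L, chain + L)
          if (length(unique(nxt_ch)) != 1 || nxt_ch[1] == "N") break
          L <- L + 1L
        }
        while (L < CRISPR_REPEAT_RANGE[2] && chain[1] > 1 &&
               min_gap - L - 1 >= CRISPR_SPACER_RANGE[1]) {
          prv_ch <- substring(s, chain - 1, chain - 1)
          if (length(unique(prv_ch)) != 1 || prv_ch[1] == "N") break
          chain <- chain - 1L; L <- L + 1L
        }
        for (sub in split_chain_by_spacers(chain, L)) {
          if (length(sub) < CRISPR_MIN_REPEATS) next
          cands[[length(cands) + 1]] <- list(starts = sub, L = L)
        }
      }
    }
    if (length(cands) == 0) next
    # resolve overlaps: most repeats, then longest span
    spans <- vapply(cands, function(cd) {
      c(cd$starts[1], cd$starts[length(cd$starts)] + cd$L - 1L)
    }, integer(2))
    ord <- order(-vapply(cands, function(cd) length(cd$starts), integer(1)),
                 -(spans[2, ] - spans[1, ]))
    kept_spans <- matrix(integer(0), nrow = 2)
    ai <- 0L
    for (ci in ord) {
      sp <- spans[, ci]
      if (ncol(kept_spans) > 0 &&
          any(sp[1] <= kept_spans[2, ] & sp[2] >= kept_spans[1, ])) next
      kept_spans <- cbind(kept_spans, sp)
      ai <- ai + 1L
      cd <- cands[[ci]]
      m <- length(cd$starts)
      sp_start <- cd$starts[-m] + cd$L          # 1-based spacer starts
      sp_end <- cd$starts[-1] - 1L
      out[[length(out) + 1]] <- tibble(
        host_scaffold_id = scaffolds$id[r],
        array_id = sprintf("%s_crispr%02d", scaffolds$id[r], ai),
        repeat_consensus = substr(s, cd$starts[1], cd$starts[1] + cd$L - 1L),
        repeat_len = cd$L,
        n_repeats = m,
        array_start = cd$starts[1] - 1L,
        array_end = cd$starts[m] + cd$L - 1L,
        spacer_index = seq_len(m - 1L),
        spacer_start = sp_start - 1L,
        spacer_seq = substring(s, sp_start, sp_end))
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Match CRISPR spacers against the viral catalogue
#'
#' Emits one host link per occurrence of a spacer as an exact, full-length
#' substring of a curated viral sequence on either strand (zero
#' mismatches; matches covering an N are discarded). The host bin is
#' resolved through the bin membership of the array's scaffold; arrays on
#' unbinned scaffolds yield links flagged `host_bin_id = "unbinned"`.
#'
#' @param spacers Spacer tibble from [detect_crispr()] (needs
#'   `host_scaffold_id`, `array_id`, `spacer_seq`).
#' @param catalogue Curated catalogue (accepted entries with `viral_id`,
#'   `seq`).
#' @param bins Bin membership tibble (`scaffold_id`, `bin_id`), optional.
#' @return Host link tibble: `virus_id`, `host_bin_id`, `evidence`
#'   (`"spacer"`), `host_scaffold_id`, `array_id`, `spacer_seq`,
#'   `position` (0-based on the viral sequence), `strand`, `unbinned`.
#' @export
match_spacers <- function(spacers, catalogue, bins = NULL) {
  empty <- tibble(virus_id = character(), host_bin_id = character(),
                  evidence = character(), host_scaffold_id = character(),
                  array_id = character(), spacer_seq = character(),
                  position = integer(), strand = character(),
                  unbinned = logical())
  if (nrow(spacers) == 0 || nrow(catalogue) == 0) return(empty)
  cat <- catalogue |> filter(!is.na(.data$seq))
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$spacer_seq[i]
    if (nchar(sp) < CRISPR_SPACER_RANGE[1] || grepl("N", sp, fixed = TRUE)) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp(sp)
      for (v in seq_len(nrow(cat))) {
        hits <- gregexpr(pat, cat$seq[v], fixed = TRUE)[[1]]
        if (hits[1] == -1) next
        for (h in hits) {
          matched <- substr(cat$seq[v], h, h + nchar(pat) - 1L)
          if (grepl("N", matched, fixed = TRUE)) next
          out[[length(out) + 1]] <- tibble(
            virus_id = cat$viral_id[v],
            host_scaffold_id = spacers$host_scaffold_id[i],
            array_id = spacers$array_id[i],
            spacer_seq = sp,
            position = h - 1L,
            strand = strand)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  links <- bind_rows(out)
  if (!is.null(bins)) {
    links <- links |> left_join(bins |> select(host_scaffold_id = "scaffold_id",
                                               "bin_id"),
                                by = "host_scaffold_id")
  } else links$bin_id <- NA_character_
  links |>
    mutate(unbinned = is.na(.data$bin_id),
           host_bin_id = dplyr::coalesce(.data$bin_id, "unbinned"),
           evidence = "spacer") |>
    select("virus_id", "host_bin_id", "evidence", "host_scaffold_id",
           "array_id", "spacer_seq", "position", "strand", "unbinned") |>
    distinct()
}

#' Shared genomic content links
#'
#' Aligns each curated viral sequence against every scaffold of the host
#' bins with the package aligner and emits a link when the merged
#' alignment reaches `shared_min_len` nt with identity at least
#' `shared_min_identity` and raw score (match +1 / mismatch -2, the
#' bit-score surrogate) at least `shared_min_score`.
#'
#' @param catalogue Curated catalogue (accepted entries with `viral_id`,
#'   `seq`).
#' @param bin_scaffolds Tibble of host scaffolds: `id`, `seq`, `bin_id`.
#' @param cfg A [pipeline_config()].
#' @return Host link tibble: `virus_id`, `host_bin_id`, `evidence`
#'   (`"shared_content"`), `host_scaffold_id`, `aligned_len`, `identity`,
#'   `score`, `unbinned`.
#' @export
shared_content <- function(catalogue, bin_scaffolds, cfg = pipeline_config()) {
  empty <- tibble(virus_id = character(), host_bin_id = character(),
                  evidence = character(), host_scaffold_id = character(),
                  aligned_len = numeric(), identity = numeric(),
                  score = numeric(), unbinned = logical())
  cat <- catalogue |> filter(!is.na(.data$seq))
  if (nrow(cat) == 0 || nrow(bin_scaffolds) == 0) return(empty)
  out <- list()
  for (v in seq_len(nrow(cat))) {
    for (h in seq_len(nrow(bin_scaffolds))) {
      if (shared_kmer_count(cat$seq[v], bin_scaffolds$seq[h]) < 5) next
      st <- ani_pair(cat$seq[v], bin_scaffolds$seq[h])
      if (st$aligned_len >= cfg$shared_min_len &&
          st$ani >= cfg$shared_min_identity &&
          st$score >= cfg$shared_min_score) {
        out[[length(out) + 1]] <- tibble(
          virus_id = cat$viral_id[v],
          host_bin_id = bin_scaffolds$bin_id[h] %||% "unbinned",
          evidence = "shared_content",
          host_scaffold_id = bin_scaffolds$id[h],
          aligned_len = st$aligned_len,
          identity = st$ani,
          score = st$score,
          unbinned = is.na(bin_scaffolds$bin_id[h]))
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |>
    group_by(.data$virus_id, .data$host_bin_id) |>
    arrange(desc(.data$score)) |>
    slice(1) |>
    ungroup()
}

#' Prophage containment links
#'
#' Every accepted prophage whose parent scaffold belongs to a host bin
#' yields one link to that bin; prophages on unbinned scaffolds are
#' flagged.
#'
#' @param catalogue Curated catalogue with `viral_id`, `parent_scaffold_id`,
#'   `is_prophage`, `accepted`.
#' @param bins Bin membership tibble (`scaffold_id`, `bin_id`).
#' @return Host link tibble: `virus_id`, `host_bin_id`, `evidence`
#'   (`"prophage"`), `host_scaffold_id`, `unbinned`.
#' @export
prophage_links <- function(catalogue, bins) {
  if (anyDuplicated(bins$scaffold_id)) {
    abort("binning integrity violation: a scaffold belongs to more than one bin")
  }
  catalogue |>
    filter(.data$is_prophage, .data$accepted) |>
    left_join(bins |> rename(parent_scaffold_id = "scaffold_id"),
              by = "parent_scaffold_id") |>
    mutate(unbinned = is.na(.data$bin_id),
           host_bin_id = dplyr::coalesce(.data$bin_id, "unbinned"),
           evidence = "prophage") |>
    select(virus_id = "viral_id", "host_bin_id", "evidence",
           host_scaffold_id = "parent_scaffold_id", "unbinned")
}

#' Predict hosts of curated viral scaffolds
#'
#' Runs all three linkage rules (CRISPR protospacer matching, prophage
#' containment, shared genomic content) and returns every evidence row;
#' reconciliation of multi-evidence conflicts is left to the user, as each
#' evidence type has its own error profile.
#'
#' @param catalogue Curated catalogue from [identify_viruses()] (accepted
#'   entries are used).
#' @param host_scaffolds Host metagenome scaffolds (`id`, `seq`).
#' @param bins Bin membership tibble (`scaffold_id`, `bin_id`).
#' @param cfg A [pipeline_config()].
#' @return Host link tibble with one row per (virus, host, evidence)
#'   finding; evidence-specific detail columns are `NA` where not
#'   applicable.
#' @export
predict_hosts <- function(catalogue, host_scaffolds, bins,
                          cfg = pipeline_config()) {
  acc <- catalogue |> filter(.data$accepted)
  arrays <- detect_crispr(host_scaffolds)
  sp_links <- match_spacers(arrays, acc, bins)
  ph_links <- prophage_links(catalogue, bins)
  bin_sc <- host_scaffolds |>
    inner_join(bins, by = c(id = "scaffold_id"))
  sc_links <- shared_content(acc |> filter(!.data$is_prophage), bin_sc, cfg)
  bind_rows(sp_links, ph_links, sc_links) |>
    arrange(.data$evidence, .data$virus_id, .data$host_bin_id)
}
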