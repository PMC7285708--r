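# Viral identification: keyword classification of genes, merging of the two
# detectors' calls, prophage boundary trimming, deduplication, and the final
# acceptance filter producing the curated catalogue.

tokenize_function_text <- function(x) {
  strsplit(tolower(x), "[^a-z0-9]+")
}

# Whole-token keyword matcher. Single-token keywords must equal a token;
# two-word keywords must appear as adjacent tokens. This deliberately
# rejects substring hits ("head" inside "heady", "t4" inside "t4ss").
match_keywords <- function(texts, keywords) {
  toks <- tokenize_function_text(texts)
  kw <- tolower(keywords)
  kw_tokens <- strsplit(kw, "[^a-z0-9]+")
  single <- kw[lengths(kw_tokens) == 1]
  pairs <- kw_tokens[lengths(kw_tokens) == 2]
  vapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0) return(FALSE)
    if (any(tk %in% single)) return(TRUE)
    if (length(pairs) > 0 && length(tk) >= 2) {
      bigrams <- paste(tk[-length(tk)], tk[-1])
      if (any(vapply(pairs, function(p) paste(p, collapse = " ") %in% bigrams,
                     logical(1)))) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Classify genes by hallmark keywords and annotation status
#'
#' Adds the four curation flags to a gene table: `virus_specific` (the
#' function text contains a hallmark keyword under case-insensitive
#' whole-token matching), `integrase` (contains the token "integrase"),
#' `unknown` (no functional assignment: empty `cog_id` and function text
#' empty or a configured "hypothetical protein" synonym), and `short`
#' (gene length below `short_gene_max_nt`, default 1 kb). A convenience
#' `hallmark` column is `virus_specific | integrase`.
#'
#' @param genes Gene tibble (internal 0-based half-open coordinates).
#' @param cfg A [pipeline_config()].
#' @return `genes` with logical columns `virus_specific`, `integrase`,
#'   `unknown`, `short`, `hallmark` appended.
#' @examples
#' g <- tibble::tibble(scaffold_id = "s", gene_id = "g1", start = 0L,
#'                     end = 900L, strand = "+", cog_id = "",
#'                     function_text = "phage terminase large subunit")
#' classify_genes(g)$virus_specific
#' @export
classify_genes <- function(genes, cfg = pipeline_config()) {
  ft <- genes$function_text %||% rep("", nrow(genes))
  ft[is.na(ft)] <- ""
  cog <- genes$cog_id %||% rep("", nrow(genes))
  cog[is.na(cog)] <- ""
  syn <- tolower(trimws(cfg$unknown_function_synonyms))
  genes |>
    mutate(
      virus_specific = match_keywords(ft, cfg$hallmark_keywords),
      integrase = match_keywords(ft, "integrase"),
      unknown = cog == "" & (trimws(ft) == "" | tolower(trimws(ft)) %in% syn),
      short = (.data$end - .data$start) < cfg$short_gene_max_nt,
      hallmark = .data$virus_specific | .data$integrase
    )
}

#' Trim a predicted prophage region to hallmark-gene boundaries
#'
#' Shrinks a predicted prophage region so that it spans from the start of
#' the first gene flagged virus-specific or integrase within the prediction
#' to the end of the last such gene; genes outside are dropped. A
#' prediction containing no hallmark gene (or no gene at all) is rejected.
#' Trimming never enlarges a region and is idempotent.
#'
#' @param region_start,region_end Predicted region, 0-based half-open, on
#'   the parent scaffold.
#' @param genes Classified genes of the parent scaffold (see
#'   [classify_genes()]), sorted by start.
#' @return A list with `start`, `end` (0-based half-open) and `status`
#'   (`"trimmed"`), or `status` `"rejected_no_hallmark"` /
#'   `"rejected_no_genes"` with `NA` coordinates.
#' @export
trim_prophage <- function(region_start, region_end, genes) {
  stopifnot("hallmark" %in% names(genes))
  inside <- genes |>
    filter(.data$start >= region_start, .data$end <= region_end) |>
    arrange(.data$start)
  if (nrow(inside) == 0) {
    return(list(start = NA_integer_, end = NA_integer_,
                status = "rejected_no_genes"))
  }
  hm <- which(inside$hallmark)
  if (length(hm) == 0) {
    return(list(start = NA_integer_, end = NA_integer_,
                status = "rejected_no_hallmark"))
  }
  list(start = inside$start[min(hm)], end = inside$end[max(hm)],
       status = "trimmed")
}

prophage_region_id <- function(scaffold_id, start, end) {
  # 1-based inclusive label, matching the on-disk gene table dialect
  sprintf("%s:%d-%d", scaffold_id, start + 1L, end)
}

#' Merge detector calls into candidate viral scaffolds
#'
#' Applies the merging and deduplication rules to the two detectors'
#' calls: protein-family calls are restricted to scaffolds of at least
#' `min_len_protein_family` nt and category-based (VirSorter-style) calls
#' to at least `min_len_virsorter` nt; categories 3 and 6 are discarded;
#' category 4/5 predictions are trimmed to hallmark boundaries with
#' [trim_prophage()]; a protein-family whole-scaffold call is dropped when
#' any prophage call exists on the same scaffold; and a scaffold called
#' whole by both detectors yields a single candidate with
#' `detectors = "both"`.
#'
#' @param calls Detector call tibble (see [read_detector_calls()]).
#' @param scaffolds Scaffold tibble from [read_fasta()].
#' @param genes Classified gene tibble ([classify_genes()]).
#' @param cfg A [pipeline_config()].
#' @return Candidate catalogue tibble: `viral_id`, `parent_scaffold_id`,
#'   `region_start`, `region_end`, `is_prophage`, `detectors`,
#'   `virsorter_category`, `trim_status`.
#' @export
merge_detector_calls <- function(calls, scaffolds, genes, cfg = pipeline_config()) {
  stopifnot("hallmark" %in% names(genes))
  calls <- calls |> left_join(scaffolds |> select("id", "length"),
                              by = c(scaffold_id = "id"))
  if (any(is.na(calls$length))) {
    abort(sprintf("detector call(s) reference unknown scaffold(s): %s",
                  paste(unique(calls$scaffold_id[is.na(calls$length)]), collapse = ", ")))
  }
  dup <- calls |>
    dplyr::count(.data$scaffold_id, .data$detector, .data$virsorter_category) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("conflicting calls from one detector on scaffold(s): %s",
                  paste(unique(dup$scaffold_id), collapse = ", ")))
  }
  dropped_cat <- calls |>
    filter(.data$detector == "virsorter", .data$virsorter_category %in% c(3L, 6L))
  if (nrow(dropped_cat) > 0) {
    inform(sprintf("discarding %d category-3/6 call(s) (only categories 1, 2, 4, 5 are used)",
                   nrow(dropped_cat)))
  }
  calls <- calls |>
    filter(!(.data$detector == "virsorter" & .data$virsorter_category %in% c(3L, 6L))) |>
    filter(!(.data$detector == "protein_family" & .data$length < cfg$min_len_protein_family)) |>
    filter(!(.data$detector == "virsorter" & .data$length < cfg$min_len_virsorter))

  out <- list()
  for (sid in unique(calls$scaffold_id)) {
    sc_calls <- calls |> filter(.data$scaffold_id == sid)
    sc_genes <- genes |> filter(.data$scaffold_id == sid)
    slen <- sc_calls$length[1]
    pro <- sc_calls |> filter(.data$detector == "virsorter",
                              .data$virsorter_category %in% c(4L, 5L))
    whole_vs <- sc_calls |> filter(.data$detector == "virsorter",
                                   .data$virsorter_category %in% c(1L, 2L))
    whole_pf <- sc_calls |> filter(.data$detector == "protein_family")
    has_prophage <- nrow(pro) > 0
    for (r in seq_len(nrow(pro))) {
      tr <- trim_prophage(pro$region_start[r], pro$region_end[r], sc_genes)
      if (tr$status == "trimmed") {
        out[[length(out) + 1]] <- tibble(
          viral_id = prophage_region_id(sid, tr$start, tr$end),
          parent_scaffold_id = sid,
          region_start = tr$start, region_end = tr$end,
          is_prophage = TRUE, detectors = "virsorter",
          virsorter_category = pro$virsorter_category[r], trim_status = tr$status)
      } else {
        out[[length(out) + 1]] <- tibble(
          viral_id = prophage_region_id(sid, pro$region_start[r], pro$region_end[r]),
          parent_scaffold_id = sid,
          region_start = NA_integer_, region_end = NA_integer_,
          is_prophage = TRUE, detectors = "virsorter",
          virsorter_category = pro$virsorter_category[r], trim_status = tr$status)
      }
    }
    # a protein-family whole-scaffold call is superseded by any prophage
    # prediction on the same scaffold
    keep_pf <- nrow(whole_pf) > 0 && !has_prophage
    keep_vs <- nrow(whole_vs) > 0
    if (keep_pf || keep_vs) {
      out[[length(out) + 1]] <- tibble(
        viral_id = sid, parent_scaffold_id = sid,
        region_start = 0L, region_end = as.integer(slen),
        is_prophage = FALSE,
        detectors = if (keep_pf && keep_vs) "both" else if (keep_pf) "protein_family" else "virsorter",
        virsorter_category = if (keep_vs) whole_vs$virsorter_category[1] else NA_integer_,
        trim_status = "whole")
    }
  }
  if (length(out) == 0) {
    return(tibble(viral_id = character(), parent_scaffold_id = character(),
                  region_start = integer(), region_end = integer(),
                  is_prophage = logical(), detectors = character(),
                  virsorter_category = integer(), trim_status = character()))
  }
  bind_rows(out)
}

#' Apply the final acceptance filter to candidate viral scaffolds
#'
#' A candidate is accepted when it contains at least one hallmark
#' (virus-specific or integrase) gene, or when the fraction of its genes
#' with no functional assignment is at least `unknown_fraction_threshold`
#' (default 0.80). The hallmark clause wins ties in the recorded reason.
#' Candidates with no genes, or prophage predictions rejected at trimming,
#' are not accepted.
#'
#' @param candidates Candidate tibble from [merge_detector_calls()].
#' @param genes Classified gene tibble.
#' @param cfg A [pipeline_config()].
#' @return `candidates` with `n_genes`, `n_unknown`, `unknown_fraction`,
#'   `accepted` (logical) and `reason` (`"virus_specific_gene"`,
#'   `"unknown_fraction"` or `"rejected"`) appended.
#' @export
accept_viral <- function(candidates, genes, cfg = pipeline_config()) {
  stopifnot("hallmark" %in% names(genes))
  if (nrow(candidates) == 0) {
    return(candidates |>
             mutate(n_genes = integer(), n_unknown = integer(),
                    unknown_fraction = numeric(), accepted = logical(),
                    reason = character()))
  }
  res <- purrr::pmap(candidates, function(viral_id, parent_scaffold_id,
                                          region_start, region_end,
                                          is_prophage, trim_status, ...) {
    if (is.na(region_start)) {
      return(tibble(n_genes = 0L, n_unknown = 0L, unknown_fraction = NA_real_,
                    accepted = FALSE, reason = "rejected"))
    }
    g <- genes |>
      filter(.data$scaffold_id == parent_scaffold_id,
             .data$start >= region_start, .data$end <= region_end)
    if (nrow(g) == 0) {
      return(tibble(n_genes = 0L, n_unknown = 0L, unknown_fraction = NA_real_,
                    accepted = FALSE, reason = "rejected"))
    }
    frac_unknown <- sum(g$unknown) / nrow(g)
    if (any(g$hallmark)) {
      tibble(n_genes = nrow(g), n_unknown = sum(g$unknown),
             unknown_fraction = frac_unknown, accepted = TRUE,
             reason = "virus_specific_gene")
    } else if (frac_unknown >= cfg$unknown_fraction_threshold) {
      tibble(n_genes = nrow(g), n_unknown = sum(g$unknown),
             unknown_fraction = frac_unknown, accepted = TRUE,
             reason = "unknown_fraction")
    } else {
      tibble(n_genes = nrow(g), n_unknown = sum(g$unknown),
             unknown_fraction = frac_unknown, accepted = FALSE,
             reason = "rejected")
    }
  })
  dplyr::bind_cols(candidates, bind_rows(res))
}

#' Identify and curate viral scaffolds
#'
#' End-to-end viral identification: classifies genes with
#' [classify_genes()], merges and deduplicates detector calls with
#' [merge_detector_calls()] (including prophage boundary trimming), applies
#' the acceptance filter with [accept_viral()], and attaches the curated
#' sequence of each accepted entry (the whole scaffold, or the trimmed
#' region for prophages).
#'
#' @param scaffolds Scaffold tibble from [read_fasta()].
#' @param genes Gene tibble from [read_gene_table()].
#' @param calls Detector call tibble from [read_detector_calls()].
#' @param cfg A [pipeline_config()].
#' @return The curated catalogue: accepted entries with columns of
#'   [accept_viral()] plus `seq` and `length`; rejected candidates are kept
#'   with `accepted = FALSE` so that curation bookkeeping
#'   (single-tool + both-tool counts) remains auditable.
#' @export
identify_viruses <- function(scaffolds, genes, calls, cfg = pipeline_config()) {
  cg <- classify_genes(genes, cfg)
  cand <- merge_detector_calls(calls, scaffolds, cg, cfg)
  cat <- accept_viral(cand, cg, cfg)
  seqs <- scaffolds$seq[match(cat$parent_scaffold_id, scaffolds$id)]
  cat |>
    mutate(
      seq = ifelse(.data$accepted,
                   substr(seqs, .data$region_start + 1L, .data$region_end),
                   NA_character_),
      length = ifelse(.data$accepted, .data$region_end - .data$region_start,
                      NA_integer_))
}
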