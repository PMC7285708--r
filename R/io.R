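#' Read scaffold sequences from FASTA
#'
#' Reads a nucleotide FASTA file into a scaffold table. Sequences are
#' uppercased; any character outside `A`, `C`, `G`, `T`, `N` is rejected.
#' The record id is the first whitespace-delimited token of the header and
#' must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length` (nt), in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- unname(toupper(as.character(ss)))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty FASTA record(s): %s",
                  paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("non-ACGTN character in record(s): %s",
                  paste(ids[bad], collapse = ", ")))
  }
  tibble(id = unname(ids), seq = unname(seqs), length = nchar(seqs))
}

#' Write scaffolds to FASTA
#'
#' @param scaffolds Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(scaffolds, path) {
  stopifnot(all(c("id", "seq") %in% names(scaffolds)))
  ss <- Biostrings::DNAStringSet(setNames(scaffolds$seq, scaffolds$id))
  Biostrings::writeXStringSet(ss, filepath = path, width = 70)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Reads a per-scaffold gene table (TSV with header) carrying coordinates,
#' strand, COG identifiers and free-text function descriptions. On-disk
#' coordinates are 1-based inclusive (GFF convention) by default and are
#' converted to the package-internal 0-based half-open convention; genes
#' are grouped per scaffold and sorted by start. Rows referencing scaffolds
#' absent from `known_scaffolds` (when given) are retained with a warning;
#' referential validation is deferred to the pipeline stages that need it.
#'
#' Expected columns: `scaffold_id`, `gene_id`, `start`, `end`, `strand`,
#' and optionally `cog_id`, `function_text`, `source_db`.
#'
#' @param path Path to a TSV file.
#' @param one_based Logical; `TRUE` (default) declares on-disk coordinates
#'   1-based inclusive.
#' @param known_scaffolds Optional character vector of valid scaffold ids.
#' @return Tibble of genes with internal 0-based half-open `start`/`end`.
#' @export
read_gene_table <- function(path, one_based = TRUE, known_scaffolds = NULL) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  req <- c("scaffold_id", "gene_id", "start", "end", "strand")
  miss <- setdiff(req, names(g))
  if (length(miss) > 0) {
    abort(sprintf("gene table %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  for (opt in c("cog_id", "function_text")) if (!opt %in% names(g)) g[[opt]] <- ""
  if (!"source_db" %in% names(g)) g$source_db <- "none"
  g <- g |>
    mutate(cog_id = replace_na(as.character(.data$cog_id), ""),
           function_text = replace_na(as.character(.data$function_text), ""))
  if (one_based) g$start <- g$start - 1L
  if (any(g$end <= g$start)) {
    bad <- g$gene_id[g$end <= g$start]
    abort(sprintf("gene(s) with end <= start after coordinate conversion: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(g$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol(s): %s",
                  paste(unique(setdiff(g$strand, c("+", "-"))), collapse = ", ")))
  }
  if (!is.null(known_scaffolds)) {
    orphan <- setdiff(unique(g$scaffold_id), known_scaffolds)
    if (length(orphan) > 0) {
      warn(sprintf("gene table references %d scaffold(s) absent from the assembly: %s",
                   length(orphan), paste(head(orphan, 5), collapse = ", ")))
    }
  }
  g |> arrange(.data$scaffold_id, .data$start) |> as_tibble()
}

#' Write a gene table (1-based inclusive coordinates)
#'
#' The on-disk dialect is GFF-like 1-based inclusive; a comment line in the
#' header records the convention so round-tripping through
#' [read_gene_table()] is the identity.
#'
#' @param genes Gene tibble with internal 0-based half-open coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes |> mutate(start = .data$start + 1L)
  con <- file(path, "w")
  writeLines("# coordinates: 1-based inclusive (GFF convention)", con)
  close(con)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read detector call tables
#'
#' Reads the merged table of upstream viral predictor calls (TSV with
#' header): columns `scaffold_id`, `detector` (`protein_family` or
#' `virsorter`), `virsorter_category` (1-6 or NA), and optional
#' `region_start`/`region_end` for prophage predictions (1-based inclusive
#' on disk). Prophage regions must be present exactly for categories 4-5.
#'
#' @param path Path to a TSV file.
#' @param one_based Logical; on-disk region coordinates are 1-based
#'   inclusive when `TRUE` (default).
#' @return Tibble of calls with internal 0-based half-open regions.
#' @export
read_detector_calls <- function(path, one_based = TRUE) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("scaffold_id", "detector")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0) {
    abort(sprintf("detector table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!"virsorter_category" %in% names(d)) d$virsorter_category <- NA_integer_
  if (!"region_start" %in% names(d)) d$region_start <- NA_real_
  if (!"region_end" %in% names(d)) d$region_end <- NA_real_
  if (!all(d$detector %in% c("protein_family", "virsorter"))) {
    abort("detector must be 'protein_family' or 'virsorter'")
  }
  d$virsorter_category <- as.integer(d$virsorter_category)
  if (any(d$detector == "protein_family" & !is.na(d$virsorter_category))) {
    abort("virsorter_category must be absent for protein_family calls")
  }
  if (any(d$detector == "virsorter" & is.na(d$virsorter_category))) {
    abort("virsorter calls must carry a category (1-6)")
  }
  if (one_based) d$region_start <- d$region_start - 1
  prophage_cat <- !is.na(d$virsorter_category) & d$virsorter_category %in% c(4L, 5L)
  has_region <- !is.na(d$region_start) & !is.na(d$region_end)
  if (any(prophage_cat != has_region)) {
    abort("prophage region coordinates must be present exactly for categories 4 and 5")
  }
  as_tibble(d)
}

#' Read the sample metadata / geochemistry table
#'
#' TSV with header; required columns `sample_id`, `core`, `depth_cm`,
#' `reads` (library read count) plus any geochemical columns (`pH`, `EC`,
#' `TOC`, `TP`, `TS`, ratio and metal columns).
#'
#' @param path Path to a TSV file.
#' @return Tibble of samples, one row per library.
#' @export
read_sample_table <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "core", "depth_cm", "reads")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0) {
    abort(sprintf("sample table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(s$reads <= 0)) abort("library read counts must be positive")
  if ("pH" %in% names(s) && any(s$pH <= 0 | s$pH >= 14)) {
    abort("pH values must lie in (0, 14)")
  }
  as_tibble(s)
}

#' Read a long coverage table
#'
#' TSV with header and columns `entity_id`, `sample_id`, `mapped_nt`
#' (number of nucleotides mapped to the entity in that library).
#'
#' @param path Path to a TSV file.
#' @return Tibble with one row per (entity, library) pair.
#' @export
read_coverage_table <- function(path) {
  cv <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("entity_id", "sample_id", "mapped_nt"), names(cv))
  if (length(miss) > 0) {
    abort(sprintf("coverage table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(cv$mapped_nt < 0)) abort("mapped_nt must be non-negative")
  as_tibble(cv)
}

#' Read bin membership and bin taxonomy tables
#'
#' @param path Path to a TSV file. Membership: columns `scaffold_id`,
#'   `bin_id`. Taxonomy: columns `bin_id`, `domain`, `phylum` (free-text
#'   lineage columns are passed through).
#' @return A tibble.
#' @export
read_bin_table <- function(path) {
  b <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("scaffold_id", "bin_id"), names(b))
  if (length(miss) > 0) {
    abort(sprintf("bin membership table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  dup <- b |> dplyr::count(.data$scaffold_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("scaffold(s) assigned to more than one bin: %s",
                  paste(head(dup$scaffold_id, 5), collapse = ", ")))
  }
  as_tibble(b)
}

#' @rdname read_bin_table
#' @export
read_bin_taxonomy <- function(path) {
  b <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"bin_id" %in% names(b)) abort("bin taxonomy table lacks column 'bin_id'")
  as_tibble(b)
}

#' Read a prokaryotic OTU abundance table
#'
#' Wide TSV: one row per OTU with columns `otu_id`, taxonomy columns
#' (at least `phylum`, optionally `domain`), and one count column per
#' sample.
#'
#' @param path Path to a TSV file.
#' @param sample_ids Optional character vector naming the count columns;
#'   defaults to every column that is not `otu_id`/taxonomy.
#' @return Tibble in long form: `otu_id`, taxonomy columns, `sample_id`,
#'   `count`.
#' @export
read_otu_table <- function(path, sample_ids = NULL) {
  o <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"otu_id" %in% names(o)) abort("OTU table lacks column 'otu_id'")
  tax_cols <- intersect(c("domain", "phylum", "lineage"), names(o))
  if (is.null(sample_ids)) sample_ids <- setdiff(names(o), c("otu_id", tax_cols))
  o |>
    pivot_longer(all_of(sample_ids), names_to = "sample_id", values_to = "count") |>
    as_tibble()
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write all pipeline products to a results directory
#'
#' Serialises every product of [run_tailings_pipeline()]: the curated viral
#' catalogue (FASTA + TSV), vOTU membership, coverage and relative-abundance
#' matrices, host links, indicator COGs, AMG report, ordination coordinates,
#' and a machine-readable run manifest (JSON) echoing the configuration and
#' seed. Empty products are written as headered, zero-row TSVs so downstream
#' tooling always finds the files. Reruns with the same inputs and seed are
#' byte-identical.
#'
#' @param results A `tv_results` list as returned by
#'   [run_tailings_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE)
  if (!ok) abort(sprintf("output directory not writable: %s", outdir))
  unlink(probe)

  if (!is.null(results$catalogue)) {
    cat_tab <- results$catalogue |> select(-any_of("seq"))
    write_tsv_file(cat_tab, file.path(outdir, "viral_catalogue.tsv"))
    acc_seq <- results$catalogue |>
      filter(.data$accepted, !is.na(.data$seq))
    if ("seq" %in% names(results$catalogue) && nrow(acc_seq) > 0) {
      write_fasta(acc_seq |> rename(id = "viral_id"),
                  file.path(outdir, "viral_catalogue.fasta"))
    }
  }
  pairs <- list(
    votus = "votu_membership.tsv",
    coverage = "normalized_coverage.tsv",
    relative_abundance = "relative_abundance.tsv",
    richness = "richness.tsv",
    host_links = "host_links.tsv",
    indicator_cogs = "indicator_cogs.tsv",
    amg_report = "amg_report.tsv",
    ordination = "ordination_coordinates.tsv",
    stats = "community_stats.tsv"
  )
  for (nm in names(pairs)) {
    if (!is.null(results[[nm]])) write_tsv_file(results[[nm]], file.path(outdir, pairs[[nm]]))
  }
  if (!is.null(results$manifest)) {
    jsonlite::write_json(results$manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(outdir)
}

#' Build a run manifest
#'
#' @param cfg A `tv_config`.
#' @param inputs Named character vector of input file paths (digested with
#'   md5 when they exist).
#' @param counts Named list of per-stage row counts.
#' @return A manifest list suitable for JSON serialisation.
#' @export
run_manifest <- function(cfg, inputs = character(), counts = list()) {
  digests <- if (length(inputs) > 0) {
    vapply(inputs, function(p) {
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
    }, character(1))
  } else character()
  list(
    tool = "tailvirkit",
    version = tryCatch(as.character(utils::packageVersion("tailvirkit")),
                       error = function(e) "dev"),
    seed = cfg$rng_seed,
    stage_order = c("identify", "cluster", "abundance", "hosts", "functions", "stats"),
    config = unclass(cfg),
    input_digests = as.list(digests),
    counts = counts
  )
}
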