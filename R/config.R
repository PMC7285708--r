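#' Pipeline configuration
#'
#' Assemble the full set of tunable thresholds used across the pipeline.
#' Defaults are the published operating point of the study design this
#' package implements: candidate scaffolds must be >= 5 kb for the
#' protein-family detector and >= 3 kb for the category-based detector;
#' a candidate lacking hallmark genes is accepted only when >= 80% of its
#' genes are functionally unknown; vOTUs are defined at 95% average
#' nucleotide identity over >= 85% of the shorter sequence; shared-content
#' host links require a merged alignment >= 2.5 kb at >= 70% identity with
#' raw score >= 50; CRISPR spacer matches allow zero mismatches over the
#' whole spacer; permutation tests use 999 permutations and alpha = 0.05.
#'
#' @param min_len_protein_family Minimum scaffold length (nt) for
#'   protein-family detector calls.
#' @param min_len_virsorter Minimum scaffold length (nt) for category-based
#'   (VirSorter-style) detector calls.
#' @param unknown_fraction_threshold Minimum fraction of unknown genes for
#'   acceptance of a candidate without hallmark genes.
#' @param ani_threshold,af_threshold vOTU clustering thresholds: average
#'   nucleotide identity and alignment fraction of the shorter sequence.
#' @param shared_min_len,shared_min_identity,shared_min_score Shared genomic
#'   content link thresholds: merged alignment length (nt), identity, and raw
#'   alignment score (match +1 / mismatch -2).
#' @param spacer_mismatches Allowed mismatches in spacer/protospacer
#'   matching (0 = exact over the whole spacer).
#' @param hallmark_keywords Character vector of hallmark tokens matched
#'   (case-insensitively, whole-token) against gene function text. Two-word
#'   entries are matched as adjacent token pairs.
#' @param unknown_function_synonyms Function-text values treated as "no
#'   functional assignment" alongside an empty string.
#' @param short_gene_max_nt Genes shorter than this many nt are flagged
#'   short.
#' @param alpha Significance level for indicator calling (on BH-adjusted q).
#' @param permutations Number of random permutations for permutation tests.
#' @param presence_threshold Normalized coverage above which a vOTU counts
#'   as present when computing richness.
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return A named list with class `tv_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$ani_threshold
#' @export
pipeline_config <- function(min_len_protein_family = 5000,
                            min_len_virsorter = 3000,
                            unknown_fraction_threshold = 0.80,
                            ani_threshold = 0.95,
                            af_threshold = 0.85,
                            shared_min_len = 2500,
                            shared_min_identity = 0.70,
                            shared_min_score = 50,
                            spacer_mismatches = 0,
                            hallmark_keywords = tv_hallmark_keywords(),
                            unknown_function_synonyms = c("hypothetical protein",
                                                          "uncharacterized protein"),
                            short_gene_max_nt = 1000,
                            alpha = 0.05,
                            permutations = 999,
                            presence_threshold = 0,
                            rng_seed = 1L) {
  cfg <- list(
    min_len_protein_family = min_len_protein_family,
    min_len_virsorter = min_len_virsorter,
    unknown_fraction_threshold = unknown_fraction_threshold,
    ani_threshold = ani_threshold,
    af_threshold = af_threshold,
    shared_min_len = shared_min_len,
    shared_min_identity = shared_min_identity,
    shared_min_score = shared_min_score,
    spacer_mismatches = spacer_mismatches,
    hallmark_keywords = hallmark_keywords,
    unknown_function_synonyms = unknown_function_synonyms,
    short_gene_max_nt = short_gene_max_nt,
    alpha = alpha,
    permutations = permutations,
    presence_threshold = presence_threshold,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "tv_config")
}

#' Hallmark keyword vocabulary
#'
#' The verbatim hallmark vocabulary used to flag virus-specific genes,
#' plus "holin" as a synonym of the listed "holing" (almost certainly a
#' typo for the phage lysis protein). Integrase genes are flagged
#' separately by [classify_genes()] and count as hallmark genes alongside
#' these. Users can edit the list through [pipeline_config()] or a YAML
#' config file.
#'
#' @return Character vector of keyword tokens (lower case).
#' @export
tv_hallmark_keywords <- function() {
  c("capsid", "phage", "terminase", "baseplate", "base plate", "prohead",
    "virion", "holing", "holin", "virus", "viral", "tape measure",
    "tapemeasure", "neck", "tail", "p22", "head", "t4", "prophage")
}

validate_config <- function(cfg) {
  prop <- c("unknown_fraction_threshold", "ani_threshold", "af_threshold",
            "shared_min_identity")
  for (p in prop) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("config field '%s' must be a proportion in (0, 1]", p))
    }
  }
  nonneg <- c("min_len_protein_family", "min_len_virsorter", "shared_min_len",
              "shared_min_score", "spacer_mismatches", "short_gene_max_nt",
              "permutations", "presence_threshold")
  for (p in nonneg) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      abort(sprintf("config field '%s' must be a non-negative number", p))
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must lie in (0, 1)")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Every threshold of [pipeline_config()] is overridable from a flat
#' key-value YAML file; keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `tv_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown config keys: %s", paste(extra, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `tv_config` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tv_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.tv_config <- function(x, ...) {
  cat("<tv_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) > 4) v <- c(v[1:4], "...")
    cat(sprintf("  %-28s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}
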