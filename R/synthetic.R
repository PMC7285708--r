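# Synthetic mine-tailings community generator. Emits a complete input
# bundle (assembly FASTA, gene table, detector calls, coverage tables,
# host bins, CRISPR arrays, geochemistry, prokaryotic OTU table) with
# planted ground truth mirroring the depth-stratified study design:
# 11 layers in 2 cores, a pH gradient from ~2 at the surface to ~7 at
# depth, prophage relative abundance declining with pH, viral and
# prokaryotic richness increasing with depth, archaea-dominated surface
# communities, and deep-enriched sulfate-assimilation AMG carriers.

#' Simulation configuration
#'
#' Parameters of [simulate_bundle()]. Defaults reproduce the reference
#' design: two cores with six and five layers, species clusters planted at
#' 98% within- and 80% between-cluster identity (straddling the 95%
#' clustering threshold), prophage relative abundance affine in pH with
#' negative slope, and an 8-fold deep enrichment of AMG carriers and
#' planted indicator COGs.
#'
#' @param seed Root seed; every sub-generator derives an independent child
#'   stream from it, so adding a feature never perturbs existing draws.
#' @param layers_per_core Named integer vector, layers per core.
#' @param votu_sizes Integer vector of members per planted free-virus
#'   vOTU.
#' @param within_votu_identity Expected pairwise identity between members
#'   of one vOTU.
#' @param between_votu_identity Expected pairwise identity between vOTU
#'   ancestors.
#' @param ani_threshold The clustering threshold the plant must straddle;
#'   configs with `between_votu_identity >= ani_threshold` or
#'   `within_votu_identity <= ani_threshold` are infeasible and rejected.
#' @param n_amg_carriers Number of planted COG0175-carrying viral
#'   scaffolds (all > 10 kb, hallmark-flanked AMG).
#' @param n_prophages Number of planted prophages (one per host scaffold).
#' @param n_host_bins Number of host genome bins (first three archaeal).
#' @param n_decoys Non-viral decoy scaffolds; half receive (false)
#'   detector calls and must be rejected by curation.
#' @param n_spacer_links Planted CRISPR spacer links (spacers copied
#'   verbatim or reverse-complemented from singleton viruses).
#' @param n_decoy_spacers Decoy spacers differing from any viral substring
#'   by one central mismatch.
#' @param prophage_ph_slope Slope (per pH unit) of the planted affine
#'   relation between prophage summed relative abundance and pH.
#' @param amg_depth_enrichment Multiplicative deep-vs-surface coverage
#'   enrichment of AMG carriers (also used for planted indicator COGs).
#' @param read_count_range Range of per-library metagenome read counts.
#' @param noise_sd Log-normal sd of per-scaffold, per-library coverage
#'   noise.
#' @param surface_layers_per_core Top layers per core forming the
#'   "surface" group of the indicator analysis.
#' @return A `tv_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       layers_per_core = c(A = 6L, B = 5L),
                       votu_sizes = c(3L, 2L, 2L, 1L, 1L, 1L),
                       within_votu_identity = 0.98,
                       between_votu_identity = 0.80,
                       ani_threshold = 0.95,
                       n_amg_carriers = 3L,
                       n_prophages = 5L,
                       n_host_bins = 8L,
                       n_decoys = 4L,
                       n_spacer_links = 4L,
                       n_decoy_spacers = 4L,
                       prophage_ph_slope = -0.09,
                       amg_depth_enrichment = 8,
                       read_count_range = c(8e5, 1.2e6),
                       noise_sd = 0.3,
                       surface_layers_per_core = 2L) {
  cfg <- as.list(environment())
  if (!(within_votu_identity > ani_threshold &&
        ani_threshold > between_votu_identity)) {
    abort("infeasible config: need within_votu_identity > ani_threshold > between_votu_identity")
  }
  structure(cfg, class = "tv_sim_config")
}

# Per-branch substitution rate so that two sequences independently mutated
# from one ancestor have expected pairwise identity `target`:
# identity(r) = (1 - r)^2 + r^2 / 3.
pairwise_rate <- function(target) {
  stats::uniroot(function(r) (1 - r)^2 + r^2 / 3 - target,
                 c(0, 0.75), tol = 1e-10)$root
}

hallmark_texts <- c("phage capsid protein", "terminase large subunit",
                    "phage tail fiber protein", "baseplate assembly protein",
                    "major head protein", "tape measure protein",
                    "prohead protease", "virion structural protein")

metabolic_texts <- tibble(
  function_text = c("ABC transporter ATP-binding protein",
                    "DNA polymerase III subunit alpha",
                    "sulfate adenylyltransferase",
                    "cytochrome c oxidase subunit I",
                    "NADH-quinone oxidoreductase subunit",
                    "elongation factor Tu",
                    "glyceraldehyde-3-phosphate dehydrogenase",
                    "iron-sulfur cluster assembly protein"),
  cog_id = c("COG1131", "COG0587", "COG2046", "COG0843",
             "COG0649", "COG0050", "COG0057", "COG0822"))

# Viral null COGs: depth-neutral cargo planted only on always-present,
# trend-free viruses so the indicator analysis must call them negative.
null_cog_texts <- tibble(
  function_text = c("DNA methyltransferase", "glycosyltransferase",
                    "tellurium resistance protein"),
  cog_id = c("COG0270", "COG1215", "COG3600"))

# One gene layout: lengths and gaps; the first gene starts at rel 0 and
# the last gene ends at the region end, so hallmark-boundary trimming of
# a planted prophage recovers the planted region exactly.
layout_genes <- function(n_genes, len_range = c(700L, 1600L),
                         gap_range = c(20L, 120L)) {
  lens <- sample(len_range[1]:len_range[2], n_genes, replace = TRUE)
  gaps <- if (n_genes > 1) {
    sample(gap_range[1]:gap_range[2], n_genes - 1, replace = TRUE)
  } else integer()
  starts <- cumsum(c(0L, lens[-n_genes] + gaps))
  tibble(rel_start = starts, rel_end = starts + lens)
}

# Gene plan for one viral entity. route "hallmark": hallmark gene forced
# at the first slot (and last when force_edge_hallmark). route "unknown":
# no hallmark, one annotated (COG-less) gene, the rest hypothetical, so
# the unknown fraction is (n-1)/n >= 0.8 for n >= 5.
viral_gene_plan <- function(route, n_genes, extra = NULL,
                            force_edge_hallmark = FALSE) {
  lay <- layout_genes(n_genes)
  ft <- rep("hypothetical protein", n_genes)
  cog <- rep("", n_genes)
  src <- rep("none", n_genes)
  slots <- seq_len(n_genes)
  if (!is.null(extra)) {
    pick <- sample(setdiff(slots, c(1L, n_genes)), nrow(extra))
    ft[pick] <- extra$function_text
    cog[pick] <- extra$cog_id
    src[pick] <- "eggnog"
    slots <- setdiff(slots, pick)
  }
  if (route == "hallmark") {
    hm_slots <- if (force_edge_hallmark) c(1L, n_genes) else 1L
    pool <- setdiff(slots, hm_slots)
    if (length(pool) > 0 && runif(1) < 0.7) {
      hm_slots <- c(hm_slots, sample(pool, 1))
    }
    ft[hm_slots] <- sample(hallmark_texts, length(hm_slots), replace = TRUE)
    src[hm_slots] <- "eggnog"
  } else {
    ann <- sample(slots, 1)
    row <- metabolic_texts[sample(nrow(metabolic_texts), 1), ]
    ft[ann] <- row$function_text
    src[ann] <- "pfam"   # annotated but COG-less: not unknown, not tested
  }
  lay |> mutate(function_text = ft, cog_id = cog, source_db = src)
}

host_gene_plan <- function(n_genes) {
  lay <- layout_genes(n_genes, len_range = c(700L, 1800L))
  rows <- metabolic_texts[sample(nrow(metabolic_texts), n_genes, replace = TRUE), ]
  lay |> mutate(function_text = rows$function_text, cog_id = rows$cog_id,
                source_db = "eggnog")
}

plan_to_genes <- function(scaffold_id, plan, offset = 0L) {
  n <- nrow(plan)
  tibble(
    scaffold_id = scaffold_id,
    gene_id = sprintf("%s_g%02d", scaffold_id, seq_len(n)),
    start = plan$rel_start + offset,
    end = plan$rel_end + offset,
    strand = sample(c("+", "-"), n, replace = TRUE),
    cog_id = plan$cog_id,
    function_text = plan$function_text,
    source_db = plan$source_db)
}

#' Plant species-level vOTU clusters with known partition
#'
#' Builds `n_votus` clusters of mutated copies of per-cluster ancestors:
#' members of one cluster are pairwise at `within_identity`, ancestors are
#' pairwise diverged to about `between_identity`, and members overlap
#' full-length so the alignment fraction is ~1. The planted partition is
#' the ground truth for clustering at thresholds strictly between the two
#' identities.
#'
#' @param n_votus Number of clusters.
#' @param members_per_votu Members per cluster (scalar or vector of length
#'   `n_votus`).
#' @param within_identity,between_identity Expected pairwise identities.
#' @param len Ancestor length (nt), scalar or per-cluster vector.
#' @param seed Integer seed.
#' @param prefix Id prefix for the emitted sequences.
#' @return List: `scaffolds` (tibble `id`, `seq`, `length`), `partition`
#'   (tibble `id`, `votu_truth`).
#' @export
plant_votus <- function(n_votus = 3, members_per_votu = 4,
                        within_identity = 0.98, between_identity = 0.80,
                        len = 6000L, seed = 1L, prefix = "vscaf") {
  if (!(within_identity > between_identity)) {
    abort("within_identity must exceed between_identity")
  }
  sizes <- rep_len(members_per_votu, n_votus)
  lens <- rep_len(len, n_votus)
  r_w <- pairwise_rate(within_identity)
  r_b <- pairwise_rate(between_identity)
  with_seed(seed, {
    master <- random_dna(max(lens))
    scaff <- list(); part <- list()
    idx <- 0L
    for (v in seq_len(n_votus)) {
      ancestor <- mutate_seq(substr(master, 1, lens[v]), r_b)
      for (m in seq_len(sizes[v])) {
        idx <- idx + 1L
        id <- sprintf("%s_%03d", prefix, idx)
        scaff[[idx]] <- tibble(id = id,
                               seq = mutate_seq(ancestor, r_w),
                               length = lens[v])
        part[[idx]] <- tibble(id = id, votu_truth = sprintf("truth_%02d", v))
      }
    }
    list(scaffolds = bind_rows(scaff), partition = bind_rows(part))
  })
}

#' Plant CRISPR arrays carrying protospacers from known viruses
#'
#' Appends synthetic CRISPR arrays (4 identical 30-nt direct repeats
#' alternating with 32-nt spacers) to host scaffolds. `n_links` arrays
#' carry one spacer copied verbatim (or reverse-complemented, alternating)
#' from a target virus; `n_decoys` additional arrays carry near-miss
#' spacers differing from the viral source by one central substitution,
#' which must never yield a link under zero-mismatch matching. Viruses
#' shorter than the spacer length are skipped with a warning.
#'
#' @param host_scaffolds Tibble `id`, `seq` of host scaffolds (recycled if
#'   fewer rows than arrays).
#' @param viruses Tibble `id`, `seq` of target viruses.
#' @param n_links Number of planted true links.
#' @param n_decoys Number of decoy arrays.
#' @param spacer_len Spacer length (nt).
#' @param seed Integer seed.
#' @return List: `scaffolds` (host scaffolds with arrays appended),
#'   `links` (tibble `virus_id`, `host_scaffold_id`, `strand`), `decoys`
#'   (tibble `host_scaffold_id`, `source_virus_id`).
#' @export
plant_crispr <- function(host_scaffolds, viruses, n_links = 4, n_decoys = 4,
                         spacer_len = 32L, seed = 1L) {
  with_seed(seed, {
    ok <- nchar(viruses$seq) >= spacer_len + 2L
    if (!all(ok)) {
      warn(sprintf("skipping %d virus(es) shorter than the spacer length",
                   sum(!ok)))
      viruses <- viruses[ok, , drop = FALSE]
    }
    n_arrays <- n_links + n_decoys
    host_idx <- rep_len(seq_len(nrow(host_scaffolds)), n_arrays)
    virus_idx <- rep_len(sample.int(nrow(viruses)), n_arrays)
    links <- list(); decoys <- list()
    for (a in seq_len(n_arrays)) {
      v <- virus_idx[a]
      pos <- sample.int(nchar(viruses$seq[v]) - spacer_len + 1L, 1)
      proto <- substr(viruses$seq[v], pos, pos + spacer_len - 1L)
      is_link <- a <= n_links
      if (is_link) {
        strand <- if (a %% 2 == 0) "-" else "+"
        spacer <- if (strand == "-") revcomp(proto) else proto
        links[[length(links) + 1]] <- tibble(
          virus_id = viruses$id[v],
          host_scaffold_id = host_scaffolds$id[host_idx[a]],
          strand = strand)
      } else {
        mid <- spacer_len %/% 2
        b <- substr(proto, mid, mid)
        spacer <- paste0(substr(proto, 1, mid - 1),
                         sample(setdiff(DNA_BASES, b), 1),
                         substr(proto, mid + 1, spacer_len))
        decoys[[length(decoys) + 1]] <- tibble(
          host_scaffold_id = host_scaffolds$id[host_idx[a]],
          source_virus_id = viruses$id[v])
      }
      rep_seq <- random_dna(30L)
      others <- replicate(2, random_dna(spacer_len))
      array_seq <- paste0(rep_seq, others[1], rep_seq, spacer,
                          rep_seq, others[2], rep_seq)
      hi <- host_idx[a]
      host_scaffolds$seq[hi] <- paste0(host_scaffolds$seq[hi],
                                       random_dna(60L), array_seq)
    }
    host_scaffolds$length <- nchar(host_scaffolds$seq)
    list(scaffolds = host_scaffolds,
         links = bind_rows(links),
         decoys = if (length(decoys) > 0) bind_rows(decoys) else
           tibble(host_scaffold_id = character(), source_virus_id = character()))
  })
}

sim_samples <- function(cfg) {
  with_seed(child_seed(cfg$seed, "samples"), {
    rows <- list()
    for (core in names(cfg$layers_per_core)) {
      L <- cfg$layers_per_core[[core]]
      depth <- sort(seq(5, 55, length.out = L) + runif(L, -1, 1))
      ph <- 2.2 + (7.0 - 2.2) * (depth - min(depth)) / (max(depth) - min(depth)) +
        rnorm(L, 0, 0.12)
      ph <- sort(pmin(pmax(ph, 1.8), 7.4))
      df <- (depth - min(depth)) / (max(depth) - min(depth))
      rows[[core]] <- tibble(
        sample_id = paste0(core, seq_len(L)),
        core = core,
        layer = seq_len(L),
        depth_cm = round(depth, 1),
        pH = round(ph, 2),
        EC = round(pmax(0.3, 8 - 6 * df + rnorm(L, 0, 0.4)), 2),
        TOC = round(0.3 + 1.4 * df + rnorm(L, 0, 0.08), 3),
        TP = round(0.05 + 0.3 * df + rnorm(L, 0, 0.02), 3),
        TS = round(pmax(0.5, 3 + rnorm(L, 0, 0.4)), 2),
        Fe2_TFe = round(pmin(pmax(0.08 + 0.8 * df + rnorm(L, 0, 0.05), 0), 1), 3),
        SO4_TS = round(pmin(pmax(0.85 - 0.7 * df + rnorm(L, 0, 0.05), 0), 1), 3),
        Pb = round(pmax(50, 900 - 400 * df + rnorm(L, 0, 60))),
        Zn = round(pmax(100, 2500 - 900 * df + rnorm(L, 0, 150))),
        Cu = round(pmax(20, 400 - 150 * df + rnorm(L, 0, 30))),
        reads = round(runif(L, cfg$read_count_range[1], cfg$read_count_range[2])))
    }
    bind_rows(rows) |>
      group_by(.data$core) |>
      mutate(surface = .data$layer <= cfg$surface_layers_per_core) |>
      ungroup()
  })
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Builds the full input set of the pipeline — assembly FASTA, gene table,
#' detector calls, scaffold- and gene-level coverage, sample geochemistry,
#' host bins with taxonomy, CRISPR arrays, and a prokaryotic OTU table —
#' for the reference 11-sample, 2-core design, together with the ground
#' truth needed to score every downstream stage. See [sim_config()] for
#' the planted structure.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, all inputs are written in
#'   the formats the package readers consume, plus `ground_truth.json` and
#'   a config echo.
#' @return A `tv_bundle` list: `scaffolds`, `genes`, `calls`, `samples`,
#'   `coverage` (scaffold-level, includes prophage region entities),
#'   `gene_coverage`, `bins`, `bin_taxonomy`, `otus` (long), `truth`
#'   (ground-truth list), `config`.
#' @export
simulate_bundle <- function(cfg = sim_config(), outdir = NULL) {
  samples <- sim_samples(cfg)
  n_s <- nrow(samples)
  n_free_votus <- length(cfg$votu_sizes)

  ## ---- free-virus gene plans, then sequences matching the plans -------
  free_plans <- with_seed(child_seed(cfg$seed, "genes"), {
    purrr::map(seq_len(n_free_votus), function(v) {
      route <- if (v %% 3 == 0) "unknown" else "hallmark"
      extra <- if (v == 1) null_cog_texts else NULL
      viral_gene_plan(route, n_genes = sample(6:8, 1), extra = extra)
    })
  })
  votu_lens <- vapply(free_plans, function(p) max(p$rel_end) + 80L, integer(1))
  pv <- plant_votus(n_votus = n_free_votus, members_per_votu = cfg$votu_sizes,
                    within_identity = cfg$within_votu_identity,
                    between_identity = cfg$between_votu_identity,
                    len = votu_lens, seed = child_seed(cfg$seed, "votus"),
                    prefix = "vscaf")
  free <- pv$scaffolds |>
    left_join(pv$partition, by = "id") |>
    mutate(votu_index = as.integer(sub("truth_", "", .data$votu_truth)))
  free_genes <- with_seed(child_seed(cfg$seed, "free_gene_rows"), {
    purrr::map(seq_len(nrow(free)), function(i) {
      plan_to_genes(free$id[i], free_plans[[free$votu_index[i]]])
    }) |> bind_rows()
  })

  ## ---- AMG carriers (> 10 kb, singleton, hallmark-flanked COG0175) ----
  amg <- with_seed(child_seed(cfg$seed, "amg"), {
    purrr::map(seq_len(cfg$n_amg_carriers), function(i) {
      extra <- tibble(function_text = "phosphoadenosine phosphosulfate reductase",
                      cog_id = "COG0175")
      plan <- viral_gene_plan("hallmark", n_genes = 11, extra = extra,
                              force_edge_hallmark = TRUE)
      while (max(plan$rel_end) <= 10000) {   # carriers must exceed 10 kb
        pad <- viral_gene_plan("hallmark", n_genes = 2)
        off <- max(plan$rel_end) + 100L
        plan <- bind_rows(plan, pad |> mutate(rel_start = .data$rel_start + off,
                                              rel_end = .data$rel_end + off))
      }
      len <- max(plan$rel_end)
      list(id = sprintf("vamg_%02d", i), plan = plan, seq = random_dna(len))
    })
  })
  amg_tbl <- tibble(id = vapply(amg, function(a) a$id, character(1)),
                    seq = vapply(amg, function(a) a$seq, character(1))) |>
    mutate(length = nchar(.data$seq))
  amg_genes <- with_seed(child_seed(cfg$seed, "amg_gene_rows"), {
    bind_rows(purrr::map(amg, function(a) plan_to_genes(a$id, a$plan)))
  })

  ## ---- surface-associated viruses (carry the surface indicator COGs,
  ## present everywhere, coverage enriched in the surface group) ---------
  surf_cogs <- tibble(function_text = c("archaeal phage integrase",
                                        "phage portal protein"),
                      cog_id = c("arCOG01244", "33PZW"))
  surf <- with_seed(child_seed(cfg$seed, "surface_viruses"), {
    purrr::map(seq_len(nrow(surf_cogs)), function(i) {
      plan <- viral_gene_plan("hallmark", n_genes = 7,
                              extra = surf_cogs[i, ])
      len <- max(plan$rel_end)
      list(id = sprintf("vsurf_%02d", i), plan = plan, seq = random_dna(len))
    })
  })
  surf_tbl <- tibble(id = vapply(surf, function(a) a$id, character(1)),
                     seq = vapply(surf, function(a) a$seq, character(1))) |>
    mutate(length = nchar(.data$seq))
  surf_genes <- with_seed(child_seed(cfg$seed, "surf_gene_rows"), {
    bind_rows(purrr::map(surf, function(a) plan_to_genes(a$id, a$plan)))
  })

  ## ---- host bins, prophages -------------------------------------------
  phyla <- c("Euryarchaeota", "Euryarchaeota", "Thermoplasmatota",
             "Proteobacteria", "Nitrospirae", "Firmicutes",
             "Actinobacteria", "Chloroflexi")
  n_bins <- cfg$n_host_bins
  bin_ids <- sprintf("bin_%02d", seq_len(n_bins))
  bin_tax <- tibble(
    bin_id = bin_ids,
    domain = ifelse(seq_len(n_bins) <= 3, "Archaea", "Bacteria"),
    phylum = rep_len(phyla, n_bins))

  prophage_bins <- rep_len(seq_len(n_bins), cfg$n_prophages)
  host <- with_seed(child_seed(cfg$seed, "hosts"), {
    scaffolds <- list(); genes <- list(); truth_pro <- list(); calls <- list()
    hs_idx <- 0L
    for (p in seq_len(cfg$n_prophages)) {
      hs_idx <- hs_idx + 1L
      hid <- sprintf("hscaf_%02d", hs_idx)
      flankL_plan <- host_gene_plan(3)
      flankL_len <- max(flankL_plan$rel_end) + 150L
      pro_plan <- viral_gene_plan("hallmark", n_genes = 7,
                                  force_edge_hallmark = TRUE)
      pro_len <- max(pro_plan$rel_end)
      flankR_plan <- host_gene_plan(3)
      flankR_len <- max(flankR_plan$rel_end) + 150L
      pro_start <- flankL_len
      pro_end <- pro_start + pro_len
      seqs <- paste0(random_dna(flankL_len), random_dna(pro_len),
                     random_dna(flankR_len))
      g <- bind_rows(
        plan_to_genes(hid, flankL_plan, offset = 0L) |>
          mutate(gene_id = sprintf("%s_fl%d", hid, row_number())),
        plan_to_genes(hid, pro_plan, offset = pro_start) |>
          mutate(gene_id = sprintf("%s_pro%d", hid, row_number())),
        plan_to_genes(hid, flankR_plan, offset = pro_end + 150L) |>
          mutate(gene_id = sprintf("%s_fr%d", hid, row_number())))
      truth_pro[[p]] <- tibble(
        viral_id = prophage_region_id(hid, pro_start, pro_end),
        parent_scaffold_id = hid,
        region_start = pro_start, region_end = pro_end,
        bin_id = bin_ids[prophage_bins[p]])
      # predicted region padded by one flanking gene on each side; the
      # hallmark-boundary trim must recover the planted region
      calls[[p]] <- tibble(
        scaffold_id = hid, detector = "virsorter",
        virsorter_category = if (p %% 2 == 0) 5L else 4L,
        region_start = flankL_plan$rel_start[3],
        region_end = pro_end + 150L + flankR_plan$rel_end[1])
      scaffolds[[hs_idx]] <- tibble(id = hid, seq = seqs, length = nchar(seqs),
                                    bin_id = bin_ids[prophage_bins[p]])
      genes[[hs_idx]] <- g
    }
    for (b in seq_len(n_bins)) {
      hs_idx <- hs_idx + 1L
      hid <- sprintf("hscaf_%02d", hs_idx)
      plan <- host_gene_plan(sample(7:10, 1))
      len <- max(plan$rel_end) + 200L
      scaffolds[[hs_idx]] <- tibble(id = hid, seq = random_dna(len),
                                    length = len, bin_id = bin_ids[b])
      genes[[hs_idx]] <- plan_to_genes(hid, plan)
    }
    list(scaffolds = bind_rows(scaffolds), genes = bind_rows(genes),
         truth_pro = bind_rows(truth_pro), pro_calls = bind_rows(calls))
  })

  # shared genomic content: the first AMG carrier shares a ~3 kb region at
  # ~95% identity with the last plain host scaffold
  host$scaffolds <- with_seed(child_seed(cfg$seed, "shared"), {
    block <- mutate_seq(substr(amg_tbl$seq[1], 1, 3000), 0.025)
    i <- nrow(host$scaffolds)
    host$scaffolds$seq[i] <- paste0(host$scaffolds$seq[i], random_dna(80), block)
    host$scaffolds$length[i] <- nchar(host$scaffolds$seq[i])
    host$scaffolds
  })
  truth_shared <- tibble(
    virus_id = amg_tbl$id[1],
    bin_id = host$scaffolds$bin_id[nrow(host$scaffolds)],
    host_scaffold_id = host$scaffolds$id[nrow(host$scaffolds)])

  ## ---- CRISPR arrays (targets: singleton viruses only, so vOTU siblings
  ## cannot carry coincidental copies of a planted protospacer) ----------
  singleton_free <- free |> filter(cfg$votu_sizes[.data$votu_index] == 1L)
  spacer_targets <- bind_rows(singleton_free |> select("id", "seq"),
                              amg_tbl |> select("id", "seq"))
  pc <- plant_crispr(host_scaffolds = host$scaffolds |> select("id", "seq"),
                     viruses = spacer_targets,
                     n_links = cfg$n_spacer_links,
                     n_decoys = cfg$n_decoy_spacers,
                     seed = child_seed(cfg$seed, "crispr"))
  host$scaffolds <- host$scaffolds |>
    select("id", "bin_id") |>
    left_join(pc$scaffolds, by = "id") |>
    select("id", "seq", "length", "bin_id")
  truth_spacer <- pc$links |>
    left_join(host$scaffolds |> select(host_scaffold_id = "id", "bin_id"),
              by = "host_scaffold_id")

  ## ---- decoys ----------------------------------------------------------
  decoys <- with_seed(child_seed(cfg$seed, "decoys"), {
    purrr::map(seq_len(cfg$n_decoys), function(i) {
      id <- sprintf("dscaf_%02d", i)
      plan <- host_gene_plan(9)
      plan$function_text[c(2, 5)] <- "hypothetical protein"
      plan$cog_id[c(2, 5)] <- ""
      plan$source_db[c(2, 5)] <- "none"
      len <- max(plan$rel_end) + 100L
      list(scaffold = tibble(id = id, seq = random_dna(len), length = len),
           genes = plan_to_genes(id, plan))
    })
  })
  decoy_scaffolds <- bind_rows(purrr::map(decoys, "scaffold"))
  decoy_genes <- bind_rows(purrr::map(decoys, "genes"))

  ## ---- detector calls --------------------------------------------------
  calls <- with_seed(child_seed(cfg$seed, "calls"), {
    vir_ids <- c(free$id, amg_tbl$id, surf_tbl$id)
    vir_len <- c(free$length, amg_tbl$length, surf_tbl$length)
    rows <- list()
    for (i in seq_along(vir_ids)) {
      mode <- i %% 3   # 0: both, 1: protein-family only, 2: virsorter only
      if (vir_len[i] < 5000) mode <- 2
      if (mode %in% c(0, 1)) {
        rows[[length(rows) + 1]] <- tibble(
          scaffold_id = vir_ids[i], detector = "protein_family",
          virsorter_category = NA_integer_,
          region_start = NA_integer_, region_end = NA_integer_)
      }
      if (mode %in% c(0, 2)) {
        rows[[length(rows) + 1]] <- tibble(
          scaffold_id = vir_ids[i], detector = "virsorter",
          virsorter_category = sample(1:2, 1),
          region_start = NA_integer_, region_end = NA_integer_)
      }
    }
    # false-positive calls on half the decoys (curation must reject them)
    for (i in seq_len(ceiling(cfg$n_decoys / 2))) {
      rows[[length(rows) + 1]] <- tibble(
        scaffold_id = decoy_scaffolds$id[i], detector = "protein_family",
        virsorter_category = NA_integer_,
        region_start = NA_integer_, region_end = NA_integer_)
    }
    bind_rows(rows)
  })
  # protein-family call on the first prophage scaffold: the dedup rule
  # must drop it in favour of the trimmed prophage
  calls <- bind_rows(
    calls,
    tibble(scaffold_id = host$truth_pro$parent_scaffold_id[1],
           detector = "protein_family", virsorter_category = NA_integer_,
           region_start = NA_integer_, region_end = NA_integer_),
    host$pro_calls)

  ## ---- assemble scaffold & gene tables --------------------------------
  scaffolds <- bind_rows(
    free |> select("id", "seq", "length"),
    amg_tbl,
    surf_tbl,
    host$scaffolds |> select("id", "seq", "length"),
    decoy_scaffolds)
  genes <- bind_rows(free_genes, amg_genes, surf_genes, host$genes,
                     decoy_genes) |>
    arrange(.data$scaffold_id, .data$start)
  bins <- host$scaffolds |> select(scaffold_id = "id", "bin_id")

  ## ---- planted coverage ------------------------------------------------
  act_depth <- setNames(seq(0, 50, length.out = n_free_votus),
                        sprintf("truth_%02d", seq_len(n_free_votus)))
  depth_of <- setNames(samples$depth_cm, samples$sample_id)
  is_surface <- setNames(samples$surface, samples$sample_id)
  ph_of <- setNames(samples$pH, samples$sample_id)
  target_ra <- pmin(pmax(0.50 + cfg$prophage_ph_slope * (ph_of - 2), 0.03), 0.90)

  covs <- with_seed(child_seed(cfg$seed, "coverage"), {
    base_votu <- rlnorm(n_free_votus, log(4), 0.4)
    base_amg <- rlnorm(cfg$n_amg_carriers, log(3), 0.3)
    base_pro <- rlnorm(cfg$n_prophages, log(1), 0.2)
    free_cov <- purrr::map(seq_len(nrow(free)), function(i) {
      vt <- free$votu_index[i]
      present <- depth_of >= act_depth[vt] - 1e-9
      cov <- base_votu[vt] / cfg$votu_sizes[vt] *
        exp(rnorm(n_s, 0, cfg$noise_sd)) * present
      tibble(entity_id = free$id[i], sample_id = names(depth_of), cov = cov)
    }) |> bind_rows()
    amg_cov <- purrr::map(seq_len(nrow(amg_tbl)), function(i) {
      mult <- ifelse(is_surface, 1, cfg$amg_depth_enrichment)
      cov <- base_amg[i] * mult * exp(rnorm(n_s, 0, cfg$noise_sd))
      tibble(entity_id = amg_tbl$id[i], sample_id = names(depth_of), cov = cov)
    }) |> bind_rows()
    base_surf <- rlnorm(nrow(surf_tbl), log(2), 0.3)
    surf_cov <- purrr::map(seq_len(nrow(surf_tbl)), function(i) {
      mult <- ifelse(is_surface, cfg$amg_depth_enrichment, 1)
      cov <- base_surf[i] * mult * exp(rnorm(n_s, 0, cfg$noise_sd))
      tibble(entity_id = surf_tbl$id[i], sample_id = names(depth_of), cov = cov)
    }) |> bind_rows()
    free_tot <- bind_rows(free_cov, amg_cov, surf_cov) |>
      group_by(.data$sample_id) |>
      summarise(tot = sum(.data$cov), .groups = "drop")
    pro_tot <- target_ra / (1 - target_ra) *
      free_tot$tot[match(names(ph_of), free_tot$sample_id)]
    pro_share <- base_pro / sum(base_pro)
    pro_cov <- purrr::map(seq_len(cfg$n_prophages), function(p) {
      cov <- pro_tot * pro_share[p] * exp(rnorm(n_s, 0, 0.15))
      tibble(entity_id = host$truth_pro$viral_id[p],
             sample_id = names(ph_of), cov = cov)
    }) |> bind_rows()
    dfrac <- (depth_of - min(depth_of)) / diff(range(depth_of))
    host_cov <- purrr::map(seq_len(nrow(host$scaffolds)), function(i) {
      arch <- bin_tax$domain[match(host$scaffolds$bin_id[i],
                                   bin_tax$bin_id)] == "Archaea"
      mult <- if (arch) exp(-2 * dfrac) else exp(1.5 * dfrac)
      tibble(entity_id = host$scaffolds$id[i], sample_id = names(depth_of),
             cov = rlnorm(1, log(8), 0.3) * mult * exp(rnorm(n_s, 0, cfg$noise_sd)))
    }) |> bind_rows()
    decoy_cov <- purrr::map(seq_len(nrow(decoy_scaffolds)), function(i) {
      tibble(entity_id = decoy_scaffolds$id[i], sample_id = names(depth_of),
             cov = rlnorm(1, log(2), 0.3) * exp(rnorm(n_s, 0, cfg$noise_sd)))
    }) |> bind_rows()
    bind_rows(free_cov, amg_cov, surf_cov, pro_cov, host_cov, decoy_cov)
  })

  entity_lengths <- bind_rows(
    scaffolds |> select(entity_id = "id", "length"),
    host$truth_pro |>
      mutate(length = .data$region_end - .data$region_start) |>
      select(entity_id = "viral_id", "length"))
  coverage <- covs |>
    left_join(entity_lengths, by = "entity_id") |>
    mutate(mapped_nt = round(.data$cov * .data$length)) |>
    select("entity_id", "sample_id", "mapped_nt")

  # gene-level coverage follows the carrying entity with mild jitter;
  # genes inside a planted prophage region follow the region's coverage
  gene_entity <- genes |>
    left_join(host$truth_pro |>
                select(scaffold_id = "parent_scaffold_id", "viral_id",
                       "region_start", "region_end"),
              by = "scaffold_id") |>
    mutate(entity_id = ifelse(!is.na(.data$viral_id) &
                                .data$start >= .data$region_start &
                                .data$end <= .data$region_end,
                              .data$viral_id, .data$scaffold_id)) |>
    select("gene_id", "entity_id", "start", "end")
  gene_coverage <- with_seed(child_seed(cfg$seed, "gene_cov"), {
    gene_entity |>
      left_join(covs, by = "entity_id", relationship = "many-to-many") |>
      mutate(cov = .data$cov * exp(rnorm(n(), 0, 0.1)),
             mapped_nt = round(.data$cov * (.data$end - .data$start))) |>
      select(entity_id = "gene_id", "sample_id", "mapped_nt")
  })

  ## ---- prokaryotic OTU table ------------------------------------------
  otus <- with_seed(child_seed(cfg$seed, "otus"), {
    n_arch <- 8L; n_bact <- 32L
    otu_ids <- sprintf("OTU_%03d", seq_len(n_arch + n_bact))
    phy <- c(rep_len(c("Euryarchaeota", "Euryarchaeota", "Thermoplasmatota"),
                     n_arch),
             rep_len(c("Proteobacteria", "Nitrospirae", "Firmicutes",
                       "Actinobacteria", "Chloroflexi", "Acidobacteria"),
                     n_bact))
    dom <- c(rep("Archaea", n_arch), rep("Bacteria", n_bact))
    act <- c(rep(0, n_arch), seq(0, 50, length.out = n_bact))
    w_base <- rlnorm(n_arch + n_bact, 0, 0.5)
    dfrac <- (depth_of - min(depth_of)) / diff(range(depth_of))
    arch_frac <- pmin(pmax(0.68 - 0.62 * dfrac + rnorm(n_s, 0, 0.02), 0.05), 0.9)
    rows <- list()
    for (s in seq_len(n_s)) {
      present <- depth_of[s] >= act - 1e-9
      w <- w_base * present * exp(rnorm(length(act), 0, 0.3))
      wa <- w * (dom == "Archaea"); wb <- w * (dom == "Bacteria")
      w_final <- arch_frac[s] * wa / sum(wa) + (1 - arch_frac[s]) * wb / sum(wb)
      total <- round(runif(1, 4e4, 1.3e5))
      rows[[s]] <- tibble(otu_id = otu_ids, domain = dom, phylum = phy,
                          sample_id = names(depth_of)[s],
                          count = round(w_final * total))
    }
    bind_rows(rows)
  })

  ## ---- ground truth ----------------------------------------------------
  family_of_votu <- setNames(
    rep_len(c("Siphoviridae", "Myoviridae", "Podoviridae", "unclassified"),
            n_free_votus),
    sprintf("truth_%02d", seq_len(n_free_votus)))
  taxonomy <- bind_rows(
    free |> mutate(family = family_of_votu[.data$votu_truth]) |>
      select("id", "family"),
    tibble(id = c(amg_tbl$id, surf_tbl$id, host$truth_pro$viral_id),
           family = "unclassified"))
  # realized per-layer family fractions over the planted viral community
  viral_cov <- covs |>
    inner_join(taxonomy, by = c(entity_id = "id"))
  family_fractions <- viral_cov |>
    group_by(.data$sample_id, .data$family) |>
    summarise(cov = sum(.data$cov), .groups = "drop_last") |>
    mutate(fraction = .data$cov / sum(.data$cov)) |>
    ungroup() |>
    select("sample_id", "family", "fraction")
  votu_partition <- bind_rows(
    free |> select("id", cluster = "votu_truth"),
    tibble(id = amg_tbl$id, cluster = paste0("amg_", seq_len(nrow(amg_tbl)))),
    tibble(id = surf_tbl$id, cluster = paste0("surf_", seq_len(nrow(surf_tbl)))),
    tibble(id = host$truth_pro$viral_id,
           cluster = paste0("pro_", seq_len(nrow(host$truth_pro)))))
  planted_indicators <- c(COG0175 = "deep", arCOG01244 = "surface",
                          `33PZW` = "surface")
  truth <- list(
    planted_viral_ids = c(free$id, amg_tbl$id, surf_tbl$id,
                          host$truth_pro$viral_id),
    planted_prophages = host$truth_pro,
    votu_partition = votu_partition,
    taxonomy = taxonomy,
    family_fractions = family_fractions,
    spacer_links = truth_spacer,
    decoy_spacers = pc$decoys,
    shared_content_link = truth_shared,
    amg_ids = amg_tbl$id,
    indicator_cogs = planted_indicators,
    null_cogs = null_cog_texts$cog_id,
    rejected_decoy_ids = decoy_scaffolds$id,
    target_prophage_ra = tibble(sample_id = names(ph_of),
                                target_prophage_ra = unname(target_ra)),
    groups = samples |>
      mutate(group = ifelse(.data$surface, "surface", "deep")) |>
      select("sample_id", "group"))

  bundle <- structure(list(
    scaffolds = scaffolds, genes = genes, calls = calls, samples = samples,
    coverage = coverage, gene_coverage = gene_coverage, bins = bins,
    bin_taxonomy = bin_tax, otus = otus, truth = truth, config = cfg),
    class = "tv_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' @param bundle A `tv_bundle` from [simulate_bundle()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$scaffolds, file.path(outdir, "assembly.fasta"))
  write_gene_table(bundle$genes, file.path(outdir, "genes.tsv"))
  calls_out <- bundle$calls |> mutate(region_start = .data$region_start + 1L)
  write_tsv_file(calls_out, file.path(outdir, "detector_calls.tsv"))
  write_tsv_file(bundle$samples, file.path(outdir, "samples.tsv"))
  write_tsv_file(bundle$coverage, file.path(outdir, "coverage_scaffolds.tsv"))
  write_tsv_file(bundle$gene_coverage, file.path(outdir, "coverage_genes.tsv"))
  write_tsv_file(bundle$bins, file.path(outdir, "bins.tsv"))
  write_tsv_file(bundle$bin_taxonomy, file.path(outdir, "bin_taxonomy.tsv"))
  otu_wide <- bundle$otus |>
    pivot_wider(names_from = "sample_id", values_from = "count")
  write_tsv_file(otu_wide, file.path(outdir, "otu_table.tsv"))
  jsonlite::write_json(bundle$truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(unclass(bundle$config), file.path(outdir, "sim_config.yaml"))
  invisible(outdir)
}

#' @export
print.tv_bundle <- function(x, ...) {
  cat(sprintf("<tv_bundle: %d scaffolds, %d genes, %d samples, %d planted viruses>\n",
              nrow(x$scaffolds), nrow(x$genes), nrow(x$samples),
              length(x$truth$planted_viral_ids)))
  invisible(x)
}
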