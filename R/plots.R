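# ggplot2 graphics for the main result types.

#' Plot an ordination
#'
#' Scatter of the first two ordination axes, optionally coloured and
#' shaped by sample metadata.
#'
#' @param ord A `tv_ordination` from [pcoa_ord()] or [pca_ord()].
#' @param metadata Optional tibble with `sample_id` plus the columns named
#'   by `colour`/`shape`.
#' @param colour,shape Column names in `metadata` (strings) or `NULL`.
#' @return A ggplot object.
#' @export
plot_ordination <- function(ord, metadata = NULL, colour = NULL, shape = NULL) {
  df <- ord$coordinates
  if (!is.null(metadata)) df <- df |> left_join(metadata, by = "sample_id")
  pe <- 100 * ord$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = if (is.null(colour)) NULL else .data[[colour]],
      shape = if (is.null(shape)) NULL else .data[[shape]]), size = 3) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", pe[1]),
      y = sprintf("Axis 2 (%.1f%%)", if (length(pe) > 1) pe[2] else NA),
      colour = colour, shape = shape,
      title = sprintf("%s ordination", ord$method)) +
    ggplot2::theme_minimal()
  p
}

#' @rdname plot_ordination
#' @param object,... `autoplot` method arguments (passed on).
#' @export
autoplot.tv_ordination <- function(object, ...) plot_ordination(object, ...)

#' Depth profiles of geochemistry and richness
#'
#' Faceted depth profiles (depth on the y axis, increasing downwards) of
#' selected per-sample variables, one line per core — the standard way to
#' display stratified core data.
#'
#' @param samples Sample tibble with `sample_id`, `core`, `depth_cm` and
#'   the variables.
#' @param vars Character vector of columns to plot.
#' @param richness Optional richness tibble (`sample_id`, `richness`)
#'   appended as another panel.
#' @return A ggplot object.
#' @export
plot_depth_profiles <- function(samples, vars = c("pH", "EC", "TOC"),
                                richness = NULL) {
  df <- samples |> select("sample_id", "core", "depth_cm", any_of(vars))
  if (!is.null(richness)) {
    df <- df |> left_join(richness, by = "sample_id")
    vars <- c(vars, setdiff(names(richness), "sample_id"))
  }
  long <- df |>
    pivot_longer(all_of(vars), names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth_cm,
                                     colour = .data$core)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(y = "depth (cm)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Prophage relative abundance against pH
#'
#' Scatter with a least-squares line, annotated with the Pearson
#' correlation computed by [pearson_cor()].
#'
#' @param prophage_ra Tibble `sample_id`, `prophage_rel_abundance`.
#' @param samples Sample tibble with `sample_id`, `pH` (and `core` for
#'   colouring when present).
#' @return A ggplot object.
#' @export
plot_prophage_ph <- function(prophage_ra, samples) {
  df <- prophage_ra |> left_join(samples, by = "sample_id")
  ct <- pearson_cor(df$pH, df$prophage_rel_abundance)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pH,
                                        y = .data$prophage_rel_abundance))
  if ("core" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$core), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(y = "prophage relative abundance",
                  subtitle = sprintf("Pearson r = %.2f, p = %.3g",
                                     ct$statistic, ct$p_value)) +
    ggplot2::theme_minimal()
}

#' Heatmap of indicator-COG profiles
#'
#' Tile heatmap of log-transformed, row-z-scored normalized coverage of
#' the indicator COGs, with rows ordered by average-linkage clustering
#' ([cluster_cog_profiles()]) and samples ordered surface before deep.
#'
#' @param indicators A `tv_indicators` tibble ([indicator_cogs()]).
#' @param cog_cov Long COG coverage ([cog_coverage()]).
#' @param groups `sample_id`/`group` tibble.
#' @param top Number of indicator COGs to show per direction.
#' @return A ggplot object.
#' @export
plot_indicator_heatmap <- function(indicators, cog_cov, groups, top = 10) {
  keep <- indicators |>
    filter(.data$indicator) |>
    group_by(.data$direction) |>
    arrange(.data$q_value, .by_group = TRUE) |>
    slice(seq_len(top)) |>
    pull(.data$cog_id)
  if (length(keep) == 0) abort("no indicator COGs to plot")
  wide <- cog_cov |>
    filter(.data$cog_id %in% keep) |>
    pivot_wider(names_from = "sample_id", values_from = "norm_cov",
                values_fill = 0)
  m <- as.matrix(wide[-1]); rownames(m) <- wide$cog_id
  row_ord <- if (nrow(m) > 2) rownames(m)[cluster_cog_profiles(m)$order]
  else rownames(m)
  col_ord <- groups |> arrange(desc(.data$group == "surface")) |>
    pull(.data$sample_id)
  z <- t(scale(t(log10(m + 1e-6))))
  long <- as_tibble(z, rownames = "cog_id") |>
    pivot_longer(-"cog_id", names_to = "sample_id", values_to = "z") |>
    mutate(cog_id = factor(.data$cog_id, levels = row_ord),
           sample_id = factor(.data$sample_id,
                              levels = intersect(col_ord, colnames(z))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$cog_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(log10 cov)") +
    ggplot2::theme_minimal()
}
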