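#' Remove promoter-overlapping peaks
#'
#' Non-promoter H3K27ac peaks proxy active enhancers: any peak with >= 1 bp
#' overlap of a promoter window is removed.
#'
#' @param peaks Interval tibble of peak calls.
#' @param promoter_windows Promoter-window tibble.
#' @return The peaks without promoter overlap.
#' @export
filter_nonpromoter_peaks <- function(peaks, promoter_windows) {
  validate_intervals(peaks, "peaks")
  validate_intervals(promoter_windows, "promoter_windows")
  keep <- !overlaps_any(as_granges(peaks), as_granges(promoter_windows))
  as_tibble(peaks[keep, , drop = FALSE])
}

#' Re-center regions to a fixed width
#'
#' Each region is replaced by a `size`-bp window around its midpoint
#' (clipped at position 0), harmonizing merged peaks of unequal width before
#' tag counting.
#'
#' @param regions Interval tibble.
#' @param size Fixed window width in bp (default 500).
#' @return Interval tibble of re-centered windows.
#' @export
recenter_regions <- function(regions, size = 500) {
  validate_intervals(regions, "regions")
  stopifnot(size > 0)
  mid <- floor((regions$start + regions$end) / 2)
  half <- size / 2
  tibble(
    chrom = regions$chrom,
    start = pmax(0, floor(mid - half)),
    end = floor(mid - half) + size
  ) %>%
    mutate(end = pmax(.data$end, .data$start + size))
}

#' One-sided Poisson upper-tail probability
#'
#' `P(X >= observed)` for `X ~ Poisson(lambda)`; non-integer observations
#' are rounded up to the next integer count.
#'
#' @param observed Observed tag counts.
#' @param lambda Poisson means.
#' @return Tail probabilities.
#' @export
poisson_tail <- function(observed, lambda) {
  k <- ceiling(observed)
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Fold-change + Poisson differential region test
#'
#' A region is flagged (in the requested direction) iff its fold change is
#' at least `fold_min` and the one-sided Poisson tail probability
#' `P(X >= observed)` — with the mean set to the comparison sample's
#' normalized count, floored at 1 pseudo-tag — is below `p_max`. Counts are
#' expected on a shared per-10M normalized scale.
#'
#' @param region_scores Tibble with `chrom`, `start`, `end` (or an `id`
#'   column) plus numeric columns `control` and `treatment` of normalized
#'   tag counts.
#' @param fold_min Minimum fold change (default 2).
#' @param p_max Maximum tail probability (default 0.05).
#' @param direction `"up"` (treatment above control) or `"down"`.
#' @return The input tibble with `fold`, `p` and logical `flagged` columns,
#'   filtered to flagged regions.
#' @export
differential_regions_by_count <- function(region_scores, fold_min = 2,
                                          p_max = 0.05,
                                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(all(c("control", "treatment") %in% names(region_scores)))
  if (nrow(region_scores) == 0) abort("empty region set.")
  obs <- if (direction == "up") region_scores$treatment else region_scores$control
  cmp <- if (direction == "up") region_scores$control else region_scores$treatment
  lambda <- pmax(cmp, 1)
  out <- region_scores %>%
    mutate(
      fold = obs / lambda,
      p = poisson_tail(obs, lambda),
      flagged = .data$fold >= fold_min & .data$p < p_max
    )
  filter(out, .data$flagged)
}

#' Consensus of per-sample differential region sets
#'
#' Thin delegate to [consensus_regions()]: the base-pair intersection across
#' samples of independently called differential regions.
#'
#' @param per_sample List of >= 2 interval tibbles.
#' @return Consensus interval tibble.
#' @export
consensus_differential <- function(per_sample) {
  consensus_regions(per_sample, require_all = TRUE)
}

#' Normalized region scores (tags per 10 million reads)
#'
#' @param region_counts Tibble with region coordinates (or `region_id`), a
#'   `sample` column, raw `count` and per-sample `library_size`.
#' @return The tibble with `tags_per_10M` added.
#' @export
score_regions <- function(region_counts) {
  stopifnot(all(c("count", "library_size") %in% names(region_counts)))
  if (any(region_counts$library_size <= 0)) abort("library_size must be positive.")
  mutate(region_counts, tags_per_10M = .data$count * 1e7 / .data$library_size)
}

#' Row-z-scored matrix for heatmap export
#'
#' Per-region (row) z-scores of a region-by-sample score tibble, the
#' `scale = "row"` heatmap convention. Zero-variance rows map to 0, not NaN,
#' so exports are deterministic.
#'
#' @param mat Tibble `id` + sample columns (or numeric matrix).
#' @return Tibble of identical shape with z-scored rows.
#' @export
heatmap_zscore <- function(mat) {
  is_tbl <- is.data.frame(mat)
  m <- if (is_tbl) matrix_from_tbl(mat) else as.matrix(mat)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  if (!is_tbl) return(z)
  out <- as_tibble(z)
  out <- mutate(out, id = mat$id)
  select(out, "id", dplyr::everything())
}

#' Threshold a DEG table into up/down gene sets
#'
#' The printed rule: `up` iff `log2fc > lfc_min` and `padj < padj_max`;
#' `down` iff `log2fc < -lfc_min` and `padj < padj_max` (strict
#' inequalities).
#'
#' @param deg DEG tibble (`gene_id`, `log2fc`, `padj`).
#' @param lfc_min Log2 fold-change bound (default 1).
#' @param padj_max Adjusted-p bound (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(deg, lfc_min = 1, padj_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(deg)))
  list(
    up = deg$gene_id[deg$log2fc > lfc_min & deg$padj < padj_max],
    down = deg$gene_id[deg$log2fc < -lfc_min & deg$padj < padj_max]
  )
}

#' Four-way gene grouping from two DEG contrasts
#'
#' Crosses disease-driven deregulation (e.g. Ph+ vs healthy) with
#' drug sensitivity (e.g. DMSO vs TKI): `PH_UP_TKI_DOWN` = up in disease and
#' down on drug; `PH_UP_ONLY` = up in disease, not drug-sensitive;
#' `TKI_DOWN_ONLY` = drug-downregulated but not disease-deregulated;
#' `OTHER` = the remainder of the universe. The result partitions the
#' universe (asserted).
#'
#' @param ph_degs,tki_degs Lists with `up`/`down` gene vectors
#'   (from [call_degs()]).
#' @param universe Character vector of assessed (active) genes.
#' @return Tibble `gene_id`, `gene_group`.
#' @export
group_genes <- function(ph_degs, tki_degs, universe) {
  ph_up <- intersect(ph_degs$up, universe)
  ph_any <- intersect(union(ph_degs$up, ph_degs$down), universe)
  tki_down <- intersect(tki_degs$down, universe)
  out <- tibble(gene_id = universe) %>%
    mutate(gene_group = dplyr::case_when(
      .data$gene_id %in% ph_up & .data$gene_id %in% tki_down ~ "PH_UP_TKI_DOWN",
      .data$gene_id %in% ph_up ~ "PH_UP_ONLY",
      .data$gene_id %in% tki_down & !(.data$gene_id %in% ph_any) ~ "TKI_DOWN_ONLY",
      TRUE ~ "OTHER"
    ))
  stopifnot(nrow(out) == length(universe), !anyNA(out$gene_group))
  out
}
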