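#' Annotate interaction ends with peak and promoter status
#'
#' Each end of every interaction is intersected (1-bp, half-open, strand
#' ignored) with the H3K27ac peak set and with the promoter windows. An end
#' is "peak-positive" if it overlaps any peak, and a "promoter" end if it
#' overlaps at least one promoter window; the full set of overlapped gene
#' ids is kept per end as a list column.
#'
#' @param interactions Interaction tibble (see the interaction readers).
#' @param peaks Interval tibble of H3K27ac peak calls.
#' @param promoters Promoter-window tibble from [make_promoter_windows()].
#' @return The interactions with added columns `peak1`, `peak2` (logical),
#'   `genes1`, `genes2` (list of gene ids), `promoter1`, `promoter2`
#'   (logical).
#' @export
annotate_ends <- function(interactions, peaks, promoters) {
  validate_interactions(interactions)
  validate_intervals(peaks, "peaks")
  validate_intervals(promoters, "promoters")
  peak_gr <- as_granges(peaks)
  prom_gr <- as_granges(promoters)

  annotate_one <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    peak_hit <- overlaps_any(gr, peak_gr)
    u <- unify_seqlevels(gr, prom_gr)
    hits <- GenomicRanges::findOverlaps(u$a, u$b)
    genes <- rep(list(character()), length(gr))
    if (length(hits) > 0) {
      by_q <- split(
        promoters$gene_id[S4Vectors::subjectHits(hits)],
        S4Vectors::queryHits(hits)
      )
      genes[as.integer(names(by_q))] <- lapply(by_q, function(g) sort(unique(g)))
    }
    list(peak = peak_hit, genes = genes)
  }

  if (nrow(interactions) == 0) {
    interactions$peak1 <- logical()
    interactions$peak2 <- logical()
    interactions$genes1 <- list()
    interactions$genes2 <- list()
    interactions$promoter1 <- logical()
    interactions$promoter2 <- logical()
    return(interactions)
  }
  e1 <- annotate_one(interactions$chrom1, interactions$start1, interactions$end1)
  e2 <- annotate_one(interactions$chrom2, interactions$start2, interactions$end2)
  interactions$peak1 <- e1$peak
  interactions$peak2 <- e2$peak
  interactions$genes1 <- e1$genes
  interactions$genes2 <- e2$genes
  interactions$promoter1 <- lengths(e1$genes) > 0
  interactions$promoter2 <- lengths(e2$genes) > 0
  interactions
}

#' Classify annotated interactions
#'
#' In `pchic` mode (asymmetric bait/other-end design; requires `bait_end`):
#' the activity class crosses bait and other-end H3K27ac status — `AP_AO`,
#' `AP_IO`, `IP_AO`, `IP_IO` (active/inactive promoter bait vs active/
#' inactive other end). The regulatory class is `EPI` when an active
#' (peak-positive) promoter bait contacts a peak-positive non-promoter other
#' end, `PPI` when the other end is a peak-positive promoter (promoter
#' identity takes precedence over the enhancer reading when an other end is
#' both; set `ambiguous_oe = "both"` to additionally count such contacts as
#' EPIs downstream via the `oe_also_enhancer` column), otherwise `none`.
#'
#' In `hichip` mode the ends are symmetric and H3K27ac is guaranteed by the
#' assay: `PPI` if both ends are promoters, `EEI` if neither is, `EPI`
#' otherwise. No activity class is emitted.
#'
#' @param interactions Annotated interaction tibble from [annotate_ends()].
#' @param mode `"pchic"` or `"hichip"`.
#' @param ambiguous_oe `"ppi"` (default) or `"both"` — how to treat other
#'   ends overlapping both a promoter window and a peak.
#' @return The interactions with `regulatory_class` (and, in pchic mode,
#'   `activity_class` and `oe_also_enhancer`) columns added.
#' @export
classify_interactions <- function(interactions, mode = c("pchic", "hichip"),
                                  ambiguous_oe = c("ppi", "both")) {
  mode <- match.arg(mode)
  ambiguous_oe <- match.arg(ambiguous_oe)
  needed <- c("peak1", "peak2", "promoter1", "promoter2")
  if (!all(needed %in% names(interactions))) {
    abort("interactions must be annotated with annotate_ends() first.")
  }
  if (mode == "pchic") {
    if (!"bait_end" %in% names(interactions) ||
        any(is.na(interactions$bait_end))) {
      abort("pchic mode requires bait/other-end role tags (`bait_end`).")
    }
    swap <- interactions$bait_end == 2L
    bait_peak <- ifelse(swap, interactions$peak2, interactions$peak1)
    oe_peak <- ifelse(swap, interactions$peak1, interactions$peak2)
    oe_promoter <- ifelse(swap, interactions$promoter1, interactions$promoter2)
    interactions$activity_class <- paste0(
      ifelse(bait_peak, "AP", "IP"), "_", ifelse(oe_peak, "AO", "IO")
    )
    interactions$regulatory_class <- dplyr::case_when(
      bait_peak & oe_peak & !oe_promoter ~ "EPI",
      bait_peak & oe_peak & oe_promoter ~ "PPI",
      TRUE ~ "none"
    )
    interactions$oe_also_enhancer <-
      ambiguous_oe == "both" & bait_peak & oe_peak & oe_promoter
  } else {
    p1 <- interactions$promoter1
    p2 <- interactions$promoter2
    interactions$regulatory_class <- dplyr::case_when(
      p1 & p2 ~ "PPI",
      !p1 & !p2 ~ "EEI",
      TRUE ~ "EPI"
    )
  }
  interactions
}

#' Classify active promoters by their interaction repertoire
#'
#' Active genes are those with mean normalized expression of at least
#' `active_count_min` across the reference samples and a peak-positive
#' promoter window. Each active gene aggregates the regulatory classes of
#' the interactions whose bait maps to its promoter and receives exactly one
#' label: `EPI_ONLY`, `PPI_ONLY`, `EPI_AND_PPI`, or `NO_ACTIVE_OE` (contacts
#' exist but none reach a peak-positive other end — or no significant
#' contacts at all; `has_any_interaction` separates the two). Baits touching
#' several promoter windows contribute to every overlapped gene.
#'
#' @param interactions Classified pchic-mode interaction tibble.
#' @param promoters Promoter-window tibble.
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param peaks Interval tibble of peaks, used to set promoter activity.
#' @param active_count_min Minimum mean normalized count (default 10).
#' @param expression_samples Columns of `expression` defining the reference
#'   condition; default all sample columns.
#' @return Tibble of active genes: `gene_id`, `promoter_class`, `n_epi`,
#'   `n_ppi`, `has_any_interaction`, `mean_expression`.
#' @export
classify_promoters <- function(interactions, promoters, expression, peaks,
                               active_count_min = 10,
                               expression_samples = NULL) {
  if (!"regulatory_class" %in% names(interactions)) {
    abort("interactions must be classified with classify_interactions() first.")
  }
  sample_cols <- expression_samples %||% setdiff(names(expression), "gene_id")
  expr_mean <- tibble(
    gene_id = expression$gene_id,
    mean_expression = rowMeans(as.matrix(expression[, sample_cols, drop = FALSE]))
  )
  genes <- distinct(promoters, .data$gene_id)
  genes <- left_join(genes, expr_mean, by = "gene_id")
  if (any(is.na(genes$mean_expression))) {
    warn(sprintf(
      "%d promoter gene(s) missing from the expression table; treated as 0.",
      sum(is.na(genes$mean_expression))
    ))
    genes$mean_expression[is.na(genes$mean_expression)] <- 0
  }
  prom_active <- annotate_promoter_activity(promoters, peaks)
  genes <- left_join(genes, prom_active, by = "gene_id")
  genes$active <- genes$mean_expression >= active_count_min & genes$peak_positive

  # bait gene -> interaction class bookkeeping
  swap <- interactions$bait_end == 2L
  bait_genes <- interactions$genes1
  bait_genes[swap] <- interactions$genes2[swap]
  per_gene <- tibble(
    gene_id = unlist(bait_genes),
    regulatory_class = rep(interactions$regulatory_class, lengths(bait_genes))
  )
  counts <- per_gene %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_epi = sum(.data$regulatory_class == "EPI"),
      n_ppi = sum(.data$regulatory_class == "PPI"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  out <- genes %>%
    filter(.data$active) %>%
    left_join(counts, by = "gene_id") %>%
    mutate(
      n_epi = dplyr::coalesce(.data$n_epi, 0L),
      n_ppi = dplyr::coalesce(.data$n_ppi, 0L),
      has_any_interaction = dplyr::coalesce(.data$n_total, 0L) > 0,
      promoter_class = dplyr::case_when(
        .data$n_epi > 0 & .data$n_ppi > 0 ~ "EPI_AND_PPI",
        .data$n_epi > 0 ~ "EPI_ONLY",
        .data$n_ppi > 0 ~ "PPI_ONLY",
        TRUE ~ "NO_ACTIVE_OE"
      )
    ) %>%
    select("gene_id", "promoter_class", "n_epi", "n_ppi",
           "has_any_interaction", "mean_expression")
  # the four labels must partition the active gene set
  stopifnot(sum(table(out$promoter_class)) == nrow(out))
  out
}

annotate_promoter_activity <- function(promoters, peaks) {
  hit <- overlaps_any(as_granges(promoters), as_granges(peaks))
  tibble(gene_id = promoters$gene_id, peak_positive = hit) %>%
    group_by(.data$gene_id) %>%
    summarise(peak_positive = any(.data$peak_positive), .groups = "drop")
}

#' Normalize raw interaction counts per 10 million reads
#'
#' `score = raw_count * 1e7 / library_size`, the HiChIP interaction-score
#' convention.
#'
#' @param interactions Interaction tibble with `raw_count`.
#' @param library_size Total reads; defaults to the per-row `library_size`
#'   column attached by [read_interactions_bedpe()].
#' @return The interactions with `score` set.
#' @examples
#' x <- tibble::tibble(raw_count = 5)
#' normalize_per_10M(x, library_size = 5e6)$score # 10
#' @export
normalize_per_10M <- function(interactions, library_size = NULL) {
  if (!"raw_count" %in% names(interactions)) {
    abort("interactions lack a raw_count column.")
  }
  ls <- library_size %||%
    (if ("library_size" %in% names(interactions)) interactions$library_size)
  if (is.null(ls)) abort("no library_size column or argument supplied.")
  if (any(ls <= 0)) abort("library_size must be positive.")
  interactions$score <- interactions$raw_count * 1e7 / ls
  interactions
}

#' Collapse duplicate interaction records
#'
#' One record per (sample, canonical id); among duplicates the record with
#' the largest `raw_count` wins (ties: first occurrence). Records whose ends
#' are swapped share a canonical id and therefore collapse.
#'
#' @param interactions Interaction tibble with canonical `id`s.
#' @return Deduplicated interaction tibble.
#' @export
deduplicate_interactions <- function(interactions) {
  validate_interactions(interactions)
  key_count <- if ("raw_count" %in% names(interactions)) {
    interactions$raw_count
  } else {
    rep(0, nrow(interactions))
  }
  key_count[is.na(key_count)] <- 0
  interactions %>%
    mutate(.key = key_count, .ord = row_number()) %>%
    arrange(.data$sample, .data$id, dplyr::desc(.data$.key), .data$.ord) %>%
    distinct(.data$sample, .data$id, .keep_all = TRUE) %>%
    select(-".key", -".ord")
}
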