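#' Pipeline configuration
#'
#' One serializable source of truth for an end-to-end run: every threshold
#' the analysis uses, the sample-group layout (carried by the synthetic
#' config) and the seed. Unknown keys are rejected so typos cannot silently
#' disable a threshold.
#'
#' @param seed Integer seed for the run.
#' @param chicago_min Interaction significance floor (default 5).
#' @param active_count_min Active-gene expression floor (default 10).
#' @param lfc_min DEG log2 fold-change bound (default 1).
#' @param padj_max DEG adjusted-p bound (default 0.05).
#' @param fold_min Differential-region fold bound (default 2).
#' @param p_max Differential-region tail-probability bound (default 0.05).
#' @param merge_gap Peak merge gap in bp (default 1000).
#' @param flank Promoter flank in bp (default 1000).
#' @param region_size Fixed differential-region width (default 500).
#' @param synergy_bound Bliss call threshold (default 10).
#' @param synthetic A [synthetic_config()]; defaults to
#'   `synthetic_config(seed)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            chicago_min = 5,
                            active_count_min = 10,
                            lfc_min = 1,
                            padj_max = 0.05,
                            fold_min = 2,
                            p_max = 0.05,
                            merge_gap = 1000,
                            flank = 1000,
                            region_size = 500,
                            synergy_bound = 10,
                            synthetic = NULL) {
  cfg <- as.list(environment())
  cfg$synthetic <- synthetic %||% synthetic_config(seed = seed)
  thresholds <- c(
    cfg$chicago_min, cfg$active_count_min, cfg$lfc_min, cfg$padj_max,
    cfg$fold_min, cfg$p_max, cfg$merge_gap, cfg$flank, cfg$region_size,
    cfg$synergy_bound
  )
  if (any(thresholds <= 0)) abort("all thresholds must be positive.")
  structure(cfg, class = "pipeline_config")
}

#' Coerce a plain list (e.g. parsed from a config file) to a pipeline config
#'
#' @param x Named list of config keys.
#' @return A validated `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate -> classify -> signature -> differential -> integrate,
#' writing each stage's tables under `out_dir` (TSV/BED/Newick, all plain
#' text). Every run is deterministic under the config seed: re-running with
#' the same config yields byte-identical outputs. Progress is logged to
#' `stderr` and to `<out_dir>/run.log`; the manifest carries the config
#' hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress stderr logging.
#' @return Invisibly, a list with `summary` (per-stage row counts), `files`
#'   (paths), `md5` (file checksums) and key results (`gene_classes`,
#'   `enrichment`, `pca`, `upgma`, `concordance`, `synergy`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage_rows <- list()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  say("pipeline start: seed %d, config hash %s", config$seed, rlang::hash(config))

  # simulate -------------------------------------------------------------
  study <- generate_synthetic_study(config$synthetic)
  write_study_bundle(study, file.path(out_dir, "simulate"))
  stage_rows$simulate <- nrow(study$interactions)
  say("simulate: %d genes, %d interaction records", nrow(study$truth$genes),
      nrow(study$interactions))

  # classify -------------------------------------------------------------
  peaks_ref <- filter(study$peaks, .data$sample == "chip_1",
                      .data$condition == "dmso")
  ints_dmso <- filter(study$interactions, .data$condition == "dmso")
  ints_dmso <- annotate_ends(ints_dmso, peaks_ref, study$promoters)
  ints_dmso <- classify_interactions(ints_dmso, mode = "pchic")
  dmso_cols <- study$sample_info$sample[study$sample_info$condition == "dmso"]
  gene_classes <- classify_promoters(
    filter(ints_dmso, .data$sample == "ph_1"),
    study$promoters, study$expression, peaks_ref,
    active_count_min = config$active_count_min,
    expression_samples = dmso_cols
  )
  flat_ints <- select(ints_dmso, -"genes1", -"genes2")
  readr::write_tsv(flat_ints, file.path(out_dir, "interaction_classes.tsv"),
                   progress = FALSE)
  readr::write_tsv(gene_classes, file.path(out_dir, "gene_classes.tsv"),
                   progress = FALSE)
  stage_rows$classify <- nrow(gene_classes)
  say("classify: %d active genes labelled", nrow(gene_classes))

  # signature ------------------------------------------------------------
  core <- core_interactions(ints_dmso, class_filter = c("EPI", "PPI"))
  mat <- build_matrix(core, select(ints_dmso, "sample", "id", "score"),
                      missing_policy = "zero")
  fit_upgma <- upgma(mat)
  fit_pca <- pca_signatures(mat)
  readr::write_tsv(tidy(fit_upgma), file.path(out_dir, "upgma_merges.tsv"),
                   progress = FALSE)
  writeLines(upgma_newick(fit_upgma), file.path(out_dir, "upgma.nwk"))
  readr::write_tsv(tidy(fit_pca), file.path(out_dir, "pca_coordinates.tsv"),
                   progress = FALSE)
  readr::write_tsv(glance(fit_pca), file.path(out_dir, "pca_variance.tsv"),
                   progress = FALSE)
  stage_rows$signature <- length(core)
  say("signature: %d core interactions across %d samples", length(core),
      length(unique(ints_dmso$sample)))

  # differential ---------------------------------------------------------
  chip_samples <- unique(study$peaks$sample)
  per_sample_lost <- purrr::map(chip_samples, function(s) {
    ref <- filter(study$peaks, .data$sample == s, .data$condition == "dmso")
    trt <- filter(study$peaks, .data$sample == s, .data$condition == "tki")
    ref_np <- filter_nonpromoter_peaks(ref, study$promoters)
    trt_np <- filter_nonpromoter_peaks(trt, study$promoters)
    lost <- presence_absence_differential(ref_np, trt_np)$lost
    merge_within_gap(lost[, c("chrom", "start", "end")], gap = config$merge_gap)
  })
  consensus_lost <- consensus_differential(per_sample_lost)
  write_bed(consensus_lost, file.path(out_dir, "consensus_lost_regions.bed"))
  diff_regions <- differential_regions_by_count(
    study$region_counts,
    fold_min = config$fold_min, p_max = config$p_max, direction = "down"
  )
  readr::write_tsv(diff_regions, file.path(out_dir, "differential_regions.tsv"),
                   progress = FALSE)
  zmat <- heatmap_zscore(tibble(
    id = study$region_counts$region_id,
    control = study$region_counts$control,
    treatment = study$region_counts$treatment
  ))
  readr::write_tsv(zmat, file.path(out_dir, "region_zscores.tsv"),
                   progress = FALSE)
  stage_rows$differential <- nrow(diff_regions)
  say("differential: %d consensus lost regions, %d flagged by count test",
      nrow(consensus_lost), nrow(diff_regions))

  # integrate ------------------------------------------------------------
  drug_sets <- call_degs(study$deg$drug, lfc_min = config$lfc_min,
                         padj_max = config$padj_max)
  ph_sets <- call_degs(study$deg$ph, lfc_min = config$lfc_min,
                       padj_max = config$padj_max)
  groups <- group_genes(ph_sets, drug_sets, universe = gene_classes$gene_id)
  epi_pos <- gene_classes$gene_id[
    gene_classes$promoter_class %in% c("EPI_ONLY", "EPI_AND_PPI")
  ]
  epi_neg <- setdiff(gene_classes$gene_id, epi_pos)
  enrich <- set_enrichment(epi_pos, epi_neg, positive = drug_sets$down,
                           labels = c("EPI+", "EPI-"))
  hic <- normalize_per_10M(deduplicate_interactions(study$hichip))
  hic <- annotate_ends(hic, peaks_ref, study$promoters)
  loops <- count_gene_loops(hic)
  loop_lfc <- hichip_gene_log2fc(
    loops,
    group_a = study$hichip_samples$sample[study$hichip_samples$group == "ph"],
    group_b = study$hichip_samples$sample[study$hichip_samples$group == "kmt2a"]
  )
  concord <- interaction_expression_concordance(loop_lfc, study$deg$ph)
  plate <- normalize_viability(study$viability, reference = "dmso")
  synergy <- bliss_synergy(pmin(viability_matrix(plate), 1))
  readr::write_tsv(groups, file.path(out_dir, "gene_groups.tsv"), progress = FALSE)
  readr::write_tsv(glance(enrich), file.path(out_dir, "epi_enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(loop_lfc, file.path(out_dir, "hichip_gene_log2fc.tsv"),
                   progress = FALSE)
  readr::write_tsv(concord, file.path(out_dir, "loop_expression_concordance.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(synergy), file.path(out_dir, "bliss_grid.tsv"),
                   progress = FALSE)
  readr::write_tsv(glance(synergy), file.path(out_dir, "bliss_summary.tsv"),
                   progress = FALSE)
  stage_rows$integrate <- nrow(groups)
  say("integrate: EPI+ fraction %.2f vs %.2f, rho %.2f, Bliss %s (%.1f)",
      enrich$fraction_a, enrich$fraction_b, concord$rho, synergy$call,
      synergy$mean_score)

  summary <- tibble(
    stage = names(stage_rows),
    n_rows = unlist(stage_rows),
    config_hash = rlang::hash(config)
  )
  readr::write_tsv(summary, file.path(out_dir, "run_summary.tsv"), progress = FALSE)
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE, full.names = TRUE),
    file.path(out_dir, "run.log")
  ))
  invisible(list(
    summary = summary,
    files = files,
    md5 = tools::md5sum(files),
    gene_classes = gene_classes,
    enrichment = enrich,
    pca = fit_pca,
    upgma = fit_upgma,
    concordance = concord,
    synergy = synergy
  ))
}
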