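#' Configuration for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: a small genome of
#' evenly spaced gene slots, planted promoter classes, an expression model
#' with a log-scale boost for EPI+ genes, a drug-sensitivity model in which
#' EPI+ genes are sensitive with probability 0.7 against a 0.2 baseline, a
#' two-group interaction-score model for signature analyses, HiChIP loop
#' counts coupled to expression differences, and a Bliss-synergistic
#' viability plate. All randomness derives from `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genes Total genes (default 200).
#' @param n_chroms Chromosomes the gene slots are spread over (default 4).
#' @param gene_slot_bp Per-gene genomic slot (default 20000 bp).
#' @param chrom_length_bp Optional explicit chromosome length; must fit the
#'   gene slots or generation errors before writing anything.
#' @param frac_inactive Fraction of genes planted inactive (default 0.15).
#' @param class_fractions Named fractions (summing to 1) of active genes per
#'   planted promoter class.
#' @param flank Promoter flank bp (default 1000).
#' @param peak_width H3K27ac peak width bp (default 800).
#' @param jitter_sd Per-sample peak-position jitter sd in bp (default 0).
#' @param expr_meanlog2,expr_sdlog2 Log2-scale base expression mean and
#'   gene-level sd for active genes (defaults 6 and 0.5).
#' @param inactive_meanlog2 Log2 expression of planted-inactive genes.
#' @param epi_boost_log2 Additive log2 expression boost for EPI+ genes.
#' @param rep_noise_log2 Replicate-level log2 noise sd (default 0.25).
#' @param n_reps Replicates per expression condition (default 3).
#' @param p_sensitive_epi,p_sensitive_other Drug-sensitivity probabilities
#'   for EPI+ vs other active genes (defaults 0.7 / 0.2).
#' @param drug_effect_log2 Log2 expression effect in treated sensitive genes
#'   (default -2).
#' @param p_ph_up,p_ph_down Fractions of active genes up-/down-regulated in
#'   the disease group vs healthy (defaults 0.3 / 0.15).
#' @param ph_effect_log2 Magnitude of the disease expression effect.
#' @param n_samples_per_group,n_groups Interaction-sample layout (3 x 2).
#' @param score_base_range CHiCAGO-convention base score range.
#' @param score_noise_sd Per-sample score noise sd (default 0.5).
#' @param n_group_specific Interactions with a group-specific score shift.
#' @param score_shift Group-specific score shift (default 5).
#' @param chicago_min Significance floor planted interactions never drop
#'   below (default 5).
#' @param hichip_base_lambda Mean loops per gene per HiChIP sample.
#' @param hichip_count_lambda Mean raw read count per loop.
#' @param region_tag_mean Mean control tag count for differential regions.
#' @param region_fold Planted fold change of drug-lost regions (default 4).
#' @param bliss_excess Planted Bliss excess (viability scale, default 0.15).
#' @param viability_noise_sd Plate noise sd (default 0.01).
#' @param n_experiments Viability plate replicates (default 3).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_genes = 200,
                             n_chroms = 4,
                             gene_slot_bp = 20000,
                             chrom_length_bp = NULL,
                             frac_inactive = 0.15,
                             class_fractions = c(
                               EPI_ONLY = 0.35, PPI_ONLY = 0.15,
                               EPI_AND_PPI = 0.20, NO_ACTIVE_OE = 0.30
                             ),
                             flank = 1000,
                             peak_width = 800,
                             jitter_sd = 0,
                             expr_meanlog2 = 6,
                             expr_sdlog2 = 0.5,
                             inactive_meanlog2 = 1,
                             epi_boost_log2 = 1,
                             rep_noise_log2 = 0.25,
                             n_reps = 3,
                             p_sensitive_epi = 0.7,
                             p_sensitive_other = 0.2,
                             drug_effect_log2 = -2,
                             p_ph_up = 0.3,
                             p_ph_down = 0.15,
                             ph_effect_log2 = 2,
                             n_samples_per_group = 3,
                             n_groups = 2,
                             score_base_range = c(8, 15),
                             score_noise_sd = 0.5,
                             n_group_specific = 40,
                             score_shift = 5,
                             chicago_min = 5,
                             hichip_base_lambda = 2,
                             hichip_count_lambda = 20,
                             region_tag_mean = 50,
                             region_fold = 4,
                             bliss_excess = 0.15,
                             viability_noise_sd = 0.01,
                             n_experiments = 3) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory.")
  cfg <- as.list(environment())
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8) {
    abort("class_fractions must sum to 1.")
  }
  if (!setequal(
    names(cfg$class_fractions),
    c("EPI_ONLY", "PPI_ONLY", "EPI_AND_PPI", "NO_ACTIVE_OE")
  )) {
    abort("class_fractions must name the four promoter classes.")
  }
  sds <- c(cfg$jitter_sd, cfg$expr_sdlog2, cfg$rep_noise_log2,
           cfg$score_noise_sd, cfg$viability_noise_sd)
  if (any(sds < 0)) abort("all sd parameters must be >= 0.")
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  needed_bp <- genes_per_chrom * cfg$gene_slot_bp
  if (is.null(cfg$chrom_length_bp)) {
    cfg$chrom_length_bp <- needed_bp
  } else if (cfg$chrom_length_bp < needed_bp) {
    abort(sprintf(
      "infeasible geometry: %d genes x %d bp slots need %d bp per chromosome, got %d.",
      genes_per_chrom, cfg$gene_slot_bp, needed_bp, cfg$chrom_length_bp
    ))
  }
  structure(cfg, class = "synthetic_config")
}

# vectorized Welch t on log2 values, BH-adjusted; the generator's DEG tables
# are computed from its own counts so pipeline and truth cannot disagree
compute_deg_table <- function(expr, ref_samples, trt_samples) {
  ref <- log2(as.matrix(expr[, ref_samples, drop = FALSE]) + 0.5)
  trt <- log2(as.matrix(expr[, trt_samples, drop = FALSE]) + 0.5)
  n1 <- ncol(ref)
  n2 <- ncol(trt)
  m1 <- rowMeans(ref)
  m2 <- rowMeans(trt)
  v1 <- apply(ref, 1, stats::var)
  v2 <- apply(trt, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  tibble(
    gene_id = expr$gene_id,
    log2fc = log2((rowMeans(as.matrix(expr[, trt_samples, drop = FALSE])) + 0.5) /
                    (rowMeans(as.matrix(expr[, ref_samples, drop = FALSE])) + 0.5)),
    padj = p.adjust(p, method = "BH")
  )
}

#' Generate a complete synthetic study with known ground truth
#'
#' Emits every downstream tabular product of the study design — annotation,
#' per-sample H3K27ac peaks under control and drug conditions, per-sample
#' significant interactions (CHiCAGO-score convention, shared fragment map
#' so canonical ids intersect cleanly across samples), HiChIP loops with raw
#' counts and library sizes, expression tables, DEG tables computed from the
#' generated counts by the standard thresholds, differential-region tag
#' counts, and a dose-response viability plate — together with the planted
#' ground truth for each. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of tibbles: `annotation`, `promoters`, `peaks` (long, with
#'   `sample` and `condition`), `interactions` (long, with `sample`,
#'   `group`, `condition`), `hichip`, `hichip_samples`, `expression`,
#'   `sample_info`, `deg` (list `drug`, `ph`), `region_counts`, `viability`,
#'   and `truth` (list `genes`, `interactions`, `regions`, `bliss_excess`).
#' @export
generate_synthetic_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_synthetic_study_impl(config))
}

generate_synthetic_study_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("gene_%04d", seq_len(n))
  genes_per_chrom <- ceiling(n / cfg$n_chroms)
  chrom <- paste0("chr", ((seq_len(n) - 1) %/% genes_per_chrom) + 1)
  slot <- (seq_len(n) - 1) %% genes_per_chrom
  offset <- slot * cfg$gene_slot_bp
  strand <- rep(c("+", "-"), length.out = n)

  annotation <- tibble(
    chrom = chrom,
    txStart = offset + 5000,
    txEnd = offset + 7000,
    strand = strand,
    gene_id = gene_id
  )
  promoters <- make_promoter_windows(annotation, flank = cfg$flank)

  # planted classes ------------------------------------------------------
  n_inactive <- round(cfg$frac_inactive * n)
  inactive <- rep(FALSE, n)
  if (n_inactive > 0) inactive[sample.int(n, n_inactive)] <- TRUE
  active_idx <- which(!inactive)
  n_active <- length(active_idx)
  class_names <- c("EPI_ONLY", "PPI_ONLY", "EPI_AND_PPI", "NO_ACTIVE_OE")
  counts <- floor(cfg$class_fractions[class_names] * n_active)
  rem <- n_active - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  planted_class <- rep(NA_character_, n)
  planted_class[active_idx[sample.int(n_active)]] <- rep(class_names, counts)

  is_epi_plus <- !inactive & planted_class %in% c("EPI_ONLY", "EPI_AND_PPI")
  sensitive <- !inactive &
    rbinom(n, 1, ifelse(is_epi_plus, cfg$p_sensitive_epi,
                        cfg$p_sensitive_other)) == 1
  ph_draw <- runif(n)
  ph_up <- !inactive & ph_draw < cfg$p_ph_up
  ph_down <- !inactive & ph_draw >= cfg$p_ph_up &
    ph_draw < cfg$p_ph_up + cfg$p_ph_down
  ph_lfc <- ifelse(ph_up, cfg$ph_effect_log2,
                   ifelse(ph_down, -cfg$ph_effect_log2, 0))

  # among NO_ACTIVE_OE genes, half have a contact to a peakless OE
  dead_oe <- rep(FALSE, n)
  no_oe_idx <- which(!inactive & planted_class == "NO_ACTIVE_OE")
  if (length(no_oe_idx) > 1) {
    dead_oe[no_oe_idx[seq_len(floor(length(no_oe_idx) / 2))]] <- TRUE
  }

  tss <- promoters$tss[match(gene_id, promoters$gene_id)]
  enh_start <- offset + 12000
  dead_start <- offset + 15000

  truth_genes <- tibble(
    gene_id = gene_id, chrom = chrom,
    planted_class = ifelse(inactive, "INACTIVE", planted_class),
    active = !inactive,
    has_interaction = !inactive & (planted_class != "NO_ACTIVE_OE" | dead_oe),
    sensitive = sensitive, ph_up = ph_up, ph_down = ph_down,
    ph_lfc = ph_lfc
  )

  # expression -----------------------------------------------------------
  mu <- ifelse(inactive, cfg$inactive_meanlog2,
               cfg$expr_meanlog2 + cfg$epi_boost_log2 * is_epi_plus +
                 rnorm(n, 0, cfg$expr_sdlog2))
  conditions <- c("dmso", "tki", "healthy")
  sample_info <- tidyr::expand_grid(condition = conditions,
                                    rep = seq_len(cfg$n_reps)) %>%
    mutate(sample = paste0(.data$condition, "_", .data$rep))
  expr <- tibble(gene_id = gene_id)
  for (i in seq_len(nrow(sample_info))) {
    cond <- sample_info$condition[i]
    shift <- switch(cond,
      dmso = 0,
      tki = cfg$drug_effect_log2 * sensitive,
      healthy = -ph_lfc
    )
    expr[[sample_info$sample[i]]] <-
      2^(mu + shift + rnorm(n, 0, cfg$rep_noise_log2))
  }

  dmso_samples <- sample_info$sample[sample_info$condition == "dmso"]
  deg <- list(
    drug = compute_deg_table(expr, dmso_samples,
                             sample_info$sample[sample_info$condition == "tki"]),
    ph = compute_deg_table(expr, sample_info$sample[sample_info$condition == "healthy"],
                           dmso_samples)
  )

  # H3K27ac peaks: promoter peaks at active genes, enhancer peaks at EPI+
  # genes; under drug, sensitive EPI+ genes lose their enhancer peak ------
  half_pk <- cfg$peak_width / 2
  base_peaks <- bind_rows(
    tibble(
      chrom = chrom[!inactive],
      start = pmax(0, tss[!inactive] - half_pk),
      end = tss[!inactive] + half_pk,
      kind = "promoter", gene_id = gene_id[!inactive]
    ),
    tibble(
      chrom = chrom[is_epi_plus],
      start = enh_start[is_epi_plus],
      end = enh_start[is_epi_plus] + cfg$peak_width,
      kind = "enhancer", gene_id = gene_id[is_epi_plus]
    )
  )
  chip_samples <- paste0("chip_", seq_len(cfg$n_samples_per_group))
  lost_enh <- is_epi_plus & sensitive
  peaks <- purrr::map_dfr(chip_samples, function(s) {
    jit <- if (cfg$jitter_sd > 0) {
      round(rnorm(nrow(base_peaks), 0, cfg$jitter_sd))
    } else {
      rep(0, nrow(base_peaks))
    }
    pk <- mutate(base_peaks,
      start = pmax(0, .data$start + jit), end = .data$end + jit,
      sample = s
    )
    bind_rows(
      mutate(pk, condition = "dmso"),
      mutate(
        filter(pk, !(.data$kind == "enhancer" &
                       .data$gene_id %in% gene_id[lost_enh])),
        condition = "tki"
      )
    )
  })

  # PCHi-C interactions (shared fragment map across all samples) ---------
  prom_win <- promoters[match(gene_id, promoters$gene_id), ]
  partner <- integer(n)
  partner[active_idx] <- active_idx[c(seq_along(active_idx)[-1], 1)]
  base_int <- bind_rows(
    tibble(
      gene = gene_id[is_epi_plus], kind = "epi",
      chrom1 = chrom[is_epi_plus],
      start1 = prom_win$start[is_epi_plus], end1 = prom_win$end[is_epi_plus],
      chrom2 = chrom[is_epi_plus],
      start2 = enh_start[is_epi_plus],
      end2 = enh_start[is_epi_plus] + cfg$peak_width
    ),
    {
      ppi <- !inactive & planted_class %in% c("PPI_ONLY", "EPI_AND_PPI")
      tibble(
        gene = gene_id[ppi], kind = "ppi",
        chrom1 = chrom[ppi],
        start1 = prom_win$start[ppi], end1 = prom_win$end[ppi],
        chrom2 = chrom[partner[ppi]],
        start2 = prom_win$start[partner[ppi]],
        end2 = prom_win$end[partner[ppi]]
      )
    },
    tibble(
      gene = gene_id[dead_oe], kind = "dead",
      chrom1 = chrom[dead_oe],
      start1 = prom_win$start[dead_oe], end1 = prom_win$end[dead_oe],
      chrom2 = chrom[dead_oe],
      start2 = dead_start[dead_oe],
      end2 = dead_start[dead_oe] + cfg$peak_width
    )
  )
  base_int$id <- canonical_interaction_id(
    base_int$chrom1, base_int$start1, base_int$end1,
    base_int$chrom2, base_int$start2, base_int$end2
  )
  base_int$base_score <- runif(nrow(base_int), cfg$score_base_range[1],
                               cfg$score_base_range[2])
  n_spec <- min(cfg$n_group_specific, sum(base_int$kind == "epi"))
  base_int$group_specific <- FALSE
  base_int$group_specific[sample(which(base_int$kind == "epi"), n_spec)] <- TRUE

  groups <- c("ph", "ctrl")[seq_len(cfg$n_groups)]
  pchic_layout <- tidyr::expand_grid(group = groups,
                                     rep = seq_len(cfg$n_samples_per_group)) %>%
    mutate(sample = paste0(.data$group, "_", .data$rep))
  interactions <- purrr::map_dfr(seq_len(nrow(pchic_layout)), function(i) {
    g <- pchic_layout$group[i]
    sc <- base_int$base_score +
      cfg$score_shift * (base_int$group_specific & g == "ph") +
      rnorm(nrow(base_int), 0, cfg$score_noise_sd)
    # generator contract: planted interactions stay significant
    sc <- pmax(sc, cfg$chicago_min + 0.5)
    dmso <- mutate(base_int,
      sample = pchic_layout$sample[i], group = g, condition = "dmso",
      score = sc, raw_count = NA_real_, bait_end = 1L
    )
    tki <- filter(dmso, !(.data$gene %in% gene_id[sensitive] &
                            .data$kind == "epi")) %>%
      mutate(condition = "tki")
    bind_rows(dmso, tki)
  }) %>%
    select("id", "sample", "group", "condition", "chrom1", "start1", "end1",
           "chrom2", "start2", "end2", "gene", "kind", "raw_count", "score",
           "bait_end")

  # HiChIP loops: per-gene loop intensity coupled to the disease
  # expression effect so loop and expression fold changes are concordant --
  hichip_groups <- c("ph", "kmt2a")
  hichip_layout <- tidyr::expand_grid(group = hichip_groups,
                                      rep = seq_len(cfg$n_samples_per_group)) %>%
    mutate(
      sample = paste0("hichip_", .data$group, "_", .data$rep),
      library_size = round(runif(dplyr::n(), 8e6, 1.2e7))
    )
  max_loop_slots <- 5
  hichip <- purrr::map_dfr(seq_len(nrow(hichip_layout)), function(i) {
    g <- hichip_layout$group[i]
    lam <- cfg$hichip_base_lambda *
      2^(ifelse(g == "ph", 1, -1) * ph_lfc / 2)
    n_loops <- pmin(rpois(n, lam), max_loop_slots)
    n_loops[inactive] <- 0
    keep <- which(n_loops > 0)
    if (length(keep) == 0) return(tibble())
    idx <- rep(keep, n_loops[keep])
    k <- unlist(lapply(n_loops[keep], seq_len)) - 1
    tibble(
      sample = hichip_layout$sample[i], group = g,
      chrom1 = chrom[idx],
      start1 = prom_win$start[idx], end1 = prom_win$end[idx],
      chrom2 = chrom[idx],
      start2 = enh_start[idx] + 1200 * k,
      end2 = enh_start[idx] + 1200 * k + cfg$peak_width,
      gene = gene_id[idx],
      raw_count = rpois(length(idx), cfg$hichip_count_lambda) + 1,
      library_size = hichip_layout$library_size[i]
    )
  })
  if (nrow(hichip) > 0) {
    hichip$id <- canonical_interaction_id(
      hichip$chrom1, hichip$start1, hichip$end1,
      hichip$chrom2, hichip$start2, hichip$end2
    )
  }

  # differential-region tag counts (per-10M scale via fixed library) -----
  region_idx <- which(is_epi_plus)
  region_lib <- 1e7
  region_control <- rpois(length(region_idx), cfg$region_tag_mean)
  region_down <- sensitive[region_idx]
  region_treat <- rpois(
    length(region_idx),
    ifelse(region_down, cfg$region_tag_mean / cfg$region_fold,
           cfg$region_tag_mean)
  )
  region_counts <- tibble(
    region_id = sprintf("%s:%d-%d", chrom[region_idx], enh_start[region_idx],
                        enh_start[region_idx] + cfg$peak_width),
    chrom = chrom[region_idx],
    start = enh_start[region_idx],
    end = enh_start[region_idx] + cfg$peak_width,
    gene_id = gene_id[region_idx],
    control = region_control * 1e7 / region_lib,
    treatment = region_treat * 1e7 / region_lib
  )

  # viability plate with planted Bliss excess ----------------------------
  doses_a <- c(0, 1, 2, 4, 8)
  doses_b <- c(0, 0.0625, 0.125, 0.25)
  plate <- tidyr::expand_grid(
    experiment = paste0("exp_", seq_len(cfg$n_experiments)),
    dose_a = doses_a, dose_b = doses_b
  ) %>%
    mutate(
      yA = .data$dose_a / (.data$dose_a + 2),
      yB = 0.5 * .data$dose_b / (.data$dose_b + 0.125),
      viability_true = pmin(pmax(
        (1 - .data$yA) * (1 - .data$yB) -
          cfg$bliss_excess * (.data$dose_a > 0 & .data$dose_b > 0),
        0
      ), 1),
      signal = pmax(
        .data$viability_true * 5e4 *
          (1 + rnorm(dplyr::n(), 0, cfg$viability_noise_sd)),
        0
      )
    ) %>%
    select("experiment", "dose_a", "dose_b", "signal")

  list(
    config = cfg,
    annotation = annotation,
    promoters = promoters,
    peaks = peaks,
    interactions = interactions,
    pchic_samples = pchic_layout,
    hichip = hichip,
    hichip_samples = hichip_layout,
    expression = expr,
    sample_info = sample_info,
    deg = deg,
    region_counts = region_counts,
    viability = plate,
    truth = list(
      genes = truth_genes,
      interactions = select(base_int, "id", "gene", "kind", "base_score",
                            "group_specific"),
      regions = tibble(region_id = region_counts$region_id,
                       planted_down = region_down),
      bliss_excess = cfg$bliss_excess
    )
  )
}

#' Write a synthetic study to disk in the package's file dialects
#'
#' Emits BED peak files per sample and condition, ibed interaction files per
#' sample, BEDPE HiChIP files per sample, expression/DEG/viability TSVs, and
#' a manifest listing every file with the seed and a config hash. Re-running
#' with the same config yields byte-identical files.
#'
#' @param study Output of [generate_synthetic_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(rel) {
    files <<- c(files, rel)
    file.path(dir, rel)
  }
  readr::write_tsv(study$annotation, emit("annotation.tsv"), progress = FALSE)
  pk <- study$peaks
  for (s in unique(pk$sample)) {
    for (cond in unique(pk$condition)) {
      sub <- filter(pk, .data$sample == s, .data$condition == cond)
      write_bed(sub[, c("chrom", "start", "end")],
                emit(sprintf("peaks_%s_%s.bed", s, cond)))
    }
  }
  ints <- study$interactions
  for (s in unique(ints$sample)) {
    for (cond in unique(ints$condition)) {
      sub <- filter(ints, .data$sample == s, .data$condition == cond)
      write_interactions_ibed(sub, emit(sprintf("pchic_%s_%s.ibed", s, cond)))
    }
  }
  if (nrow(study$hichip) > 0) {
    for (s in unique(study$hichip$sample)) {
      sub <- filter(study$hichip, .data$sample == s)
      write_interactions_bedpe(sub, emit(sprintf("%s.bedpe", s)))
    }
  }
  readr::write_tsv(study$hichip_samples, emit("hichip_samples.tsv"), progress = FALSE)
  readr::write_tsv(study$expression, emit("expression.tsv"), progress = FALSE)
  readr::write_tsv(study$sample_info, emit("sample_info.tsv"), progress = FALSE)
  readr::write_tsv(study$deg$drug, emit("deg_drug.tsv"), progress = FALSE)
  readr::write_tsv(study$deg$ph, emit("deg_ph.tsv"), progress = FALSE)
  readr::write_tsv(study$region_counts, emit("region_counts.tsv"), progress = FALSE)
  readr::write_tsv(study$viability, emit("viability.tsv"), progress = FALSE)
  readr::write_tsv(study$truth$genes, emit("truth_genes.tsv"), progress = FALSE)
  manifest <- tibble(
    file = files,
    seed = study$config$seed,
    config_hash = rlang::hash(study$config)
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
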