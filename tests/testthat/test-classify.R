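mini_annot <- function() {
  tibble::tibble(
    chrom = "chr1",
    txStart = c(5000, 25000), txEnd = c(7000, 27000),
    strand = "+", gene_id = c("gA", "gB")
  )
}

test_that("end annotation records peak and promoter overlaps per end", {
  prom <- make_promoter_windows(mini_annot())
  peaks <- genomic_intervals("chr1", c(4600, 12000), c(5400, 12800))
  ints <- tibble::tibble(
    id = c("i1", "i2"), sample = "s1",
    chrom1 = "chr1", start1 = c(4000, 4000), end1 = c(6000, 6000),
    chrom2 = "chr1", start2 = c(12000, 30000), end2 = c(12800, 30800),
    bait_end = 1L
  )
  ann <- annotate_ends(ints, peaks, prom)
  expect_true(ann$peak1[1] && ann$promoter1[1])
  expect_equal(ann$genes1[[1]], "gA")
  expect_true(ann$peak2[1] && !ann$promoter2[1]) # peak, no promoter
  expect_false(ann$peak2[2] || ann$promoter2[2]) # neither
})

test_that("end annotation agrees with an all-pairs brute-force oracle", {
  withr::with_seed(31, {
    peaks <- random_intervals(60)
    prom_src <- random_intervals(40)
    prom <- tibble::tibble(
      gene_id = paste0("g", seq_len(40)), chrom = prom_src$chrom,
      tss = prom_src$start, strand = "+",
      start = prom_src$start, end = prom_src$end
    )
    ends <- random_intervals(300)
    ints <- tibble::tibble(
      id = paste0("i", 1:150), sample = "s1",
      chrom1 = ends$chrom[1:150], start1 = ends$start[1:150],
      end1 = ends$end[1:150],
      chrom2 = ends$chrom[151:300], start2 = ends$start[151:300],
      end2 = ends$end[151:300],
      bait_end = 1L
    )
    ann <- annotate_ends(ints, peaks, prom)
    brute_hit <- function(e, set) {
      any(vapply(seq_len(nrow(set)), function(j) {
        oracle_overlap(e, set[j, ])
      }, logical(1)))
    }
    for (i in c(1, 7, 40, 88, 150)) {
      e1 <- tibble::tibble(chrom = ints$chrom1[i], start = ints$start1[i],
                           end = ints$end1[i])
      expect_equal(ann$peak1[i], brute_hit(e1, peaks))
      genes_brute <- sort(prom$gene_id[vapply(seq_len(nrow(prom)), function(j) {
        oracle_overlap(e1, prom[j, c("chrom", "start", "end")])
      }, logical(1))])
      expect_equal(ann$genes1[[i]], genes_brute)
    }
    # full-vector check of the peak flags against the oracle
    all_peak1 <- vapply(seq_len(nrow(ints)), function(i) {
      brute_hit(tibble::tibble(chrom = ints$chrom1[i], start = ints$start1[i],
                               end = ints$end1[i]), peaks)
    }, logical(1))
    expect_equal(ann$peak1, all_peak1)
  })
})

test_that("pchic classification distinguishes EPI, PPI, activity classes, and needs bait tags", {
  prom <- make_promoter_windows(mini_annot())
  peaks <- genomic_intervals("chr1", c(4600, 24600, 12000), c(5400, 25400, 12800))
  ints <- tibble::tibble(
    id = paste0("i", 1:4), sample = "s1",
    chrom1 = "chr1", start1 = 4000, end1 = 6000,
    chrom2 = "chr1",
    start2 = c(12000, 24000, 15000, 24000),
    end2 = c(12800, 26000, 15800, 26000),
    bait_end = 1L
  )
  ann <- annotate_ends(ints, peaks, prom)
  cls <- classify_interactions(ann, mode = "pchic")
  expect_equal(cls$regulatory_class[1], "EPI") # active bait -> peak+ non-promoter
  expect_equal(cls$regulatory_class[2], "PPI") # active bait -> peak+ promoter gB
  expect_equal(cls$regulatory_class[3], "none") # peakless OE
  expect_equal(cls$activity_class[1:3], c("AP_AO", "AP_AO", "AP_IO"))
  expect_error(classify_interactions(dplyr::select(ann, -"bait_end"), "pchic"),
               "bait")
})

test_that("an OE that is both promoter and peaked is PPI by precedence, optionally dual", {
  prom <- make_promoter_windows(mini_annot())
  peaks <- genomic_intervals("chr1", c(4600, 24600), c(5400, 25400))
  ints <- tibble::tibble(
    id = "i1", sample = "s1",
    chrom1 = "chr1", start1 = 4000, end1 = 6000,
    chrom2 = "chr1", start2 = 24000, end2 = 26000,
    bait_end = 1L
  )
  ann <- annotate_ends(ints, peaks, prom)
  expect_equal(classify_interactions(ann, "pchic")$regulatory_class, "PPI")
  dual <- classify_interactions(ann, "pchic", ambiguous_oe = "both")
  expect_equal(dual$regulatory_class, "PPI")
  expect_true(dual$oe_also_enhancer)
})

test_that("hichip classification is symmetric in the two ends", {
  prom <- make_promoter_windows(mini_annot())
  peaks <- genomic_intervals("chr1", 1, 2) # irrelevant in hichip mode
  ends <- tibble::tibble(
    start = c(4000, 12000, 4000, 12000),
    end = c(6000, 12800, 6000, 12800),
    partner_start = c(24000, 15000, 12000, 4000),
    partner_end = c(26000, 15800, 12800, 6000)
  )
  ints <- tibble::tibble(
    id = paste0("i", 1:4), sample = "h1",
    chrom1 = "chr1", start1 = ends$start, end1 = ends$end,
    chrom2 = "chr1", start2 = ends$partner_start, end2 = ends$partner_end
  )
  cls <- classify_interactions(annotate_ends(ints, peaks, prom), "hichip")
  expect_equal(cls$regulatory_class, c("PPI", "EEI", "EPI", "EPI"))
  # end-swap invariance
  swapped <- ints
  swapped[, c("start1", "end1", "start2", "end2")] <-
    ints[, c("start2", "end2", "start1", "end1")]
  cls_sw <- classify_interactions(annotate_ends(swapped, peaks, prom), "hichip")
  expect_equal(cls_sw$regulatory_class, cls$regulatory_class)
  expect_false("activity_class" %in% names(cls))
})

test_that("worked example promoter classes match the hand-checked table", {
  wx <- worked_example()
  ints <- annotate_ends(
    dplyr::filter(wx$interactions, sample == "s1"),
    dplyr::filter(wx$peaks, sample == "s1"), wx$promoters
  )
  ints <- classify_interactions(ints, "pchic")
  got <- classify_promoters(
    ints, wx$promoters, wx$expression,
    dplyr::filter(wx$peaks, sample == "s1")
  )
  expect_equal(nrow(got), 5) # g6 inactive
  merged <- dplyr::inner_join(got, wx$expected, by = "gene_id",
                              suffix = c("", "_want"))
  expect_equal(merged$promoter_class, merged$promoter_class_want)
  expect_equal(merged$n_epi, merged$n_epi_want)
  expect_equal(merged$n_ppi, merged$n_ppi_want)
  expect_equal(merged$has_any_interaction, merged$has_any_interaction_want)
})

test_that("promoter class labels always partition the active gene set", {
  st <- generate_synthetic_study(synthetic_config(seed = 7, n_genes = 120))
  pk <- dplyr::filter(st$peaks, sample == "chip_1", condition == "dmso")
  ints <- classify_interactions(
    annotate_ends(dplyr::filter(st$interactions, condition == "dmso",
                                sample == "ph_1"), pk, st$promoters),
    "pchic"
  )
  gc <- classify_promoters(ints, st$promoters, st$expression, pk,
                           expression_samples = paste0("dmso_", 1:3))
  expect_equal(sum(table(gc$promoter_class)), nrow(gc))
  expect_setequal(unique(gc$promoter_class),
                  intersect(c("EPI_ONLY", "PPI_ONLY", "EPI_AND_PPI",
                              "NO_ACTIVE_OE"), gc$promoter_class))
  truth_active <- st$truth$genes$gene_id[st$truth$genes$active]
  expect_setequal(gc$gene_id, truth_active)
})

test_that("per-10M normalization follows the score convention and its sum identity", {
  x <- tibble::tibble(raw_count = c(5, 0, 12))
  out <- normalize_per_10M(x, library_size = 5e6)
  expect_equal(out$score, c(10, 0, 24))
  withr::with_seed(32, {
    counts <- rpois(50, 30)
    lib <- 8.5e6
    scores <- normalize_per_10M(tibble::tibble(raw_count = counts), lib)$score
    expect_equal(sum(scores), 1e7 * sum(counts) / lib)
  })
  expect_error(normalize_per_10M(x, library_size = 0), "positive")
  expect_error(normalize_per_10M(tibble::tibble(a = 1)), "raw_count")
})

test_that("deduplication keeps one record per sample and canonical id, max count wins", {
  base <- tibble::tibble(
    sample = "s1",
    chrom1 = "chr1", start1 = 100, end1 = 200,
    chrom2 = "chr1", start2 = 500, end2 = 600,
    raw_count = 5
  )
  swapped <- tibble::tibble(
    sample = "s1",
    chrom1 = "chr1", start1 = 500, end1 = 600,
    chrom2 = "chr1", start2 = 100, end2 = 200,
    raw_count = 9
  )
  other <- tibble::tibble(
    sample = "s1",
    chrom1 = "chr1", start1 = 100, end1 = 200,
    chrom2 = "chr1", start2 = 900, end2 = 990,
    raw_count = 2
  )
  x <- dplyr::bind_rows(base, base, swapped, other)
  x$id <- canonical_interaction_id(x$chrom1, x$start1, x$end1,
                                   x$chrom2, x$start2, x$end2)
  out <- deduplicate_interactions(x)
  expect_equal(nrow(out), 2)
  expect_equal(out$raw_count[out$id == x$id[1]], 9) # max count among dups
})

test_that("promoter-class recovery degrades monotonically with peak jitter", {
  recovery_at <- function(jit) {
    st <- generate_synthetic_study(
      synthetic_config(seed = 33, n_genes = 120, jitter_sd = jit)
    )
    pk <- dplyr::filter(st$peaks, sample == "chip_1", condition == "dmso")
    ints <- classify_interactions(
      annotate_ends(dplyr::filter(st$interactions, condition == "dmso",
                                  sample == "ph_1"), pk, st$promoters),
      "pchic"
    )
    gc <- classify_promoters(ints, st$promoters, st$expression, pk,
                             expression_samples = paste0("dmso_", 1:3))
    cmp <- dplyr::inner_join(gc, st$truth$genes, by = "gene_id")
    mean(cmp$promoter_class == cmp$planted_class)
  }
  r <- vapply(c(0, 400, 1500), recovery_at, numeric(1))
  expect_equal(r[1], 1)
  expect_true(r[1] >= r[2] && r[2] >= r[3])
  expect_lt(r[3], 1)
})

test_that("EPI genes are higher expressed than genes without active other ends", {
  st <- generate_synthetic_study(synthetic_config(seed = 34))
  pk <- dplyr::filter(st$peaks, sample == "chip_1", condition == "dmso")
  ints <- classify_interactions(
    annotate_ends(dplyr::filter(st$interactions, condition == "dmso",
                                sample == "ph_1"), pk, st$promoters),
    "pchic"
  )
  gc <- classify_promoters(ints, st$promoters, st$expression, pk,
                           expression_samples = paste0("dmso_", 1:3))
  epi <- gc$mean_expression[gc$promoter_class %in% c("EPI_ONLY", "EPI_AND_PPI")]
  no_oe <- gc$mean_expression[gc$promoter_class == "NO_ACTIVE_OE"]
  expect_gt(mean(epi), mean(no_oe))
})
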