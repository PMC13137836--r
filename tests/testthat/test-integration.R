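test_that("enrichment reports cross-product odds ratio and Fisher p", {
  a <- paste0("a", 1:10)
  b <- paste0("b", 1:10)
  res <- set_enrichment(a, b, positive = c(a[1:8], b[1]))
  expect_equal(res$fraction_a, 0.8)
  expect_equal(res$fraction_b, 0.1)
  expect_equal(res$odds_ratio, (8 * 9) / (2 * 1)) # 36
  expect_equal(res$p_value, oracle_fisher_p(res$counts), tolerance = 1e-12)
  # identical composition
  same <- set_enrichment(a, b, positive = c(a[1:5], b[1:5]))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  expect_error(set_enrichment(character(), b, positive = b), "set_a")
  # Haldane correction keeps the OR finite with a zero cell
  zero <- set_enrichment(a, b, positive = a)
  expect_true(is.finite(zero$odds_ratio))
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  withr::with_seed(61, {
    for (k in 1:40) {
      n1 <- sample(2:40, 1)
      n2 <- sample(2:40, 1)
      a <- paste0("a", seq_len(n1))
      b <- paste0("b", seq_len(n2))
      pos <- c(sample(a, sample.int(n1, 1)), sample(b, sample.int(n2, 1)))
      res <- set_enrichment(a, b, positive = pos)
      expect_equal(res$p_value, oracle_fisher_p(res$counts), tolerance = 1e-9)
    }
  })
})

test_that("epi_enrichment recovers planted sensitivity fractions", {
  st <- generate_synthetic_study(synthetic_config(seed = 62))
  truth <- dplyr::filter(st$truth$genes, .data$active)
  epi_pos <- truth$gene_id[truth$planted_class %in% c("EPI_ONLY", "EPI_AND_PPI")]
  epi_neg <- setdiff(truth$gene_id, epi_pos)
  down <- call_degs(st$deg$drug)$down
  res <- set_enrichment(epi_pos, epi_neg, positive = down)
  expect_gt(res$fraction_a, 0.55)
  expect_lt(res$fraction_b, 0.35)
  expect_lt(res$p_value, 1e-4)
})

test_that("expression contrasts handle Welch, degenerate, and paired cases", {
  sets <- list(hi = paste0("h", 1:50), lo = paste0("l", 1:50))
  withr::with_seed(63, {
    vals <- setNames(c(rnorm(50, 1), rnorm(50, 0)), c(sets$hi, sets$lo))
    out <- expression_contrast(sets, vals)
    expect_lt(out$p_value, 0.05) # power > 0.99 at delta 1, sd 1, n 50
    expect_gt(out$mean_difference, 0)
  })
  const <- setNames(rep(2, 8), c(paste0("h", 1:4), paste0("l", 1:4)))
  out0 <- expression_contrast(list(hi = paste0("h", 1:4), lo = paste0("l", 1:4)),
                              const)
  expect_equal(out0$p_value, 1)
  expect_true(out0$degenerate)
  # paired mode on (x, x + c) recovers the constant shift exactly
  x <- c(4, 7, 9, 12)
  expr <- setNames(c(x, x + 3), c(paste0("g", 1:4, "_a"), paste0("g", 1:4, "_b")))
  outp <- expression_contrast(
    list(after = paste0("g", 1:4, "_b"), before = paste0("g", 1:4, "_a")),
    expr, paired = TRUE
  )
  expect_equal(outp$mean_difference, 3)
  expect_true(outp$degenerate) # constant shift has zero paired variance
})

test_that("per-gene EPI score aggregates and condition deltas are bookkept exactly", {
  ints <- tibble::tibble(
    id = paste0("i", 1:3), sample = "s1",
    regulatory_class = c("EPI", "EPI", "PPI"),
    score = c(5, 7, 9),
    bait_end = 1L,
    genes1 = list("gA", "gA", "gB"),
    genes2 = list(character(), character(), "gC")
  )
  sc <- gene_epi_scores(ints)
  expect_equal(sc$epi_score_mean[sc$gene_id == "gA"], 6)
  expect_equal(sc$n_epi[sc$gene_id == "gA"], 2L)
  expect_false("gB" %in% sc$gene_id) # PPI only -> absent
  # removing one of two EPIs lowers the mean and the count deterministically
  after <- gene_epi_scores(ints[-2, ])
  d <- epi_score_delta(sc, after)
  expect_equal(d$delta_n[d$gene_id == "gA"], -1L)
  expect_equal(d$delta_mean[d$gene_id == "gA"], 5 - 6)
})

test_that("HiChIP per-gene log2FC uses pseudocounts and is antisymmetric", {
  loops <- tibble::tibble(
    gene_id = rep(c("gA", "gB"), each = 4),
    sample = rep(c("a1", "a2", "b1", "b2"), 2),
    n_loops = c(4, 4, 1, 1, 2, 2, 2, 2)
  )
  out <- hichip_gene_log2fc(loops, c("a1", "a2"), c("b1", "b2"), pseudocount = 0)
  expect_equal(out$loop_log2fc[out$gene_id == "gA"], 2) # log2(4/1)
  expect_equal(out$loop_log2fc[out$gene_id == "gB"], 0)
  swapped <- hichip_gene_log2fc(loops, c("b1", "b2"), c("a1", "a2"),
                                pseudocount = 0)
  expect_equal(swapped$loop_log2fc, -out$loop_log2fc)
  # default pseudocount 0.5
  outp <- hichip_gene_log2fc(loops, c("a1", "a2"), c("b1", "b2"))
  expect_equal(outp$loop_log2fc[outp$gene_id == "gA"], log2(4.5 / 1.5))
})

test_that("loop-expression concordance is Spearman with midrank ties and a floor on n", {
  mono <- tibble::tibble(gene_id = paste0("g", 1:12),
                         loop_log2fc = 1:12)
  expr <- tibble::tibble(gene_id = paste0("g", 1:12), log2fc = (1:12)^3)
  expect_equal(interaction_expression_concordance(mono, expr)$rho, 1)
  expect_error(
    interaction_expression_concordance(mono[1:5, ], expr),
    ">= 10"
  )
  withr::with_seed(64, {
    tied <- tibble::tibble(
      gene_id = paste0("g", 1:30),
      loop_log2fc = sample(rep(1:5, 6))
    )
    texpr <- tibble::tibble(gene_id = paste0("g", 1:30),
                            log2fc = sample(rep(1:3, 10)))
    got <- interaction_expression_concordance(tied, texpr)$rho
    midrank_rho <- stats::cor(rank(tied$loop_log2fc), rank(texpr$log2fc))
    expect_equal(got, midrank_rho, tolerance = 1e-12)
  })
})

test_that("TF-dependency overlaps report per-TF and union fractions", {
  pon <- genomic_intervals("chr1", c(0, 1000, 2000, 3000), c(100, 1100, 2100, 3100))
  tfs <- list(
    tf1 = genomic_intervals("chr1", 50, 60),
    tf2 = genomic_intervals("chr1", c(1050, 2050), c(1060, 2060)),
    tf3 = genomic_intervals("chr2", 0, 5000)
  )
  out <- peak_dependency_overlap(pon, tfs)
  expect_equal(out$fraction[out$tf == "tf1"], 0.25)
  expect_equal(out$fraction[out$tf == "tf2"], 0.5)
  expect_equal(out$fraction[out$tf == "tf3"], 0) # disjoint chromosome
  union_frac <- out$fraction[out$tf == "union"]
  expect_equal(union_frac, 0.75)
  expect_true(all(union_frac >= out$fraction[out$tf != "union"]))
  expect_error(peak_dependency_overlap(pon[0, ], tfs), "empty")
})

test_that("drug treatment pulls sensitive-gene expression toward insensitive levels", {
  st <- generate_synthetic_study(synthetic_config(seed = 65))
  truth <- dplyr::filter(st$truth$genes, .data$active)
  dmso_mean <- rowMeans(st$expression[, paste0("dmso_", 1:3)])
  tki_mean <- rowMeans(st$expression[, paste0("tki_", 1:3)])
  sens <- st$expression$gene_id %in% truth$gene_id[truth$sensitive]
  insens <- st$expression$gene_id %in% truth$gene_id[!truth$sensitive]
  # sensitive genes start above the insensitive baseline (EPI-boost enrichment),
  # and treatment brings them down to or below it
  expect_gt(mean(log2(dmso_mean[sens])), mean(log2(tki_mean[sens])))
  expect_gt(mean(log2(dmso_mean[sens])), mean(log2(dmso_mean[insens])))
  expect_lt(mean(log2(tki_mean[sens])), mean(log2(dmso_mean[insens])))
})
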