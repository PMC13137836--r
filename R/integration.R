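#' Two-set enrichment of a gene property (2x2 Fisher test)
#'
#' Compares the fraction of predicate-positive genes between two gene sets —
#' e.g. the fraction of genes with EPIs among drug-sensitive vs insensitive
#' genes, or the fraction of drug-sensitive genes among EPI+ vs EPI- genes.
#' The p-value is the two-sided Fisher exact test; the odds ratio is the
#' sample (cross-product) odds ratio, with a Haldane 0.5 correction applied
#' to every cell when any cell is zero.
#'
#' @param set_a,set_b Character vectors of gene ids (overlap allowed).
#' @param positive Predicate: either a character vector of positive genes or
#'   a function `gene_id -> logical`, total on the union of the sets.
#' @param labels Length-2 labels for the sets (used in tidies and plots).
#' @return Object of class `epi_enrichment` with the 2x2 counts, per-set
#'   fractions, odds ratio and p-value; see [tidy.epi_enrichment()].
#' @examples
#' set_enrichment(paste0("g", 1:10), paste0("h", 1:10),
#'   positive = c(paste0("g", 1:8), "h1")
#' )
#' @export
set_enrichment <- function(set_a, set_b, positive, labels = c("a", "b")) {
  if (length(set_a) == 0) abort("gene set `set_a` is empty.")
  if (length(set_b) == 0) abort("gene set `set_b` is empty.")
  pred <- if (is.function(positive)) {
    positive
  } else {
    function(g) g %in% positive
  }
  pa <- pred(set_a)
  pb <- pred(set_b)
  if (anyNA(pa) || anyNA(pb)) abort("predicate must be total on both sets.")
  counts <- matrix(
    c(sum(pa), sum(!pa), sum(pb), sum(!pb)),
    nrow = 2, byrow = TRUE,
    dimnames = list(set = labels, status = c("positive", "negative"))
  )
  cc <- counts
  if (any(cc == 0)) cc <- cc + 0.5 # Haldane correction
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  p <- fisher.test(counts, alternative = "two.sided")$p.value
  structure(
    list(
      counts = counts,
      fraction_a = sum(pa) / length(pa),
      fraction_b = sum(pb) / length(pb),
      odds_ratio = unname(or),
      p_value = p,
      labels = labels
    ),
    class = "epi_enrichment"
  )
}

#' @rdname set_enrichment
#' @param gene_stats Gene table with `gene_id` and `promoter_class`.
#' @param epi_classes Promoter classes counted as EPI-positive.
#' @export
epi_enrichment <- function(set_a, set_b, gene_stats,
                           epi_classes = c("EPI_ONLY", "EPI_AND_PPI"),
                           labels = c("a", "b")) {
  stopifnot(all(c("gene_id", "promoter_class") %in% names(gene_stats)))
  epi_pos <- gene_stats$gene_id[gene_stats$promoter_class %in% epi_classes]
  set_enrichment(set_a, set_b, positive = epi_pos, labels = labels)
}

#' @export
print.epi_enrichment <- function(x, ...) {
  cat(sprintf(
    "Enrichment: %s %.1f%% vs %s %.1f%% positive; OR %.2f, p = %.3g\n",
    x$labels[1], 100 * x$fraction_a, x$labels[2], 100 * x$fraction_b,
    x$odds_ratio, x$p_value
  ))
  invisible(x)
}

#' @describeIn set_enrichment 2x2 table in long form.
#' @param x An `epi_enrichment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.epi_enrichment <- function(x, ...) {
  tibble(
    set = rep(x$labels, each = 2),
    status = rep(c("positive", "negative"), 2),
    n = as.vector(t(x$counts))
  )
}

#' @describeIn set_enrichment One-row summary with fractions, OR and p.
#' @exportS3Method generics::glance
glance.epi_enrichment <- function(x, ...) {
  tibble(
    fraction_a = x$fraction_a, fraction_b = x$fraction_b,
    odds_ratio = x$odds_ratio, p_value = x$p_value
  )
}

#' Expression contrasts between gene sets
#'
#' Welch two-sample t-tests (unpaired, default) on per-gene expression
#' values between every pair of gene sets, or a paired t-test for matched
#' before/after values of the same genes (`paired = TRUE`). Degenerate
#' (zero-variance) comparisons report `p = 1` with `degenerate = TRUE`
#' rather than erroring.
#'
#' @param gene_sets Named list of character gene-id vectors.
#' @param expression Named numeric vector of per-gene expression values, or
#'   tibble with `gene_id` and a `value` column.
#' @param paired Paired mode: sets must then be equal-length aligned vectors
#'   of the same genes measured under two conditions, and `expression` a
#'   tibble with `gene_id`, `condition`, `value`.
#' @return Tibble with one row per set pair: means, mean difference, t
#'   p-value, `degenerate` flag.
#' @export
expression_contrast <- function(gene_sets, expression, paired = FALSE) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2, !is.null(names(gene_sets)))
  lookup <- if (is.data.frame(expression)) {
    setNames(expression$value, expression$gene_id)
  } else {
    expression
  }
  vals <- lapply(gene_sets, function(g) unname(lookup[g]))
  lapply(names(gene_sets), function(nm) {
    if (length(vals[[nm]]) < 2) abort(sprintf("gene set '%s' has < 2 genes.", nm))
    if (anyNA(vals[[nm]])) abort(sprintf("missing expression for genes in '%s'.", nm))
  })
  pairs <- utils::combn(names(gene_sets), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- vals[[pr[1]]]
    y <- vals[[pr[2]]]
    degenerate <- (sd(x) == 0 && sd(y) == 0) ||
      (paired && sd(x - y) == 0)
    p <- if (degenerate) {
      1
    } else {
      tryCatch(
        t.test(x, y, paired = paired, var.equal = FALSE)$p.value,
        error = function(e) 1
      )
    }
    tibble(
      set_a = pr[1], set_b = pr[2],
      mean_a = mean(x), mean_b = mean(y),
      mean_difference = mean(x) - mean(y),
      p_value = p,
      degenerate = degenerate
    )
  })
}

#' Aggregate EPI scores per gene
#'
#' For each gene, the mean (plus sum and count) of the interaction scores of
#' its EPIs — interactions classified `EPI` whose bait maps to the gene's
#' promoter. Genes without EPIs are absent from the result.
#'
#' @param interactions Classified pchic-mode interaction tibble (annotated,
#'   with `score`).
#' @return Tibble `gene_id`, `epi_score_mean`, `epi_score_sum`, `n_epi`.
#' @export
gene_epi_scores <- function(interactions) {
  stopifnot(all(c("regulatory_class", "score", "bait_end") %in% names(interactions)))
  epis <- filter(interactions, .data$regulatory_class == "EPI")
  if (nrow(epis) == 0) {
    return(tibble(
      gene_id = character(), epi_score_mean = numeric(),
      epi_score_sum = numeric(), n_epi = integer()
    ))
  }
  swap <- epis$bait_end == 2L
  bait_genes <- epis$genes1
  bait_genes[swap] <- epis$genes2[swap]
  tibble(
    gene_id = unlist(bait_genes),
    score = rep(epis$score, lengths(bait_genes))
  ) %>%
    group_by(.data$gene_id) %>%
    summarise(
      epi_score_mean = mean(.data$score),
      epi_score_sum = sum(.data$score),
      n_epi = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-gene change in EPI score between conditions
#'
#' Deltas (`b - a`) of the per-gene EPI aggregates, computed on the
#' intersection of genes present in both conditions.
#'
#' @param scores_a,scores_b Tibbles from [gene_epi_scores()].
#' @return Tibble with per-gene deltas of mean, sum and count.
#' @export
epi_score_delta <- function(scores_a, scores_b) {
  inner_join(scores_a, scores_b, by = "gene_id", suffix = c("_a", "_b")) %>%
    mutate(
      delta_mean = .data$epi_score_mean_b - .data$epi_score_mean_a,
      delta_sum = .data$epi_score_sum_b - .data$epi_score_sum_a,
      delta_n = .data$n_epi_b - .data$n_epi_a
    )
}

#' Count chromatin loops per gene
#'
#' A loop is assigned to a gene when either end overlaps the gene's promoter
#' window; counted per sample.
#'
#' @param interactions Annotated interaction tibble ([annotate_ends()]).
#' @return Tibble `gene_id`, `sample`, `n_loops`.
#' @export
count_gene_loops <- function(interactions) {
  stopifnot(all(c("genes1", "genes2") %in% names(interactions)))
  both <- purrr::map2(interactions$genes1, interactions$genes2,
                      function(a, b) unique(c(a, b)))
  tibble(
    gene_id = unlist(both),
    sample = rep(interactions$sample, lengths(both))
  ) %>%
    count(.data$gene_id, .data$sample, name = "n_loops")
}

#' Per-gene log2 fold change of mean loop counts between groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` of per-sample
#' loop counts averaged within each group; genes absent from a sample count
#' as 0 loops there.
#'
#' @param gene_loops Tibble `gene_id`, `sample`, `n_loops`
#'   (from [count_gene_loops()]).
#' @param group_a,group_b Character vectors of sample labels.
#' @param pseudocount Added to both means (default 0.5).
#' @return Tibble `gene_id`, `mean_a`, `mean_b`, `loop_log2fc`.
#' @export
hichip_gene_log2fc <- function(gene_loops, group_a, group_b, pseudocount = 0.5) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  stopifnot(all(c("gene_id", "sample", "n_loops") %in% names(gene_loops)))
  mean_over <- function(samples) {
    gene_loops %>%
      filter(.data$sample %in% samples) %>%
      group_by(.data$gene_id) %>%
      summarise(m = sum(.data$n_loops) / length(samples), .groups = "drop")
  }
  a <- rename(mean_over(group_a), mean_a = "m")
  b <- rename(mean_over(group_b), mean_b = "m")
  dplyr::full_join(a, b, by = "gene_id") %>%
    mutate(
      mean_a = dplyr::coalesce(.data$mean_a, 0),
      mean_b = dplyr::coalesce(.data$mean_b, 0),
      loop_log2fc = log2((.data$mean_a + pseudocount) /
                           (.data$mean_b + pseudocount))
    )
}

#' Rank concordance of loop changes with expression changes
#'
#' Spearman correlation between per-gene loop log2 fold changes and
#' expression log2 fold changes on the genes shared by both tables (>= 10
#' required). The exact p-value is used where `cor.test` provides it
#' (n < 1290, no ties), the t-approximation otherwise.
#'
#' @param loop_lfc Tibble `gene_id`, `loop_log2fc`.
#' @param expr_lfc Tibble `gene_id`, `log2fc`.
#' @return Tibble with `rho`, `p_value`, `n_genes`.
#' @export
interaction_expression_concordance <- function(loop_lfc, expr_lfc) {
  shared <- inner_join(
    select(loop_lfc, "gene_id", "loop_log2fc"),
    select(expr_lfc, "gene_id", "log2fc"),
    by = "gene_id"
  )
  if (nrow(shared) < 10) {
    abort(sprintf("only %d genes shared between tables; >= 10 required.", nrow(shared)))
  }
  ct <- suppressWarnings(
    cor.test(shared$loop_log2fc, shared$log2fc, method = "spearman")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_genes = nrow(shared))
}

#' Overlap of differential regions with TF-dependent regions
#'
#' For each transcription-factor-dependent region set, the fraction of the
#' query regions (e.g. Ponatinib-downregulated H3K27ac peaks) with at least
#' 1 bp overlap; the union fraction across all TF sets is reported as row
#' `"union"`.
#'
#' @param query_regions Interval tibble (non-empty).
#' @param tf_sets Named list of interval tibbles.
#' @return Tibble `tf`, `n_overlap`, `fraction`.
#' @export
peak_dependency_overlap <- function(query_regions, tf_sets) {
  validate_intervals(query_regions, "query_regions")
  if (nrow(query_regions) == 0) abort("query region set is empty.")
  stopifnot(is.list(tf_sets), !is.null(names(tf_sets)))
  q <- as_granges(query_regions)
  hits <- lapply(tf_sets, function(s) overlaps_any(q, as_granges(s)))
  per_tf <- purrr::imap_dfr(hits, function(h, nm) {
    tibble(tf = nm, n_overlap = sum(h), fraction = mean(h))
  })
  any_hit <- Reduce(`|`, hits)
  bind_rows(per_tf, tibble(
    tf = "union", n_overlap = sum(any_hit), fraction = mean(any_hit)
  ))
}
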