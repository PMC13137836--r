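#' Miniature hand-checkable study
#'
#' A fixed six-gene toy study small enough to verify every classification
#' and score by hand; the same tables are shipped as plain-text fixtures
#' under `inst/extdata/worked_example/`. Genes g1-g5 are active (normalized
#' count >= 10 and a promoter H3K27ac peak); g6 is inactive. The planted
#' repertoire is: g1 one EPI and one PPI (`EPI_AND_PPI`), g2 one EPI
#' (`EPI_ONLY`), g3 one PPI (`PPI_ONLY`), g4 one contact to a peakless
#' other end and g5 no contacts (both `NO_ACTIVE_OE`, distinguished by
#' `has_any_interaction`). The HiChIP sample has one EPI loop with raw
#' count 5 at library size 5e6 (score 10), and the viability plate's single
#' combination cell is the Bliss textbook case (yA = 0.5, yB = 0.4,
#' observed inhibition 0.9, excess +20).
#'
#' @return A list of tibbles: `annotation`, `promoters`, `peaks`,
#'   `interactions`, `expression`, `deg`, `hichip`, `viability`, and the
#'   `expected` per-gene classification table.
#' @export
worked_example <- function() {
  offset <- (0:5) * 20000
  gene_id <- paste0("g", 1:6)
  annotation <- tibble(
    chrom = "chr1",
    txStart = offset + 5000,
    txEnd = offset + 7000,
    strand = "+",
    gene_id = gene_id
  )
  promoters <- make_promoter_windows(annotation, flank = 1000)
  tss <- offset + 5000

  active <- 1:5
  epi_genes <- 1:2
  peaks_one <- bind_rows(
    tibble(chrom = "chr1", start = tss[active] - 400, end = tss[active] + 400),
    tibble(
      chrom = "chr1", start = offset[epi_genes] + 12000,
      end = offset[epi_genes] + 12800
    )
  )
  peaks <- purrr::map_dfr(paste0("s", 1:3), function(s) {
    mutate(peaks_one, sample = s, condition = "dmso")
  })

  win <- function(i) c(offset[i] + 4000, offset[i] + 6000)
  enh <- function(i) c(offset[i] + 12000, offset[i] + 12800)
  rows <- list(
    list(gene = "g1", kind = "epi", e1 = win(1), e2 = enh(1), score = 6),
    list(gene = "g1", kind = "ppi", e1 = win(1), e2 = win(2), score = 8),
    list(gene = "g2", kind = "epi", e1 = win(2), e2 = enh(2), score = 5.2),
    list(gene = "g3", kind = "ppi", e1 = win(3), e2 = win(1), score = 7),
    list(
      gene = "g4", kind = "dead",
      e1 = win(4), e2 = c(offset[4] + 15000, offset[4] + 15800), score = 6
    )
  )
  base_int <- purrr::map_dfr(rows, function(r) {
    tibble(
      chrom1 = "chr1", start1 = r$e1[1], end1 = r$e1[2],
      chrom2 = "chr1", start2 = r$e2[1], end2 = r$e2[2],
      gene = r$gene, kind = r$kind, score = r$score
    )
  })
  base_int$id <- canonical_interaction_id(
    base_int$chrom1, base_int$start1, base_int$end1,
    base_int$chrom2, base_int$start2, base_int$end2
  )
  interactions <- purrr::map_dfr(paste0("s", 1:3), function(s) {
    mutate(base_int, sample = s, raw_count = NA_real_, bait_end = 1L)
  })

  expression <- tibble(
    gene_id = gene_id,
    dmso_1 = c(50, 64, 20, 30, 12, 2),
    dmso_2 = c(52, 60, 22, 28, 14, 2)
  )
  deg <- tibble(
    gene_id = paste0("g", 1:5),
    log2fc = c(1.5, -2, 0.5, -1.5, 0),
    padj = c(0.01, 0.01, 0.001, 0.2, 0.9)
  )

  hichip <- tibble(
    sample = "h1",
    chrom1 = "chr1",
    start1 = c(win(1)[1], win(1)[1], enh(1)[1]),
    end1 = c(win(1)[2], win(1)[2], enh(1)[2]),
    chrom2 = "chr1",
    start2 = c(enh(1)[1], win(2)[1], enh(2)[1]),
    end2 = c(enh(1)[2], win(2)[2], enh(2)[2]),
    raw_count = c(5, 3, 2),
    library_size = 5e6
  )
  hichip$id <- canonical_interaction_id(
    hichip$chrom1, hichip$start1, hichip$end1,
    hichip$chrom2, hichip$start2, hichip$end2
  )

  viability <- tidyr::expand_grid(
    experiment = "exp_1", dose_a = c(0, 1), dose_b = c(0, 1)
  ) %>%
    mutate(signal = c(1, 0.6, 0.5, 0.1)[match(
      paste(.data$dose_a, .data$dose_b), c("0 0", "0 1", "1 0", "1 1")
    )] * 1000)

  expected <- tibble(
    gene_id = paste0("g", 1:5),
    promoter_class = c(
      "EPI_AND_PPI", "EPI_ONLY", "PPI_ONLY", "NO_ACTIVE_OE", "NO_ACTIVE_OE"
    ),
    n_epi = c(1L, 1L, 0L, 0L, 0L),
    n_ppi = c(1L, 0L, 1L, 0L, 0L),
    has_any_interaction = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )

  list(
    annotation = annotation, promoters = promoters, peaks = peaks,
    interactions = interactions, expression = expression, deg = deg,
    hichip = hichip, viability = viability, expected = expected
  )
}
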