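test_that("promoter windows follow the slop convention, clip at 0, and place the minus-strand TSS", {
  ann <- tibble::tibble(
    chrom = "chr1",
    txStart = c(5000, 500, 2000),
    txEnd = c(8000, 900, 3000),
    strand = c("+", "+", "-"),
    gene_id = c("gA", "gB", "gC")
  )
  win <- make_promoter_windows(ann, flank = 1000)
  expect_equal(win$start, c(4000, 0, 1999))
  expect_equal(win$end, c(6000, 1500, 3999))
  expect_equal(win$tss, c(5000, 500, 2999))
  # gC by per-base arithmetic: tss is the last transcribed base, 2999
  expect_true(win$tss[3] >= win$start[3] && win$tss[3] < win$end[3])
  # default flank is 1 kb: full windows span 2 kb
  expect_equal(make_promoter_windows(ann[1, ])$end -
                 make_promoter_windows(ann[1, ])$start, 2000)
})

test_that("promoter construction rejects bad records by identity and collapses duplicates", {
  bad_strand <- tibble::tibble(
    chrom = "chr1", txStart = 10, txEnd = 20, strand = "*", gene_id = "gX"
  )
  expect_error(make_promoter_windows(bad_strand), "gX")
  bad_coord <- tibble::tibble(
    chrom = "chr1", txStart = 30, txEnd = 20, strand = "+", gene_id = "gY"
  )
  expect_error(make_promoter_windows(bad_coord), "gY")
  dup <- tibble::tibble(
    chrom = "chr1", txStart = c(5000, 5000), txEnd = c(8000, 9000),
    strand = "+", gene_id = "gA"
  )
  expect_equal(nrow(make_promoter_windows(dup)), 1)
})

test_that("promoter windows are idempotent when rebuilt from their own TSSs", {
  ann <- tibble::tibble(
    chrom = "chr1", txStart = c(5000, 12000), txEnd = c(8000, 15000),
    strand = c("+", "-"), gene_id = c("gA", "gB")
  )
  win1 <- make_promoter_windows(ann)
  ann2 <- tibble::tibble(
    chrom = win1$chrom, txStart = win1$tss, txEnd = win1$tss + 1,
    strand = "+", gene_id = win1$gene_id
  )
  win2 <- make_promoter_windows(ann2)
  expect_equal(win2[, c("chrom", "start", "end", "tss")],
               win1[, c("chrom", "start", "end", "tss")])
})

test_that("overlap is half-open, symmetric, and matches the arithmetic form", {
  a <- genomic_intervals("chr1", 100, 200)
  expect_true(interval_overlaps(a, genomic_intervals("chr1", 199, 300)))
  expect_false(interval_overlaps(a, genomic_intervals("chr1", 200, 300)))
  expect_false(interval_overlaps(a, genomic_intervals("chr2", 100, 200)))
  withr::with_seed(11, {
    x <- random_intervals(300)
    y <- random_intervals(300)
    got <- interval_overlaps(x, y)
    expect_equal(got, interval_overlaps(y, x))
    arith <- x$chrom == y$chrom & pmax(x$start, y$start) < pmin(x$end, y$end)
    expect_equal(got, arith)
  })
})

test_that("merge_within_gap bridges gaps up to the bound and leaves larger gaps", {
  close_pair <- genomic_intervals("chr1", c(0, 600), c(100, 700))
  expect_equal(merge_within_gap(close_pair, gap = 1000),
               tibble::tibble(chrom = "chr1", start = 0, end = 700))
  far_pair <- genomic_intervals("chr1", c(0, 1500), c(100, 1600))
  merged <- merge_within_gap(far_pair, gap = 1000)
  expect_equal(nrow(merged), 2)
  # boundary: gap exactly 1000 merges, 1001 does not
  expect_equal(nrow(merge_within_gap(
    genomic_intervals("chr1", c(0, 1100), c(100, 1200)), 1000
  )), 1)
  expect_equal(nrow(merge_within_gap(
    genomic_intervals("chr1", c(0, 1101), c(100, 1201)), 1000
  )), 2)
})

test_that("merged output is separated by more than the gap and equals the dilated-union oracle", {
  withr::with_seed(12, {
    for (gap in c(0, 10, 100)) {
      x <- random_intervals(120)
      got <- merge_within_gap(x, gap = gap)
      expect_equal(got[, c("chrom", "start", "end")], oracle_merge(x, gap))
      by_chrom <- split(got, got$chrom)
      for (g in by_chrom) {
        if (nrow(g) > 1) {
          expect_true(all(g$start[-1] - g$end[-nrow(g)] > gap))
        }
      }
    }
  })
})

test_that("consensus regions are the bp-level intersection across samples", {
  same <- genomic_intervals("chr1", 100, 200)
  expect_equal(
    consensus_regions(list(same, same, same)),
    tibble::tibble(chrom = "chr1", start = 100, end = 200)
  )
  stag <- list(
    genomic_intervals("chr1", 0, 300),
    genomic_intervals("chr1", 100, 400),
    genomic_intervals("chr1", 200, 500)
  )
  expect_equal(consensus_regions(stag),
               tibble::tibble(chrom = "chr1", start = 200, end = 300))
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  expect_equal(nrow(consensus_regions(list(same, empty))), 0)
  expect_error(consensus_regions(list(same)), "at least 2")
})

test_that("consensus output is a bp-subset of every sample and matches the coverage oracle", {
  withr::with_seed(13, {
    per_sample <- lapply(1:3, function(i) random_intervals(60))
    got <- consensus_regions(per_sample)
    expect_equal(got, oracle_consensus(per_sample))
    got_pos <- oracle_positions(got)
    for (s in per_sample) {
      s_pos <- oracle_positions(s)
      for (ch in names(got_pos)) {
        expect_true(all(got_pos[[ch]] %in% s_pos[[ch]]))
      }
    }
  })
})

test_that("presence/absence differential is overlap-based set difference", {
  ref <- genomic_intervals("chr1", c(0, 500), c(100, 600))
  trt <- genomic_intervals("chr1", 0, 100)
  d <- presence_absence_differential(ref, trt)
  expect_equal(d$lost[, c("start", "end")], tibble::tibble(start = 500, end = 600))
  expect_equal(nrow(d$gained), 0)
  disj <- presence_absence_differential(
    genomic_intervals("chr1", 0, 100), genomic_intervals("chr2", 0, 100)
  )
  expect_equal(nrow(disj$lost), 1)
  expect_equal(nrow(disj$gained), 1)
  withr::with_seed(14, {
    a <- random_intervals(50)
    b <- random_intervals(50)
    got <- presence_absence_differential(a, b)
    want <- oracle_presence_absence(a, b)
    expect_equal(got$lost, want$lost)
    expect_equal(got$gained, want$gained)
  })
})

test_that("BED round-trips preserve intervals and chromosome normalization is explicit", {
  x <- genomic_intervals(c("chr1", "chr2"), c(0, 50), c(10, 99))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  expect_equal(read_bed(path), x[, c("chrom", "start", "end")])
  x6 <- genomic_intervals("chr1", 5, 80, strand = "-", name = "pk1", score = 7)
  path6 <- withr::local_tempfile(fileext = ".bed")
  write_bed(x6, path6)
  back <- read_bed(path6)
  expect_equal(back$name, "pk1")
  expect_equal(back$strand, "-")
  expect_equal(normalize_chroms(tibble::tibble(chrom = c("1", "chrX")))$chrom,
               c("chr1", "chrX"))
  expect_equal(
    normalize_chroms(tibble::tibble(chrom = "chr1"), style = "plain")$chrom, "1"
  )
})
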