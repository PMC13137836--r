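#' Genomic intervals as tibbles
#'
#' All coordinates in this package are BED-style: 0-based starts, half-open
#' `[start, end)` spans. An interval table is an ordinary tibble with at least
#' the columns `chrom` (character), `start` and `end` (non-negative, `end >
#' start`); `strand`, `name` and `score` are optional. Annotation dialects
#' using 1-based closed coordinates must be converted at the reading boundary
#' (see [read_bed()] and the readers in the interaction I/O layer).
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default).
#' @param name Optional labels.
#' @param score Optional numeric scores.
#'
#' @return A tibble with one row per interval, sorted as given.
#' @examples
#' genomic_intervals("chr1", c(0, 500), c(100, 900))
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              score = NA_real_) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    name = as.character(name),
    score = as.numeric(score)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` lacks required column(s): %s.", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("`%s` has empty chromosome names.", arg))
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has invalid coordinates (start < 0 or end <= start) at row(s) %s, e.g. %s:%d-%d.",
      arg, paste(head(bad, 5), collapse = ", "),
      x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed) and back
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# put two GRanges on one seqlevel universe so set/overlap ops are quiet
unify_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

overlaps_any <- function(query_gr, subject_gr) {
  u <- unify_seqlevels(query_gr, subject_gr)
  IRanges::overlapsAny(u$a, u$b)
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Sort an interval table by (chrom, start, end)
#'
#' @param x Interval tibble.
#' @return The sorted tibble.
#' @export
sort_intervals <- function(x) {
  validate_intervals(x)
  arrange(x, .data$chrom, .data$start, .data$end)
}

#' Pairwise interval overlap predicate
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least 1 bp under half-open semantics: `max(starts) < min(ends)`. Strand is
#' ignored. Inputs are recycled row-wise like ordinary vectorized arithmetic.
#'
#' @param a,b Interval tibbles with equal row counts (or one row, recycled).
#' @return Logical vector, one verdict per row pair.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' interval_overlaps(a, genomic_intervals("chr1", 199, 300)) # TRUE
#' interval_overlaps(a, genomic_intervals("chr1", 200, 300)) # FALSE: half-open
#' @export
interval_overlaps <- function(a, b) {
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Merge intervals lying within a gap of each other
#'
#' Replicates `bedtools merge -d <gap>`: intervals on the same chromosome
#' whose gap is at most `gap` bp (overlapping and book-ended included) are
#' merged transitively, so chains collapse into single spans. Input order is
#' irrelevant; output is sorted.
#'
#' @param x Interval tibble.
#' @param gap Maximum gap in bp bridged by a merge (default 1000).
#' @return Sorted tibble of merged intervals; consecutive output intervals on
#'   a chromosome are separated by more than `gap` bp.
#' @examples
#' merge_within_gap(genomic_intervals("chr1", c(0, 600), c(100, 700)), gap = 1000)
#' @export
merge_within_gap <- function(x, gap = 1000) {
  validate_intervals(x)
  stopifnot(is.numeric(gap), length(gap) == 1, gap >= 0)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1)
  sort_intervals(granges_to_tbl(gr))
}

#' Consensus regions covered by every sample
#'
#' Base-pair-resolution intersection across per-sample interval sets, the
#' `bedtools multiinter` filter for regions "overlapped by all samples": the
#' maximal sub-intervals at which every sample has coverage. With
#' `require_all = FALSE` the union (coverage by at least one sample) is
#' returned instead.
#'
#' @param per_sample A list (length >= 2) of interval tibbles, one per sample.
#' @param require_all Require coverage by every sample (default) or any.
#' @return Sorted tibble of consensus intervals (possibly empty).
#' @examples
#' consensus_regions(list(
#'   genomic_intervals("chr1", 0, 300),
#'   genomic_intervals("chr1", 100, 400),
#'   genomic_intervals("chr1", 200, 500)
#' )) # chr1:[200,300)
#' @export
consensus_regions <- function(per_sample, require_all = TRUE) {
  if (!is.list(per_sample) || length(per_sample) < 2) {
    abort("`per_sample` must be a list of at least 2 interval sets.")
  }
  grs <- lapply(per_sample, function(s) GenomicRanges::reduce(as_granges(s)))
  out <- if (require_all) {
    Reduce(function(a, b) {
      u <- unify_seqlevels(a, b)
      GenomicRanges::intersect(u$a, u$b, ignore.strand = TRUE)
    }, grs)
  } else {
    GenomicRanges::reduce(do.call(c, grs))
  }
  sort_intervals(granges_to_tbl(out))
}

#' Presence/absence differential peaks between two conditions
#'
#' The intersect `-v` convention for binary differential peak calling:
#' `lost` are reference peaks with no 1-bp overlap in the treatment set,
#' `gained` are treatment peaks with no overlap in the reference set.
#'
#' @param reference,treatment Interval tibbles of peak calls.
#' @return A list with interval tibbles `lost` and `gained`.
#' @export
presence_absence_differential <- function(reference, treatment) {
  validate_intervals(reference, "reference")
  validate_intervals(treatment, "treatment")
  ref_gr <- as_granges(reference)
  trt_gr <- as_granges(treatment)
  lost_idx <- !overlaps_any(ref_gr, trt_gr)
  gained_idx <- !overlaps_any(trt_gr, ref_gr)
  list(
    lost = as_tibble(reference[lost_idx, , drop = FALSE]),
    gained = as_tibble(treatment[gained_idx, , drop = FALSE])
  )
}

#' Promoter windows around transcription start sites
#'
#' For each annotation record the TSS is `txStart` on the plus strand and
#' `txEnd - 1` on the minus strand (0-based). The promoter window is the
#' `slop -b`-style symmetric flank `[tss - flank, tss + flank)`, clipped at
#' position 0. Duplicate identical windows for the same gene collapse to one
#' record.
#'
#' @param annotation Tibble with columns `chrom`, `txStart`, `txEnd`,
#'   `strand` (`+`/`-`) and `gene_id` (plus optional `transcript_id`),
#'   0-based half-open.
#' @param flank Flank size in bp on each side of the TSS (default 1000,
#'   i.e. a 2-kb window).
#' @return Tibble of promoter records: `gene_id`, `chrom`, `tss`, `strand`,
#'   `start`, `end` (the window).
#' @examples
#' ann <- tibble::tibble(
#'   chrom = "chr1", txStart = 5000, txEnd = 8000,
#'   strand = "+", gene_id = "gA"
#' )
#' make_promoter_windows(ann) # window chr1:[4000,6000)
#' @export
make_promoter_windows <- function(annotation, flank = 1000) {
  stopifnot(is.data.frame(annotation))
  needed <- c("chrom", "txStart", "txEnd", "strand", "gene_id")
  missing_cols <- setdiff(needed, names(annotation))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "annotation lacks column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  stopifnot(is.numeric(flank), length(flank) == 1, flank > 0)
  bad <- which(annotation$txStart < 0 | annotation$txEnd <= annotation$txStart)
  if (length(bad) > 0) {
    abort(sprintf(
      "annotation has negative or inverted coordinates for gene %s (row %d).",
      annotation$gene_id[bad[1]], bad[1]
    ))
  }
  bad_strand <- which(!annotation$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf(
      "annotation has unknown strand '%s' for gene %s (row %d).",
      annotation$strand[bad_strand[1]], annotation$gene_id[bad_strand[1]],
      bad_strand[1]
    ))
  }
  tss <- ifelse(annotation$strand == "+", annotation$txStart, annotation$txEnd - 1)
  out <- tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    tss = as.numeric(tss),
    strand = annotation$strand,
    start = pmax(0, tss - flank),
    end = as.numeric(tss + flank)
  )
  distinct(out, .data$gene_id, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

#' Normalize chromosome naming style
#'
#' Exact string equality is the matching rule everywhere in this package;
#' this converter is the explicit, opt-in bridge between the "chr1" (UCSC)
#' and "1" (Ensembl-style) dialects. It is never applied implicitly.
#'
#' @param x Interval tibble (or any tibble with a `chrom` column).
#' @param style Target style: `"ucsc"` prefixes bare names with "chr",
#'   `"plain"` strips a leading "chr".
#' @return The tibble with `chrom` rewritten.
#' @export
normalize_chroms <- function(x, style = c("ucsc", "plain")) {
  style <- match.arg(style)
  stopifnot("chrom" %in% names(x))
  x$chrom <- if (style == "ucsc") {
    ifelse(grepl("^chr", x$chrom), x$chrom, paste0("chr", x$chrom))
  } else {
    sub("^chr", "", x$chrom)
  }
  x
}

#' Read and write BED3/BED6 files
#'
#' Tab-separated, half-open 0-based coordinates, `#` comment lines skipped.
#' Three-column files yield `chrom`/`start`/`end`; six-column files add
#' `name`, `score`, `strand`.
#'
#' @param path File path.
#' @return For `read_bed`, an interval tibble.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = FALSE, comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("BED file '%s' is empty.", path))
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (ncol(raw) < 3) abort(sprintf("BED file '%s' has fewer than 3 columns.", path))
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]])
  )
  if (ncol(raw) >= 6) {
    out$name <- as.character(raw[[4]])
    out$score <- suppressWarnings(as.numeric(raw[[5]]))
    out$strand <- as.character(raw[[6]])
  }
  validate_intervals(out, path)
  out
}

#' @rdname read_bed
#' @param x Interval tibble to write.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x)) &&
      !anyNA(x$name) && !anyNA(x$score) && !anyNA(x$strand)) {
    cols <- c(cols, "name", "score", "strand")
  }
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
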