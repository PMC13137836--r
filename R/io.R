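#' Canonical interaction identifiers
#'
#' A two-ended contact gets one id regardless of which end is listed first:
#' the two ends are ordered lexicographically by (chrom, start, end) and
#' concatenated. Collisions therefore occur only for genuinely identical
#' coordinate pairs.
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 Coordinate vectors of the two
#'   ends (0-based half-open).
#' @return Character vector of canonical ids.
#' @export
canonical_interaction_id <- function(chrom1, start1, end1, chrom2, start2, end2) {
  key1 <- sprintf("%s:%d-%d", chrom1, as.integer(start1), as.integer(end1))
  key2 <- sprintf("%s:%d-%d", chrom2, as.integer(start2), as.integer(end2))
  swap <- (chrom2 < chrom1) |
    (chrom2 == chrom1 & start2 < start1) |
    (chrom2 == chrom1 & start2 == start1 & end2 < end1)
  paste(ifelse(swap, key2, key1), ifelse(swap, key1, key2), sep = "__")
}

# interaction tibble column contract shared by all readers
interaction_cols <- c(
  "id", "sample", "chrom1", "start1", "end1", "chrom2", "start2", "end2"
)

validate_interactions <- function(x, arg = "interactions") {
  missing_cols <- setdiff(interaction_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` lacks interaction column(s): %s.", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(x)
}

read_numeric_table <- function(path) {
  readr::read_tsv(path,
    col_names = FALSE, comment = "#", show_col_types = FALSE,
    progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Read CHiCAGO-style ibed interaction files
#'
#' Expects the 10-column ibed dialect: bait chrom/start/end/name, other-end
#' chrom/start/end/name, read count, CHiCAGO score. A header line is
#' tolerated. Rows with `score < min_score` are dropped (CHiCAGO's
#' conventional significance cut of 5 is inclusive: kept iff
#' `score >= min_score`). The bait is always end 1.
#'
#' @param path ibed file path.
#' @param sample Sample label attached to every interaction.
#' @param min_score Minimum retained score (default 5).
#' @return Interaction tibble with columns `id`, `sample`, end coordinates,
#'   `bait_name`, `oe_name`, `raw_count`, `score`, and `bait_end = 1L`.
#' @export
read_interactions_ibed <- function(path, sample, min_score = 5) {
  raw <- read_numeric_table(path)
  if (nrow(raw) == 0) {
    warn(sprintf("ibed file '%s' is empty.", path))
    return(empty_interactions())
  }
  header_offset <- 0L
  if (is.na(suppressWarnings(as.numeric(raw[[2]][1])))) {
    raw <- raw[-1, , drop = FALSE]
    header_offset <- 1L
    if (nrow(raw) == 0) {
      warn(sprintf("ibed file '%s' has a header but no rows.", path))
      return(empty_interactions())
    }
  }
  if (ncol(raw) < 10) {
    abort(sprintf("ibed file '%s' has %d columns; 10 expected.", path, ncol(raw)))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "ibed file '%s': non-numeric %s at line %d.",
        path, what, bad[1] + header_offset
      ))
    }
    v
  }
  out <- tibble(
    sample = sample,
    chrom1 = as.character(raw[[1]]),
    start1 = num(2, "bait start"), end1 = num(3, "bait end"),
    bait_name = as.character(raw[[4]]),
    chrom2 = as.character(raw[[5]]),
    start2 = num(6, "other-end start"), end2 = num(7, "other-end end"),
    oe_name = as.character(raw[[8]]),
    raw_count = num(9, "read count"),
    score = num(10, "score")
  )
  out$id <- canonical_interaction_id(
    out$chrom1, out$start1, out$end1, out$chrom2, out$start2, out$end2
  )
  out$bait_end <- 1L
  out <- filter(out, .data$score >= min_score)
  select(out, all_of(interaction_cols), "bait_name", "oe_name", "raw_count",
         "score", "bait_end")
}

#' @rdname read_interactions_ibed
#' @param x Interaction tibble to write (bait is end 1).
#' @export
write_interactions_ibed <- function(x, path) {
  validate_interactions(x)
  col_or <- function(nm, default) if (nm %in% names(x)) x[[nm]] else default
  n_reads <- col_or("raw_count", rep(0, nrow(x)))
  n_reads[is.na(n_reads)] <- 0
  out <- tibble(
    bait_chr = x$chrom1, bait_start = as.integer(x$start1),
    bait_end = as.integer(x$end1),
    bait_name = col_or("bait_name", col_or("gene", x$id)),
    otherEnd_chr = x$chrom2, otherEnd_start = as.integer(x$start2),
    otherEnd_end = as.integer(x$end2),
    otherEnd_name = col_or("oe_name", rep(".", nrow(x))),
    N_reads = as.integer(n_reads), score = x$score
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

empty_interactions <- function() {
  tibble(
    id = character(), sample = character(),
    chrom1 = character(), start1 = numeric(), end1 = numeric(),
    chrom2 = character(), start2 = numeric(), end2 = numeric(),
    bait_name = character(), oe_name = character(),
    raw_count = numeric(), score = numeric(), bait_end = integer()
  )
}

#' Read and write BEDPE interaction files with raw counts
#'
#' Reads loops in BEDPE layout (`chrom1 start1 end1 chrom2 start2 end2
#' [name] count`): at least 7 columns, with the raw read count taken from the
#' last numeric column after the six coordinates (column 7 in the minimal
#' dialect, column 8 when a name column is present). Scores are left unset;
#' per-10M normalization is a separate step ([normalize_per_10M()]). The
#' library size is attached both as a column and as an attribute.
#'
#' @param path BEDPE file path.
#' @param sample Sample label.
#' @param library_size Total sequenced reads for the sample.
#' @return Interaction tibble with `raw_count` and `library_size` columns.
#' @export
read_interactions_bedpe <- function(path, sample, library_size) {
  stopifnot(is.numeric(library_size), length(library_size) == 1, library_size > 0)
  raw <- read_numeric_table(path)
  if (nrow(raw) == 0) {
    warn(sprintf("BEDPE file '%s' is empty.", path))
    out <- empty_interactions()
    out$library_size <- numeric()
    return(select(out, -"bait_name", -"oe_name", -"score", -"bait_end"))
  }
  if (is.na(suppressWarnings(as.numeric(raw[[2]][1])))) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 7) {
    abort(sprintf(
      "BEDPE file '%s' has %d columns; need chrom1,start1,end1,chrom2,start2,end2,[name,]count.",
      path, ncol(raw)
    ))
  }
  # minimal dialect: column 7 is the count; with a name column, column 8
  col7_numeric <- !any(is.na(suppressWarnings(as.numeric(raw[[7]]))))
  count_col <- if (ncol(raw) == 7L) 7L else if (col7_numeric) 7L else 8L
  cnt <- suppressWarnings(as.numeric(raw[[count_col]]))
  if (any(is.na(cnt)) || any(cnt < 0)) {
    abort(sprintf(
      "BEDPE file '%s': count column (column %d) must be non-negative numeric.",
      path, count_col
    ))
  }
  out <- tibble(
    sample = sample,
    chrom1 = as.character(raw[[1]]),
    start1 = as.numeric(raw[[2]]), end1 = as.numeric(raw[[3]]),
    chrom2 = as.character(raw[[4]]),
    start2 = as.numeric(raw[[5]]), end2 = as.numeric(raw[[6]]),
    raw_count = cnt,
    library_size = library_size
  )
  out$id <- canonical_interaction_id(
    out$chrom1, out$start1, out$end1, out$chrom2, out$start2, out$end2
  )
  out <- select(out, all_of(interaction_cols), "raw_count", "library_size")
  attr(out, "library_size") <- library_size
  out
}

#' @rdname read_interactions_bedpe
#' @param x Interaction tibble to write (coordinates plus `raw_count`).
#' @export
write_interactions_bedpe <- function(x, path) {
  validate_interactions(x)
  out <- x[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "id",
               "raw_count")]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a wide interaction-by-sample score matrix
#'
#' The peak-matrix layout: one row per interaction with both ends'
#' coordinates (`chrom1 start1 end1 chrom2 start2 end2`) followed by one
#' numeric score column per sample. Absent scores are `NA` — distinct from 0;
#' the fill policy is applied later by [build_matrix()]. Duplicate
#' interaction rows (same canonical id) are an error.
#'
#' @param path TSV path with a header line.
#' @return Tibble with an `id` column followed by one column per sample.
#' @export
read_peak_matrix <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  coord_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(coord_cols %in% names(raw))) {
    abort(sprintf(
      "peak matrix '%s' must have header columns %s followed by sample columns.",
      path, paste(coord_cols, collapse = ", ")
    ))
  }
  sample_cols <- setdiff(names(raw), coord_cols)
  if (nrow(raw) == 0) {
    return(tibble(id = character()))
  }
  id <- canonical_interaction_id(
    raw$chrom1, raw$start1, raw$end1, raw$chrom2, raw$start2, raw$end2
  )
  if (anyDuplicated(id)) {
    abort(sprintf(
      "peak matrix '%s' has duplicate interaction rows (e.g. %s).",
      path, id[duplicated(id)][1]
    ))
  }
  out <- tibble(id = id)
  for (s in sample_cols) out[[s]] <- as.numeric(raw[[s]])
  out
}

#' @rdname read_peak_matrix
#' @param x Interaction tibble (one row per id) with score columns; must
#'   carry the six end-coordinate columns.
#' @export
write_peak_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read normalized expression tables
#'
#' TSV with a header: a `gene_id` column plus one numeric column of
#' normalized transcript counts per sample. Counts must be non-negative.
#' Exact duplicate gene rows are collapsed; conflicting duplicates are an
#' error.
#'
#' @param path TSV path.
#' @return Tibble `gene_id` + sample columns.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(raw)) {
    abort(sprintf("expression table '%s' lacks a gene_id column.", path))
  }
  sample_cols <- setdiff(names(raw), "gene_id")
  for (s in sample_cols) {
    v <- as.numeric(raw[[s]])
    if (any(is.na(v))) abort(sprintf("expression table '%s': non-numeric counts in '%s'.", path, s))
    if (any(v < 0)) abort(sprintf("expression table '%s': negative counts in '%s'.", path, s))
    raw[[s]] <- v
  }
  raw <- distinct(raw)
  if (anyDuplicated(raw$gene_id)) {
    abort(sprintf(
      "expression table '%s': conflicting duplicate rows for gene %s.",
      path, raw$gene_id[duplicated(raw$gene_id)][1]
    ))
  }
  as_tibble(raw)
}

#' Read differential-expression (DEG) tables
#'
#' TSV with header columns `gene_id`, `log2fc`, `padj`. Adjusted p-values
#' must lie in \[0, 1\]. A `direction` column (sign of `log2fc`) is added.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `log2fc`, `padj`, `direction`.
#' @export
read_deg <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  needed <- c("gene_id", "log2fc", "padj")
  if (!all(needed %in% names(raw))) {
    abort(sprintf(
      "DEG table '%s' must have columns %s.", path, paste(needed, collapse = ", ")
    ))
  }
  raw$log2fc <- as.numeric(raw$log2fc)
  raw$padj <- as.numeric(raw$padj)
  if (any(is.na(raw$log2fc)) || any(is.na(raw$padj))) {
    abort(sprintf("DEG table '%s': non-numeric log2fc or padj.", path))
  }
  if (any(raw$padj < 0 | raw$padj > 1)) {
    abort(sprintf(
      "DEG table '%s': padj outside [0, 1] for gene %s.",
      path, raw$gene_id[which(raw$padj < 0 | raw$padj > 1)[1]]
    ))
  }
  raw <- distinct(raw)
  if (anyDuplicated(raw$gene_id)) {
    abort(sprintf(
      "DEG table '%s': conflicting duplicate rows for gene %s.",
      path, raw$gene_id[duplicated(raw$gene_id)][1]
    ))
  }
  raw$direction <- dplyr::case_when(
    raw$log2fc > 0 ~ "up", raw$log2fc < 0 ~ "down", TRUE ~ "none"
  )
  as_tibble(raw)
}

#' Export interactions as WashU longrange text (write-only)
#'
#' One line per interaction end pair in the WashU epigenome browser
#' `longrange` dialect: `chrom start end chrom2:start2-end2,score`. Provided
#' for visualization; never re-imported.
#'
#' @param x Interaction tibble with a `score` column.
#' @param path Output path.
#' @export
write_longrange <- function(x, path) {
  validate_interactions(x)
  score <- if ("score" %in% names(x)) x$score else rep(1, nrow(x))
  lines <- sprintf(
    "%s\t%d\t%d\t%s:%d-%d,%g",
    x$chrom1, as.integer(x$start1), as.integer(x$end1),
    x$chrom2, as.integer(x$start2), as.integer(x$end2), score
  )
  writeLines(lines, path)
  invisible(path)
}
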