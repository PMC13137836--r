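# Brute-force per-base oracles, deliberately independent of the package's
# GenomicRanges-backed implementations: every operation is recomputed on
# explicit integer position sets.

oracle_positions <- function(x) {
  # named list chrom -> sorted unique covered positions
  out <- list()
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    out[[ch]] <- c(out[[ch]], seq(x$start[i], x$end[i] - 1))
  }
  lapply(out, function(p) sort(unique(p)))
}

runs_to_intervals <- function(chrom, pos, max_gap = 0) {
  # contiguous (or gap-bridged) runs of positions -> half-open intervals
  if (length(pos) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  brk <- which(diff(pos) > max_gap + 1)
  starts <- pos[c(1, brk + 1)]
  ends <- pos[c(brk, length(pos))] + 1
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

oracle_merge <- function(x, gap) {
  pos <- oracle_positions(x)
  dplyr::bind_rows(lapply(names(pos), function(ch) {
    runs_to_intervals(ch, pos[[ch]], max_gap = gap)
  })) |>
    dplyr::arrange(chrom, start, end)
}

oracle_consensus <- function(per_sample) {
  pos_sets <- lapply(per_sample, oracle_positions)
  chroms <- sort(unique(unlist(lapply(pos_sets, names))))
  dplyr::bind_rows(lapply(chroms, function(ch) {
    covered <- lapply(pos_sets, function(p) p[[ch]])
    shared <- Reduce(intersect, covered)
    runs_to_intervals(ch, sort(shared))
  })) |>
    dplyr::arrange(chrom, start, end)
}

oracle_presence_absence <- function(reference, treatment) {
  hit <- function(x, against) {
    vapply(seq_len(nrow(x)), function(i) {
      any(vapply(seq_len(nrow(against)), function(j) {
        oracle_overlap(x[i, ], against[j, ])
      }, logical(1)))
    }, logical(1))
  }
  list(
    lost = x_subset(reference, !hit(reference, treatment)),
    gained = x_subset(treatment, !hit(treatment, reference))
  )
}

x_subset <- function(x, keep) tibble::as_tibble(x[keep, , drop = FALSE])

random_intervals <- function(n, n_chroms = 3, max_pos = 2000, max_width = 150) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

# Fisher two-sided p by direct hypergeometric enumeration with choose()
oracle_fisher_p <- function(counts) {
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  m <- a + b # row 1 total
  n2 <- c + d # row 2 total
  k <- a + c # column 1 total
  total <- m + n2
  support <- max(0, k - n2):min(k, m)
  probs <- choose(m, support) * choose(n2, k - support) / choose(total, k)
  p_obs <- choose(m, a) * choose(n2, k - a) / choose(total, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct-summation Poisson upper tail (no ppois): sum P(X = i) for i >= k
# far enough into the tail that the remainder is negligible
oracle_poisson_tail <- function(k, lambda) {
  k <- ceiling(k)
  if (k <= 0) return(1)
  i <- k:(k + 3000 + ceiling(10 * lambda))
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}
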