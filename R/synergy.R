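#' Bliss-independence synergy scoring of a dose-response matrix
#'
#' Input is a viability matrix (fraction of live cells, in \[0, 1\]) over a
#' dose grid of drug A (rows) x drug B (columns), including the zero-dose
#' margins: row 1 is drug B alone, column 1 drug A alone, cell (1,1)
#' untreated. Inhibition is `y = 1 - viability`; the Bliss-expected combo
#' inhibition is `e = yA + yB - yA*yB` from the single-agent margins, and
#' the excess over expectation `(y_obs - e) * 100` is reported per
#' combination cell. The mean score is the unweighted mean over combination
#' cells only (margins excluded); a mean above +10 is called synergistic,
#' below -10 antagonistic, additive in between.
#'
#' @param viability Numeric matrix with numeric dose dimnames; `[1,1]` must
#'   be the zero/zero reference well.
#' @return Object of class `bliss_synergy`: `excess` matrix (combo cells),
#'   `mean_score`, `call`.
#' @examples
#' v <- matrix(c(1, 0.6, 0.5, 0.1), 2, 2,
#'   dimnames = list(c("0", "1"), c("0", "1"))
#' )
#' bliss_synergy(v)$excess # (1-0.1) - (0.5+0.4-0.2) = +0.2 -> +20
#' @export
bliss_synergy <- function(viability) {
  m <- as.matrix(viability)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("viability matrix needs zero-dose margins plus >= 1 combination cell.")
  }
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort("viability values outside [0, 1]; normalize first (normalize_viability).")
  }
  y <- 1 - m
  yA <- y[, 1] # drug A alone (column of zero drug B)
  yB <- y[1, ] # drug B alone
  excess <- matrix(NA_real_, nrow(m) - 1, ncol(m) - 1,
    dimnames = list(rownames(m)[-1], colnames(m)[-1])
  )
  for (i in 2:nrow(m)) {
    for (j in 2:ncol(m)) {
      e <- yA[i] + yB[j] - yA[i] * yB[j]
      excess[i - 1, j - 1] <- (y[i, j] - e) * 100
    }
  }
  mean_score <- mean(excess)
  call <- if (mean_score > 10) "synergistic" else if (mean_score < -10) {
    "antagonistic"
  } else {
    "additive"
  }
  structure(
    list(excess = excess, mean_score = mean_score, call = call),
    class = "bliss_synergy"
  )
}

#' @export
print.bliss_synergy <- function(x, ...) {
  cat(sprintf("Bliss synergy: mean score %.2f (%s)\n", x$mean_score, x$call))
  invisible(x)
}

#' @describeIn bliss_synergy Per-cell excess scores in long form.
#' @param x A `bliss_synergy` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bliss_synergy <- function(x, ...) {
  ex <- x$excess
  tidyr::expand_grid(
    dose_a = rownames(ex), dose_b = colnames(ex)
  ) %>%
    mutate(excess = as.vector(t(ex)))
}

#' @describeIn bliss_synergy One-row summary: mean score and call.
#' @exportS3Method generics::glance
glance.bliss_synergy <- function(x, ...) {
  tibble(mean_score = x$mean_score, call = x$call)
}

#' @describeIn bliss_synergy Dose-grid tile plot of excess scores.
#' @param object A `bliss_synergy` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bliss_synergy <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_b, .data$dose_a,
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "dose B", y = "dose A", fill = "Bliss excess") +
    ggplot2::theme_minimal()
}

#' Normalize a viability plate to its reference wells
#'
#' Each well's signal is divided by the mean signal of the experiment's
#' reference wells: `"dmso"` uses the untreated wells (both doses 0),
#' `"tki_only"` the wells treated with drug A alone (dose B 0, dose A > 0)
#' — the normalization used when combination effects are expressed relative
#' to TKI-only treatment.
#'
#' @param plate Tibble with columns `experiment`, `dose_a`, `dose_b`,
#'   `signal`.
#' @param reference `"dmso"` or `"tki_only"`.
#' @return The plate with a `viability` column (signal / reference mean).
#' @export
normalize_viability <- function(plate, reference = c("dmso", "tki_only")) {
  reference <- match.arg(reference)
  stopifnot(all(c("experiment", "dose_a", "dose_b", "signal") %in% names(plate)))
  is_ref <- if (reference == "dmso") {
    plate$dose_a == 0 & plate$dose_b == 0
  } else {
    plate$dose_b == 0 & plate$dose_a > 0
  }
  ref_means <- plate %>%
    filter(is_ref) %>%
    group_by(.data$experiment) %>%
    summarise(ref_mean = mean(.data$signal), .groups = "drop")
  missing_exp <- setdiff(unique(plate$experiment), ref_means$experiment)
  if (length(missing_exp) > 0) {
    abort(sprintf(
      "experiment(s) without %s reference wells: %s.",
      reference, paste(missing_exp, collapse = ", ")
    ))
  }
  if (any(ref_means$ref_mean == 0)) abort("zero reference-well mean.")
  plate %>%
    left_join(ref_means, by = "experiment") %>%
    mutate(viability = .data$signal / .data$ref_mean) %>%
    select(-"ref_mean")
}

#' Pivot a normalized plate into a dose-grid viability matrix
#'
#' @param plate Tibble with `dose_a`, `dose_b`, `viability` (replicate wells
#'   averaged).
#' @return Matrix with drug-A doses as rows, drug-B doses as columns.
#' @export
viability_matrix <- function(plate) {
  stopifnot(all(c("dose_a", "dose_b", "viability") %in% names(plate)))
  agg <- plate %>%
    group_by(.data$dose_a, .data$dose_b) %>%
    summarise(viability = mean(.data$viability), .groups = "drop")
  doses_a <- sort(unique(agg$dose_a))
  doses_b <- sort(unique(agg$dose_b))
  m <- matrix(NA_real_, length(doses_a), length(doses_b),
    dimnames = list(as.character(doses_a), as.character(doses_b))
  )
  m[cbind(match(agg$dose_a, doses_a), match(agg$dose_b, doses_b))] <- agg$viability
  m
}
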