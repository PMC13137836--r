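#' Core interactions shared by every sample
#'
#' The cross-sample "core" signature set: canonical interaction ids present
#' in every sample, restricted to the given regulatory classes — and the
#' class filter is evaluated per sample, so an interaction that is (say) an
#' EPI in two samples but unclassified in the third is excluded.
#'
#' @param interactions Classified interaction tibble covering >= 2 samples.
#' @param class_filter Regulatory classes that qualify (default EPI + PPI).
#' @return Sorted character vector of canonical ids.
#' @export
core_interactions <- function(interactions, class_filter = c("EPI", "PPI")) {
  if (!"regulatory_class" %in% names(interactions)) {
    abort("interactions must be classified first.")
  }
  samples <- unique(interactions$sample)
  if (length(samples) < 2) abort("core_interactions needs >= 2 samples.")
  qualifying <- interactions %>%
    filter(.data$regulatory_class %in% class_filter) %>%
    distinct(.data$sample, .data$id)
  per_sample_ids <- split(qualifying$id, factor(qualifying$sample, levels = samples))
  sort(Reduce(intersect, per_sample_ids))
}

#' Build an interaction-by-sample score matrix
#'
#' @param ids Row ids (canonical interaction or region ids).
#' @param scores Long tibble with columns `sample`, `id`, `score`.
#' @param missing_policy `"zero"` (default) fills absent scores with 0 — an
#'   undetected interaction is treated as absent at the score threshold;
#'   `"drop"` removes rows not observed in every sample.
#' @return Tibble with `id` plus one numeric column per sample.
#' @export
build_matrix <- function(ids, scores, missing_policy = c("zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(c("sample", "id", "score") %in% names(scores)))
  extra <- setdiff(unique(scores$id[scores$id %in% ids]), ids)
  stopifnot(length(extra) == 0)
  wide <- scores %>%
    filter(.data$id %in% ids) %>%
    distinct(.data$sample, .data$id, .keep_all = TRUE) %>%
    tidyr::pivot_wider(
      id_cols = "id", names_from = "sample", values_from = "score"
    )
  wide <- left_join(tibble(id = ids), wide, by = "id")
  sample_cols <- setdiff(names(wide), "id")
  if (missing_policy == "zero") {
    wide <- mutate(wide, across(all_of(sample_cols), ~ dplyr::coalesce(.x, 0)))
  } else {
    wide <- filter(wide, !dplyr::if_any(all_of(sample_cols), is.na))
  }
  wide
}

matrix_from_tbl <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
  rownames(m) <- x$id
  storage.mode(m) <- "double"
  m
}

#' Average-linkage (UPGMA) clustering of sample score profiles
#'
#' Samples are the column vectors of the score matrix; pairwise Euclidean
#' distances feed average-linkage agglomeration (`dist()` +
#' `hclust(method = "average")`), whose merge heights are mean inter-cluster
#' distances and are non-decreasing (UPGMA admits no inversions).
#'
#' @param mat Score tibble from [build_matrix()] (`id` + sample columns), or
#'   a numeric matrix with samples as columns.
#' @return An object of class `upgma` wrapping the `hclust` fit; see
#'   [tidy.upgma()] and [upgma_newick()].
#' @export
upgma <- function(mat) {
  m <- if (is.data.frame(mat)) matrix_from_tbl(mat) else as.matrix(mat)
  if (ncol(m) < 2) abort("upgma needs >= 2 samples.")
  if (!all(is.finite(m))) abort("upgma requires finite scores.")
  hc <- hclust(dist(t(m), method = "euclidean"), method = "average")
  structure(
    list(hclust = hc, samples = colnames(m), n_features = nrow(m)),
    class = "upgma"
  )
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf(
    "UPGMA (average-linkage, Euclidean) of %d samples on %d features\n",
    length(x$samples), x$n_features
  ))
  invisible(x)
}

#' @describeIn upgma Merge list as a tibble: one row per agglomeration with
#'   its height and member labels.
#' @param x An `upgma` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.upgma <- function(x, ...) {
  hc <- x$hclust
  tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1],
    right = hc$merge[, 2],
    height = hc$height
  )
}

#' @describeIn upgma One-row summary: sample count and first/last merge
#'   heights.
#' @exportS3Method generics::glance
glance.upgma <- function(x, ...) {
  tibble(
    n_samples = length(x$samples),
    n_features = x$n_features,
    first_merge_height = x$hclust$height[1],
    last_merge_height = x$hclust$height[length(x$hclust$height)]
  )
}

#' @describeIn upgma Newick serialization of the dendrogram.
#' @param fit An `upgma` object.
#' @export
upgma_newick <- function(fit) {
  stopifnot(inherits(fit, "upgma"))
  ape::write.tree(ape::as.phylo(fit$hclust))
}

#' First-merged sample pair of a dendrogram
#'
#' @param fit An `upgma` object.
#' @return Character vector of the two sample labels merged first.
#' @export
first_merge_pair <- function(fit) {
  stopifnot(inherits(fit, "upgma"))
  m <- fit$hclust$merge[1, ]
  fit$hclust$labels[-m]
}

#' PCA of sample score profiles
#'
#' Samples are observations (the stored matrix is transposed before
#' `prcomp()`), columns are centered, not scaled — the `prcomp()` defaults.
#' Since SVD component signs are arbitrary, each component is canonicalized
#' so its largest-magnitude loading is positive, making coordinates
#' deterministic.
#'
#' @param mat Score tibble (`id` + sample columns) or numeric matrix with
#'   samples as columns.
#' @param center,scale. Passed to [stats::prcomp()].
#' @return Object of class `signature_pca`: `scores` (samples x PCs),
#'   `loadings`, `explained` (variance fractions), `centered` matrix.
#' @export
pca_signatures <- function(mat, center = TRUE, scale. = FALSE) {
  m <- if (is.data.frame(mat)) matrix_from_tbl(mat) else as.matrix(mat)
  if (ncol(m) < 2) abort("pca_signatures needs >= 2 samples.")
  if (nrow(m) < 1) abort("pca_signatures needs >= 1 feature.")
  tm <- t(m) # samples as rows
  fit <- prcomp(tm, center = center, scale. = scale.)
  # canonical signs: largest-|loading| coordinate positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    k <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[k, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  total_var <- sum(fit$sdev^2)
  explained <- if (total_var > 0) fit$sdev^2 / total_var else rep(0, length(fit$sdev))
  structure(
    list(
      scores = fit$x,
      loadings = fit$rotation,
      sdev = fit$sdev,
      explained = explained,
      centered = scale(tm, center = center, scale = scale.),
      samples = rownames(tm)
    ),
    class = "signature_pca"
  )
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    length(x$samples), 100 * x$explained[1],
    if (length(x$explained) > 1) 100 * x$explained[2] else 0
  ))
  invisible(x)
}

#' @describeIn pca_signatures Per-sample PC coordinates as a tibble.
#' @param x A `signature_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.signature_pca <- function(x, ...) {
  out <- as_tibble(x$scores)
  out$sample <- x$samples
  select(out, "sample", dplyr::everything())
}

#' @describeIn pca_signatures Explained-variance fractions per component.
#' @exportS3Method generics::glance
glance.signature_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$explained)),
    explained_variance = x$explained
  )
}

#' @describeIn pca_signatures PC1/PC2 scatter, optionally colored by group.
#' @param object A `signature_pca` object.
#' @param groups Optional named vector mapping sample -> group label.
#' @exportS3Method ggplot2::autoplot
autoplot.signature_pca <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  df$group <- if (is.null(groups)) "sample" else unname(groups[df$sample])
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}
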