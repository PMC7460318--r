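# Beta diversity: Bray-Curtis dissimilarity, principal coordinate analysis
# (Gower double-centering + eigendecomposition), shared-OTU (Venn)
# accounting across groups, and UPGMA similarity clustering.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between samples. By the
#' QIIME convention the input should be relative abundances
#' ([relative_abundance()]); the measure is then invariant to sequencing
#' depth.
#'
#' @param x A samples-by-taxa abundance matrix, or an `otu_tbl`
#'   (converted to relative abundances and transposed).
#' @return A [stats::dist] object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_tbl")) t(relative_abundance(x)) else as.matrix(x)
  if (any(m < 0)) abort("Abundances must be non-negative.")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(paste0("All-zero sample(s): ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2 / 2`,
#' eigendecomposition, axis scores = eigenvectors scaled by the square root
#' of their (positive) eigenvalues. Negative eigenvalues, which arise for
#' non-Euclidean dissimilarities such as Bray-Curtis, are reported as-is —
#' no Cailliez/Lingoes correction — and the proportion explained is taken
#' over the positive eigenvalues only.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @return A `pcoa_ord` object: `eigenvalues` (all, descending), `scores`
#'   (samples x positive axes), `proportion_explained`, `labels`.
#' @export
pcoa_ord <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-12)) abort("Dissimilarity matrix must be symmetric.")
  n <- nrow(m)
  labels <- rownames(m) %||% paste0("sample_", seq_len(n))
  a <- -0.5 * m^2
  centered <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(centered, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  scores <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  rownames(scores) <- labels
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(eigenvalues = eig$values,
                 scores = scores,
                 proportion_explained = eig$values[pos] / sum(eig$values[pos]),
                 labels = labels, method = "PCoA"),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- min(2, length(x$proportion_explained))
  cat("PCoA of", length(x$labels), "samples;",
      paste0("axis ", seq_len(k), ": ",
             sprintf("%.2f%%", 100 * x$proportion_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pcoa_ord Axis scores as a long-friendly tibble (one row per
#'   sample, axes as columns, proportions in attributes).
#' @param x A `pcoa_ord` object.
#' @param ... Unused.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  out <- as_tibble(x$scores) |> mutate(sample = x$labels, .before = 1)
  out
}

#' @describeIn pcoa_ord One-row summary: sample count, positive/negative
#'   eigenvalue counts, first two proportions explained.
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  pe <- x$proportion_explained
  tibble(n_samples = length(x$labels),
         n_positive = length(pe),
         n_negative = sum(x$eigenvalues < 0),
         prop_axis1 = pe[1],
         prop_axis2 = if (length(pe) > 1) pe[2] else NA_real_)
}

#' Shared-OTU (Venn) accounting across sample groups
#'
#' An OTU belongs to a group when its summed count over the group's samples
#' is positive. Reports, for every non-empty subset of groups, the number
#' of OTUs present in exactly those groups; the counts partition the OTU
#' union, and the all-groups cell is the shared core.
#'
#' @param x An `otu_tbl`.
#' @param groups Named character vector or list mapping every sample to a
#'   group label.
#' @return A `venn_counts` object: `membership` tibble (subset, degree,
#'   n_otus), `group_totals`, `core`, `union_size`, `core_pct`.
#' @export
shared_otu_sets <- function(x, groups) {
  samples <- otu_samples(x)
  groups <- unlist(groups)
  unmapped <- setdiff(samples, names(groups))
  if (length(unmapped)) {
    abort(paste0("Sample(s) without a group: ", paste(unmapped, collapse = ", ")))
  }
  m <- otu_counts(x)
  glev <- unique(unname(groups[samples]))
  present <- matrix(vapply(glev, function(g) {
    rowSums(m[, samples[groups[samples] == g], drop = FALSE]) > 0
  }, logical(nrow(m))), nrow = nrow(m), dimnames = list(NULL, glev))  # otus x groups
  in_any <- rowSums(present) > 0
  present <- present[in_any, , drop = FALSE]
  pattern <- apply(present, 1, function(r) paste(glev[r], collapse = "&"))
  membership <- tibble(subset = pattern) |>
    group_by(.data$subset) |>
    summarise(n_otus = n(), .groups = "drop") |>
    mutate(degree = stringr::str_count(.data$subset, stringr::fixed("&")) + 1L) |>
    arrange(desc(.data$degree), .data$subset) |>
    select("subset", "degree", "n_otus")
  core_row <- membership$degree == length(glev)
  core <- if (any(core_row)) membership$n_otus[core_row] else 0L
  structure(list(membership = membership,
                 group_totals = setNames(colSums(present), glev),
                 core = core,
                 union_size = nrow(present),
                 core_pct = 100 * core / nrow(present)),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("OTU union:", x$union_size, "| shared core:", x$core,
      sprintf("(%.1f%%)\n", x$core_pct))
  print(x$membership)
  invisible(x)
}

#' @describeIn shared_otu_sets Per-subset membership counts as a tibble.
#' @param x A `venn_counts` object.
#' @param ... Unused.
#' @method tidy venn_counts
#' @export
tidy.venn_counts <- function(x, ...) x$membership

#' UPGMA similarity clustering of a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering, as used for ordering the rows
#' of a sample-similarity heatmap.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @return List with the `hclust` merge tree (`tree`) and the display
#'   `leaf_order` (labels, left to right).
#' @export
similarity_cluster <- function(d) {
  dd <- if (inherits(d, "dist")) d else {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-12)) abort("Dissimilarity matrix must be symmetric.")
    stats::as.dist(m)
  }
  if (attr(dd, "Size") < 2) abort("Clustering needs at least 2 samples.")
  hc <- hclust(dd, method = "average")
  list(tree = hc, leaf_order = hc$labels[hc$order])
}
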