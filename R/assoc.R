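# Environment-taxon association: abundance filtering, Spearman and Pearson
# correlation tables with significance stars, display clustering for
# heatmaps, one-way ANOVA for group differences, and the small composition
# arithmetic used when summarising community tables.

#' Filter taxa by mean relative abundance
#'
#' Keeps taxa whose mean relative abundance across all samples exceeds the
#' threshold — the usual "> 1%" cut applied before correlation heatmaps.
#'
#' @param taxa Taxa-by-samples matrix of proportions.
#' @param threshold Proportion in `[0, 1)`; default 0.01.
#' @return The filtered matrix (possibly zero rows).
#' @export
abundance_filter <- function(taxa, threshold = 0.01) {
  m <- as.matrix(taxa)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1) {
    abort("threshold must be a single proportion in [0, 1).")
  }
  keep <- rowMeans(m) > threshold
  if (threshold == 0) keep <- keep & rowSums(m) > 0
  m[keep, , drop = FALSE]
}

#' Spearman correlation table between taxa and environment
#'
#' Rank correlation (average ranks for ties) of each taxon row against
#' each numeric environment variable, with two-sided p-values from the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` and significance
#' stars at p < 0.05 (`*`) and p < 0.01 (`**`). Constant columns give a
#' missing rho with a warning. No multiple-testing correction by default;
#' `adjust = "BH"` appends a Benjamini-Hochberg column.
#'
#' @param taxa Taxa-by-samples abundance matrix (typically filtered
#'   relative abundances).
#' @param env Data frame of numeric environment variables, samples in rows
#'   aligned with the columns of `taxa`.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A `cor_result`: long tibble with `taxon`, `variable`, `rho`,
#'   `p_value`, `stars`, and `p_adj` when requested.
#' @export
spearman_matrix <- function(taxa, env, adjust = "none") {
  cor_table(as.matrix(taxa), env, method = "spearman", adjust = adjust,
            row_name = "taxon")
}

#' Pearson correlation table among environment variables
#'
#' Product-moment correlation of every pair of numeric environment
#' variables, with the same t-approximation p-values and stars as
#' [spearman_matrix()].
#'
#' @inheritParams spearman_matrix
#' @return A `cor_result` long tibble (`variable` x `variable2`).
#' @export
pearson_matrix <- function(env, adjust = "none") {
  env <- as.data.frame(env)
  num <- env[vapply(env, is.numeric, logical(1))]
  m <- t(as.matrix(num))
  rownames(m) <- names(num)
  out <- cor_table(m, num, method = "pearson",
                   adjust = adjust, row_name = "variable1")
  names(out)[names(out) == "variable"] <- "variable2"
  names(out)[names(out) == "variable1"] <- "variable"
  out
}

cor_table <- function(m, env, method, adjust, row_name) {
  env <- as.data.frame(env)
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  if (!length(num)) abort("No numeric environment variables.")
  n <- ncol(m)
  if (nrow(env) != n) abort("taxa samples and env rows must align.")
  if (n < 3) abort("Need at least 3 paired observations.")
  rows <- list()
  warned <- character(0)
  for (tx in rownames(m)) {
    for (v in num) {
      x <- m[tx, ]
      y <- env[[v]]
      if (sd(x) == 0 || sd(y) == 0) {
        warned <- union(warned, if (sd(y) == 0) v else tx)
        rho <- NA_real_; p <- NA_real_
      } else {
        if (method == "spearman") { x <- rank(x); y <- rank(y) }
        rho <- cor(x, y)
        p <- t_approx_p(rho, n)
      }
      rows[[length(rows) + 1]] <- tibble(!!row_name := tx, variable = v,
                                         rho = rho, p_value = p)
    }
  }
  if (length(warned)) {
    warn(paste0("Constant column(s), correlation undefined: ",
                paste(warned, collapse = ", ")))
  }
  out <- bind_rows(rows) |> mutate(stars = star_labels(.data$p_value))
  if (adjust != "none") out <- out |> mutate(p_adj = p.adjust(.data$p_value, method = adjust))
  structure(out, class = c("cor_result", class(out)), method = method)
}

# two-sided p for a correlation via the t distribution with n-2 df
t_approx_p <- function(rho, n) {
  if (abs(rho) >= 1) return(.Machine$double.eps)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Significance stars at 0.05 / 0.01
#' @param p Vector of p-values (NA allowed).
#' @return `""`, `"*"` or `"**"` per element.
#' @export
star_labels <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Display ordering of a correlation table for heatmaps
#'
#' UPGMA clustering on Euclidean distances between the rows (and columns)
#' of the rho matrix; missing correlations are imputed as 0 with a
#' warning, for ordering only.
#'
#' @param result A `cor_result` from [spearman_matrix()].
#' @return List with `row_order` and `col_order` label vectors.
#' @export
cluster_order <- function(result) {
  rn <- names(result)[1]
  cn <- names(result)[2]
  wide <- tidyr::pivot_wider(as_tibble(result)[c(rn, cn, "rho")],
                             names_from = dplyr::all_of(cn), values_from = "rho")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide[[1]]
  if (anyNA(m)) {
    warn("Missing correlations imputed as 0 for clustering.")
    m[is.na(m)] <- 0
  }
  order_of <- function(mm) {
    if (nrow(mm) < 2) return(rownames(mm))
    hc <- hclust(dist(mm), method = "average")
    rownames(mm)[hc$order]
  }
  list(row_order = order_of(m), col_order = order_of(t(m)))
}

#' One-way ANOVA for a group difference
#'
#' Classical (equal-variance) one-way analysis of variance of a numeric
#' response across groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; every group needs at least 2
#'   observations and there must be at least 2 groups.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @export
group_difference <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("Group(s) with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  tibble(statistic = unname(ow$statistic),
         df_between = unname(ow$parameter[1]),
         df_within = unname(ow$parameter[2]),
         p_value = unname(ow$p.value))
}

#' Whole-community share of a nested taxon
#'
#' Converts a within-group relative abundance (e.g. a phylum's share of
#' all archaeal reads) into its share of the whole community, given the
#' group's own fraction of the community.
#'
#' @param within Proportion of the taxon within its group.
#' @param group_fraction The group's proportion of the whole community.
#' @return `within * group_fraction`.
#' @examples
#' total_community_share(0.5578, 0.024)  # ~0.0134
#' @export
total_community_share <- function(within, group_fraction) {
  if (any(within < 0 | within > 1) || any(group_fraction < 0 | group_fraction > 1)) {
    abort("Proportions must lie in [0, 1].")
  }
  within * group_fraction
}

#' Combined share of dominant taxa
#'
#' Sums the relative abundances exceeding a dominance threshold (the usual
#' "relative richness > 5%" summary of composition barplots).
#'
#' @param props Vector of relative abundances.
#' @param threshold Dominance cut, default 0.05.
#' @return Summed proportion of the dominant taxa.
#' @export
dominance_share <- function(props, threshold = 0.05) {
  if (any(props < 0 | props > 1)) abort("Proportions must lie in [0, 1].")
  sum(props[props > threshold])
}
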