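# Constrained ordination: redundancy analysis (RDA) of community
# composition on environmental variables, Monte Carlo permutation tests of
# their significance, greedy forward selection, and variance partitioning
# on the adjusted-R2 scale.
#
# RDA is PCA of the fitted values of a multivariate least-squares
# regression of the (transformed, column-centred) species matrix on the
# standardized environment matrix. The implementation below keeps that
# definition explicit — projection through a QR decomposition, then an SVD
# of the fitted values — so that general-purpose ordination packages remain
# available as independent cross-checks.

#' Redundancy analysis
#'
#' The species matrix is optionally Hellinger-transformed (square root of
#' relative abundances — the standard variance stabilisation for abundance
#' RDA), column-centred, and regressed on the standardized environmental
#' variables; canonical axes are the principal components of the fitted
#' values.
#'
#' @param species Samples-by-taxa abundance matrix, or an `otu_tbl`.
#' @param env Data frame of numeric environmental variables (samples in
#'   rows, aligned with `species`), e.g. from [env_numeric()].
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return An `rda_fit` object: `eigenvalues` (canonical, descending),
#'   `scores` (site scores, fitted-value principal coordinates),
#'   `biplot` (correlations of env variables with the axes),
#'   `proportion_explained` (per axis, of the constrained variance),
#'   `r_squared`, `adj_r_squared`, `total_ss`, `constrained_ss`, `rank`.
#' @export
rda_fit <- function(species, env, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  prep <- rda_prepare(species, env, transform)
  fit <- rda_core(prep$y, prep$x)
  sv <- svd(fit$fitted)
  keep <- sv$d > max(sv$d, 1) * 1e-9
  eigenvalues <- sv$d[keep]^2 / (prep$n - 1)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = sum(keep))
  rownames(scores) <- prep$labels
  if (ncol(scores)) colnames(scores) <- paste0("RDA", seq_len(ncol(scores)))
  biplot <- if (ncol(scores)) {
    suppressWarnings(cor(prep$x, scores))
  } else matrix(nrow = ncol(prep$x), ncol = 0)
  r2 <- fit$ss_fit / fit$ss_tot
  structure(list(eigenvalues = eigenvalues,
                 scores = scores,
                 biplot = biplot,
                 proportion_explained = if (length(eigenvalues))
                   eigenvalues / sum(eigenvalues) else numeric(0),
                 r_squared = r2,
                 adj_r_squared = adj_r2(r2, prep$n, fit$rank),
                 total_ss = fit$ss_tot,
                 constrained_ss = fit$ss_fit,
                 rank = fit$rank,
                 n = prep$n,
                 transform = transform,
                 variables = colnames(prep$x),
                 method = "RDA"),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("RDA on", length(x$variables), "variable(s);",
      sprintf("R2 = %.3f (adj %.3f)", x$r_squared, x$adj_r_squared), "\n")
  if (length(x$proportion_explained)) {
    k <- min(2, length(x$proportion_explained))
    cat("Constrained axes:",
        paste0("RDA", seq_len(k), " ",
               sprintf("%.2f%%", 100 * x$proportion_explained[seq_len(k)]),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn rda_fit Site scores as a tibble.
#' @param x An `rda_fit` object.
#' @param ... Unused.
#' @method tidy rda_fit
#' @export
tidy.rda_fit <- function(x, ...) {
  as_tibble(x$scores) |> mutate(sample = rownames(x$scores), .before = 1)
}

#' @describeIn rda_fit One-row fit summary.
#' @method glance rda_fit
#' @export
glance.rda_fit <- function(x, ...) {
  pe <- x$proportion_explained
  tibble(n_samples = x$n, n_variables = length(x$variables), rank = x$rank,
         r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         prop_rda1 = if (length(pe)) pe[1] else NA_real_,
         prop_rda2 = if (length(pe) > 1) pe[2] else NA_real_)
}

#' Monte Carlo permutation test for RDA
#'
#' Recomputes the pseudo-F statistic
#' `F = (SS_fit / m) / (SS_res / (n - m - 1))` after permuting the rows of
#' the environment matrix uniformly at random `n_perm` times; the p-value
#' is `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @inheritParams rda_fit
#' @param vars Optional character vector restricting `env` to a variable
#'   subset.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; recorded in the result.
#' @return A `perm_test` object: `statistic`, `p_value`, `n_perm`, `seed`,
#'   `r_squared`, `variables`.
#' @export
permutation_test <- function(species, env, vars = NULL, n_perm = 999,
                             seed = NULL, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  if (n_perm < 1) abort("n_perm must be >= 1.")
  if (!is.null(vars)) env <- env[, vars, drop = FALSE]
  prep <- rda_prepare(species, env, transform)
  obs <- rda_core(prep$y, prep$x)
  f_obs <- pseudo_f(obs, prep$n)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    xp <- prep$x[sample.int(prep$n), , drop = FALSE]
    f_b <- pseudo_f(rda_core(prep$y, xp), prep$n)
    if (f_b >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(statistic = f_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, seed = seed,
                 r_squared = obs$ss_fit / obs$ss_tot,
                 variables = colnames(prep$x)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " permutations): pseudo-F = ",
      sprintf("%.3f", x$statistic), ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' @describeIn permutation_test One-row summary of the test.
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_perm = x$n_perm,
         r_squared = x$r_squared,
         variables = paste(x$variables, collapse = "+"))
}

#' Greedy forward selection of environmental variables
#'
#' At each step the candidate adding the largest R2 to the current model is
#' tested by a Monte Carlo permutation test of its conditional
#' contribution (permuting the candidate's values while the selected
#' variables stay fixed); it is admitted while its p-value is at most
#' `alpha`, and selection stops at the first rejection.
#'
#' @inheritParams permutation_test
#' @param alpha Admission threshold on the permutation p-value.
#' @return Tibble of selected variables in order: `variable`, `r2_added`,
#'   `cum_r2`, `p_value`.
#' @export
forward_select <- function(species, env, alpha = 0.05, n_perm = 199,
                           seed = NULL, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  if (ncol(env) < 1) abort("forward_select() needs at least one candidate variable.")
  if (!is.null(seed)) set.seed(seed)
  prep <- rda_prepare(species, env, transform)
  n <- prep$n
  selected <- character(0)
  rows <- list()
  r2_cur <- 0
  repeat {
    candidates <- setdiff(colnames(prep$x), selected)
    if (!length(candidates)) break
    r2_with <- vapply(candidates, function(v) {
      fit <- rda_core(prep$y, prep$x[, c(selected, v), drop = FALSE])
      fit$ss_fit / fit$ss_tot
    }, numeric(1))
    best <- candidates[which.max(r2_with)]
    r2_new <- max(r2_with)
    # conditional permutation test of the added term
    m_full <- length(selected) + 1L
    f_obs <- cond_f(r2_new, r2_cur, n, m_full)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      xb <- prep$x[, c(selected, best), drop = FALSE]
      xb[, m_full] <- xb[sample.int(n), m_full]
      fit_b <- rda_core(prep$y, xb)
      r2_b <- fit_b$ss_fit / fit_b$ss_tot
      f_b <- cond_f(r2_b, r2_cur, n, m_full)
      if (f_b >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    if (p > alpha) break
    rows[[best]] <- tibble(variable = best, r2_added = r2_new - r2_cur,
                           cum_r2 = r2_new, p_value = p)
    selected <- c(selected, best)
    r2_cur <- r2_new
    if (length(selected) >= n - 2) break  # residual df exhausted
  }
  bind_rows(rows)
}

#' Variance partitioning analysis (VPA)
#'
#' Partitions the community variance explained by 2-4 non-overlapping
#' groups of environmental variables into unique and shared fractions on
#' the adjusted-R2 scale (Ezekiel correction), via RDA of every union of
#' groups and inclusion-exclusion. Shared fractions can be slightly
#' negative — an adjusted-R2 artifact — and are reported as-is. Unique,
#' shared and residual fractions sum to 1 exactly.
#'
#' @inheritParams rda_fit
#' @param env_groups Named list of character vectors: which `env` columns
#'   form each group. Groups must not overlap.
#' @return A `vpa_result` object with a `fractions` tibble (`fraction`,
#'   `groups`, `adj_r2`) including the residual row.
#' @export
vpa <- function(species, env, env_groups,
                transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  k <- length(env_groups)
  if (k < 2 || k > 4) abort("vpa() needs 2 to 4 predictor groups.")
  if (is.null(names(env_groups)) || any(!nzchar(names(env_groups)))) {
    abort("env_groups must be a named list.")
  }
  cols <- unlist(env_groups)
  if (anyDuplicated(cols)) {
    abort(paste0("Overlapping group column(s): ",
                 paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  }
  missing_cols <- setdiff(cols, names(env))
  if (length(missing_cols)) {
    abort(paste0("Group column(s) not in env: ",
                 paste(missing_cols, collapse = ", ")))
  }
  gnames <- names(env_groups)
  subsets <- make_subsets(k)
  r_union <- vapply(subsets, function(s) {
    vars <- unlist(env_groups[s])
    fit <- rda_fit(species, env[, vars, drop = FALSE], transform = transform)
    fit$adj_r_squared
  }, numeric(1))
  # solve R(S) = sum over atoms T with T intersecting S
  nm <- length(subsets)
  amat <- matrix(0, nm, nm)
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (length(intersect(subsets[[i]], subsets[[j]]))) amat[i, j] <- 1
  }
  atoms <- solve(amat, r_union)
  frac <- tibble(
    fraction = vapply(subsets, function(s) {
      if (length(s) == 1) paste0("unique_", gnames[s])
      else paste0("shared_", paste(gnames[s], collapse = "_"))
    }, character(1)),
    groups = vapply(subsets, function(s) paste(gnames[s], collapse = "+"),
                    character(1)),
    adj_r2 = atoms)
  total <- r_union[[nm]]  # all groups = last subset
  frac <- bind_rows(frac, tibble(fraction = "residual", groups = "",
                                 adj_r2 = 1 - total))
  structure(list(fractions = frac, total_adj_r2 = total,
                 group_names = gnames), class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variance partitioning over groups:",
      paste(x$group_names, collapse = ", "),
      sprintf("| total adj-R2 = %.3f\n", x$total_adj_r2))
  print(x$fractions)
  invisible(x)
}

#' @describeIn vpa Fractions table.
#' @param x A `vpa_result` object.
#' @param ... Unused.
#' @method tidy vpa_result
#' @export
tidy.vpa_result <- function(x, ...) x$fractions

# ---- internals -------------------------------------------------------------

# Species transform + centring, env standardization + collinearity check.
rda_prepare <- function(species, env, transform) {
  y <- if (inherits(species, "otu_tbl")) t(otu_counts(species)) else as.matrix(species)
  env <- as.data.frame(env)
  if (nrow(env) != nrow(y)) {
    abort("species and env must have the same number of rows (samples).")
  }
  bad <- names(env)[!vapply(env, is.numeric, logical(1))]
  if (length(bad)) abort(paste0("Non-numeric env column(s): ",
                                paste(bad, collapse = ", ")))
  if (transform == "hellinger") {
    rs <- rowSums(y)
    if (any(rs <= 0)) abort("Hellinger transform needs positive sample totals.")
    y <- vegan::decostand(y, method = "hellinger")
  }
  y <- scale(y, center = TRUE, scale = FALSE)
  sds <- vapply(env, sd, numeric(1))
  const <- names(env)[sds == 0 | !is.finite(sds)]
  if (length(const)) abort(paste0("Constant env column(s): ",
                                  paste(const, collapse = ", ")))
  x <- scale(as.matrix(env))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dep <- colnames(x)[setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])]
    abort(paste0("Collinear env column(s): ", paste(dep, collapse = ", ")))
  }
  labels <- rownames(y) %||% env_rownames(env) %||% paste0("sample_", seq_len(nrow(y)))
  list(y = y, x = x, n = nrow(y), labels = labels)
}

env_rownames <- function(env) {
  rn <- rownames(env)
  if (is.null(rn) || identical(rn, as.character(seq_len(nrow(env))))) NULL else rn
}

# Least-squares projection of centred y on x; returns fitted values and SS.
rda_core <- function(y, x) {
  qx <- qr(x)
  fitted <- qr.fitted(qx, y)
  list(fitted = fitted,
       ss_fit = sum(fitted^2),
       ss_tot = sum(y^2),
       rank = qx$rank)
}

pseudo_f <- function(fit, n) {
  m <- fit$rank
  df_res <- n - m - 1
  if (df_res <= 0) abort("Not enough residual degrees of freedom for pseudo-F.")
  (fit$ss_fit / m) / ((fit$ss_tot - fit$ss_fit) / df_res)
}

# F for adding one term on top of a model with r2_cur (m_full terms total)
cond_f <- function(r2_full, r2_red, n, m_full) {
  df_res <- n - m_full - 1
  (r2_full - r2_red) / ((1 - r2_full) / df_res)
}

# Ezekiel adjusted R2
adj_r2 <- function(r2, n, m) {
  if (n - m - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

make_subsets <- function(k) {
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
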