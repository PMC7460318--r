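# Alpha diversity on count vectors: richness, Chao1, Shannon entropy,
# Gini-Simpson, and exact (hypergeometric) rarefaction curves.

#' Observed species richness
#' @param counts Non-negative count vector.
#' @return Number of taxa with count > 0.
#' @export
observed_species <- function(counts) {
  check_counts(counts)
  if (all(counts == 0)) {
    warn("All counts are zero; observed richness is 0.")
    return(0L)
  }
  sum(counts > 0)
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1 the number of singletons
#' and F2 the number of doubletons. The bias-corrected form stays defined
#' when no doubletons are present and never falls below the observed
#' richness.
#'
#' @param counts Integer count vector.
#' @return Estimated richness.
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort("chao1() needs integer counts.")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity
#'
#' `-sum p_i log_base(p_i)` over positive proportions. Default base 2,
#' following the convention of early 16S pipelines; natural log available
#' via `base = exp(1)`.
#'
#' @param counts Count (or abundance) vector with at least one positive entry.
#' @param base Logarithm base.
#' @return Entropy in the configured base.
#' @export
shannon <- function(counts, base = 2) {
  check_counts(counts)
  if (all(counts == 0)) abort("shannon() needs at least one positive count.")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity
#'
#' `1 - sum p_i^2`: the probability that two randomly drawn individuals
#' belong to different taxa. Low values flag poor evenness.
#'
#' @param counts Count (or abundance) vector with at least one positive entry.
#' @return Value in `[0, 1)`.
#' @export
simpson <- function(counts) {
  check_counts(counts)
  if (all(counts == 0)) abort("simpson() needs at least one positive count.")
  p <- counts[counts > 0] / sum(counts)
  1 - sum(p^2)
}

#' Per-sample alpha diversity table
#'
#' @param x An `otu_tbl` or taxa-by-samples count matrix.
#' @param base Shannon logarithm base.
#' @return Tibble: sample, observed_species, chao1, shannon, simpson.
#' @export
alpha_diversity <- function(x, base = 2) {
  m <- if (inherits(x, "otu_tbl")) otu_counts(x) else as.matrix(x)
  tibble(sample = colnames(m),
         observed_species = unname(apply(m, 2, observed_species)),
         chao1 = unname(apply(m, 2, chao1)),
         shannon = unname(apply(m, 2, shannon, base = base)),
         simpson = unname(apply(m, 2, simpson)))
}

#' Exact rarefaction ("dilution") curve
#'
#' Expected number of taxa observed in a without-replacement subsample of
#' each depth, computed from the hypergeometric expectation
#' (via [vegan::rarefy()]) rather than repeated subsampling, so curves are
#' deterministic. Monotone non-decreasing and concave in depth; equals the
#' observed richness at full depth.
#'
#' @param x An `otu_tbl`, taxa-by-samples count matrix, or a single count
#'   vector.
#' @param depths Subsample sizes; default 20 depths spanning 1 to each
#'   sample's total. Depths above a sample's total are an error.
#' @return Tibble: sample, depth, expected_species.
#' @export
rarefaction_curve <- function(x, depths = NULL) {
  m <- if (inherits(x, "otu_tbl")) otu_counts(x)
       else if (is.matrix(x)) x
       else matrix(x, ncol = 1, dimnames = list(NULL, "sample_1"))
  purrr::map(colnames(m), function(s) {
    counts <- m[, s]
    total <- sum(counts)
    d <- depths %||% unique(pmax(1, round(seq(1, total, length.out = 20))))
    if (any(d > total)) {
      abort(paste0("Depth exceeds total count (", total, ") for sample '", s, "'."))
    }
    if (any(d < 1)) abort("Depths must be >= 1.")
    # vegan warns when a sample has no singletons; irrelevant for the
    # hypergeometric expectation, so muffle that advisory only
    exp_s <- withCallingHandlers(
      as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = d)),
      warning = function(w) {
        if (grepl("observed count data", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    tibble(sample = s, depth = d, expected_species = exp_s)
  }) |> bind_rows()
}

check_counts <- function(counts) {
  if (length(counts) == 0) abort("Empty count vector.")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("Counts must be finite and non-negative.")
  }
  invisible(TRUE)
}
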