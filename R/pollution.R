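# Hakanson and Nemerow pollution scoring.
#
# For metal i at a site: Cf_i = Cs_i / Cn_i (measured over background),
# Er_i = Tr_i * Cf_i (toxicity-weighted risk), RI = sum_i Er_i, and
# PN = sqrt((max(Cf)^2 + mean(Cf)^2) / 2). PN is pinned between mean(Cf)
# and max(Cf), making it sensitive to the single worst pollutant; RI adds
# toxicity weighting so Cd dominates even at modest enrichment.

#' Contamination factor Cf = Cs / Cn
#'
#' @param cs Measured concentration(s), mg/kg.
#' @param cn Regional background concentration(s), mg/kg.
#' @return `cs / cn`, dimensionless.
#' @examples
#' contamination_factor(10, 4)  # 2.5
#' @export
contamination_factor <- function(cs, cn) {
  if (any(!is.finite(cs)) || any(cs <= 0)) abort("Concentrations cs must be finite and > 0.")
  if (any(!is.finite(cn)) || any(cn <= 0)) abort("Backgrounds cn must be finite and > 0.")
  cs / cn
}

#' Ecological risk of a single metal, Er = Tr * Cf
#'
#' @param cf Contamination factor(s).
#' @param tr Toxic-response factor(s).
#' @return `tr * cf`, dimensionless.
#' @export
ecological_risk <- function(cf, tr) {
  if (any(!is.finite(cf)) || any(cf <= 0)) abort("Contamination factors must be finite and > 0.")
  if (any(!is.finite(tr)) || any(tr <= 0)) abort("Toxic-response factors must be finite and > 0.")
  tr * cf
}

#' Nemerow comprehensive pollution index
#'
#' `PN = sqrt((max(Cf)^2 + mean(Cf)^2) / 2)` over the contamination factors
#' of one site. Always satisfies `mean(Cf) <= PN <= max(Cf)`.
#'
#' @param cf Vector of contamination factors for one site.
#' @return The PN value.
#' @examples
#' nemerow_index(c(4, 2))  # sqrt(12.5) ~ 3.536
#' @export
nemerow_index <- function(cf) {
  if (length(cf) == 0) abort("nemerow_index() needs at least one contamination factor.")
  if (any(!is.finite(cf)) || any(cf <= 0)) abort("Contamination factors must be finite and > 0.")
  sqrt((max(cf)^2 + mean(cf)^2) / 2)
}

#' Potential ecological risk index RI per site
#'
#' `RI = sum_i Tr_i * Cs_i / Cn_i` over all measured metals.
#'
#' @param panel A [metal_panel()].
#' @param ref A [background_ref()] covering every metal in the panel.
#' @return Tibble with columns `site` and `ri` (one row per panel row; a
#'   `sample` column is carried through when present).
#' @export
risk_index <- function(panel, ref) {
  metals <- panel_metals(panel)
  check_coverage(metals, ref)
  cn <- setNames(ref$cn, ref$metal)[metals]
  tr <- setNames(ref$tr, ref$metal)[metals]
  conc <- as.matrix(panel[metals])
  cf <- sweep(conc, 2, cn, "/")
  ri <- drop(sweep(cf, 2, tr, "*") %*% rep(1, length(metals)))
  out <- tibble(site = panel$site, ri = ri)
  if ("sample" %in% names(panel)) out <- tibble(site = panel$site, sample = panel$sample, ri = ri)
  out
}

#' Grade a Nemerow index value
#'
#' Thresholds: clean (PN <= 0.7), warning (<= 1), light (<= 2),
#' moderate (<= 3), heavy (> 3).
#'
#' @param pn Numeric PN value(s).
#' @return Character grade(s).
#' @export
classify_pn <- function(pn) {
  if (any(!is.finite(pn)) || any(pn < 0)) abort("PN must be finite and >= 0.")
  cut(pn, c(-Inf, 0.7, 1, 2, 3, Inf),
      labels = c("clean", "warning", "light", "moderate", "heavy"),
      right = TRUE) |> as.character()
}

#' Grade a potential ecological risk index value
#'
#' Thresholds: low (RI < 150), moderate (< 300), strong (< 600),
#' very strong (>= 600).
#'
#' @param ri Numeric RI value(s).
#' @return Character grade(s).
#' @export
classify_ri <- function(ri) {
  if (any(!is.finite(ri)) || any(ri < 0)) abort("RI must be finite and >= 0.")
  cut(ri, c(-Inf, 150, 300, 600, Inf),
      labels = c("low", "moderate", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Full pollution assessment of a metal panel
#'
#' Computes per-metal contamination factors and ecological risks, per-site
#' RI and PN, grade labels, and site rankings. With a replicate-level panel
#' (repeated sites), `mode` controls aggregation: `"mean_conc"` averages
#' concentrations per site before scoring; `"per_replicate"` scores every
#' replicate and reports the per-site mean with its standard deviation.
#'
#' @param panel A [metal_panel()].
#' @param ref A [background_ref()].
#' @param mode Aggregation mode for replicate panels; ignored when sites are
#'   unique.
#' @return A `pollution_scores` object: list with `cf` (long tibble:
#'   site, metal, cs, cn, cf, tr, er), `site` (tibble: site, ri, pn,
#'   optional `ri_sd`/`pn_sd`, grades and ranks), and `mode`.
#' @export
assess_pollution <- function(panel, ref,
                             mode = c("mean_conc", "per_replicate")) {
  mode <- match.arg(mode)
  metals <- panel_metals(panel)
  check_coverage(metals, ref)
  replicated <- anyDuplicated(panel$site) > 0

  score_panel <- function(p) {
    conc <- as.matrix(p[metals])
    cn_v <- setNames(ref$cn, ref$metal)[metals]
    tr_v <- setNames(ref$tr, ref$metal)[metals]
    cf <- sweep(conc, 2, cn_v, "/")
    er <- sweep(cf, 2, tr_v, "*")
    long <- tidyr::expand_grid(site = p$site, metal = metals) |>
      mutate(cs = as.vector(t(conc)),
             cn = rep(unname(cn_v), nrow(p)),
             cf = as.vector(t(cf)),
             tr = rep(unname(tr_v), nrow(p)),
             er = as.vector(t(er)))
    per_site <- tibble(site = p$site,
                       ri = rowSums(er),
                       pn = apply(cf, 1, nemerow_index))
    list(long = long, per_site = per_site)
  }

  if (replicated && mode == "mean_conc") {
    agg <- as_tibble(panel) |>
      group_by(.data$site) |>
      summarise(across(dplyr::all_of(metals), mean), .groups = "drop")
    sc <- score_panel(agg)
    site <- sc$per_site
  } else if (replicated) {
    sc <- score_panel(as_tibble(panel))
    site <- sc$per_site |>
      group_by(.data$site) |>
      summarise(ri_sd = sd(.data$ri), pn_sd = sd(.data$pn),
                ri = mean(.data$ri), pn = mean(.data$pn), .groups = "drop") |>
      select("site", "ri", "ri_sd", "pn", "pn_sd")
    sc$long <- sc$long |>
      group_by(.data$site, .data$metal) |>
      summarise(across(c("cs", "cn", "cf", "tr", "er"), mean), .groups = "drop")
  } else {
    sc <- score_panel(as_tibble(panel))
    site <- sc$per_site
  }

  site <- site |>
    mutate(pn_grade = classify_pn(.data$pn),
           ri_grade = classify_ri(.data$ri),
           rank_pn = rank(-.data$pn, ties.method = "min"),
           rank_ri = rank(-.data$ri, ties.method = "min"))
  structure(list(cf = sc$long, site = site, mode = mode,
                 metals = metals), class = "pollution_scores")
}

#' @export
print.pollution_scores <- function(x, ...) {
  cat("Pollution assessment (", x$mode, ") over metals: ",
      paste(x$metals, collapse = ", "), "\n", sep = "")
  print(x$site |> arrange(.data$rank_pn))
  invisible(x)
}

#' @describeIn assess_pollution Long per-site, per-metal table of Cf and Er.
#' @param x A `pollution_scores` object.
#' @param ... Unused.
#' @method tidy pollution_scores
#' @export
tidy.pollution_scores <- function(x, ...) x$cf

#' @describeIn assess_pollution One-row summary: site/metal counts, the most
#'   polluted site and its PN and RI.
#' @method glance pollution_scores
#' @export
glance.pollution_scores <- function(x, ...) {
  top <- x$site |> arrange(desc(.data$pn)) |> head(1)
  tibble(n_sites = nrow(x$site), n_metals = length(x$metals),
         top_site = top$site, max_pn = top$pn,
         max_ri = max(x$site$ri), mode = x$mode)
}

#' Per-site pollution score table
#' @param x A `pollution_scores` object.
#' @return Tibble of per-site RI, PN, grades and ranks.
#' @export
pollution_sites <- function(x) x$site

check_coverage <- function(metals, ref) {
  if (!inherits(ref, "background_ref")) ref <- background_ref(ref)
  missing <- setdiff(metals, ref$metal)
  if (length(missing)) {
    abort(paste0("No background entry for metal(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Hakanson toxic-response defaults and example backgrounds
#'
#' Returns a [background_ref()] with the conventional Hakanson
#' toxic-response factors (Cu = Pb = Ni = 5, Zn = 1, Cd = 30) and
#' literature-plausible background concentrations for copper-mining soils
#' of the lower Yangtze region. Backgrounds are region-specific: supply
#' your own `cn` for real assessments.
#'
#' @param metals Subset of metals to include.
#' @return A `background_ref` tibble.
#' @export
default_background <- function(metals = c("Cu", "Zn", "Pb", "Cd", "Ni")) {
  full <- tibble(metal = c("Cu", "Zn", "Pb", "Cd", "Ni"),
                 cn = c(24.4, 66.5, 26.2, 0.186, 29.8),
                 tr = c(5, 1, 5, 30, 5))
  background_ref(full[match(metals, full$metal), ])
}
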