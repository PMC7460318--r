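# Seeded synthetic scenario generator.
#
# Emulates the sampling design the pipeline targets: seven sites on the two
# banks of a river draining a mining area (four on the mine-side left bank,
# three on the right), three composite samples per site, with
#   * metal concentrations decaying exponentially with distance from the
#     mine plus a left-bank penalty, under lognormal measurement noise:
#       conc = cn * (1 + A * exp(-distance / lambda) + penalty * [left]) * e^N(0, sd)
#   * physicochemical covariates (pH, MC, TOC, TN, TP, AK) drawn per
#     vegetation class (abandoned / vegetable / paddy),
#   * taxon abundances from a log-linear response to standardized pH and
#     the true Nemerow index, sampled as a Dirichlet-multinomial at the
#     configured sequencing depth.
# Ground truth (noise-free PN/RI, decay and response coefficients) rides
# along so every downstream stage can be scored for recovery.

#' Configuration of a synthetic river-bank scenario
#'
#' Defaults describe the emulated study design: seven sites, S1-S4 on the
#' left (mine-side) bank at 100-1200 m from the mine, S5-S7 on the right
#' bank, the farthest site a low-disturbance reference; abandoned land
#' nearest the mine, vegetable fields near the settlements, paddy fields
#' elsewhere; three composite samples per site. Site spacing is chosen so
#' that expected pollution indices of neighbouring sites differ by more
#' than replicate-level measurement noise, keeping site rankings
#' identifiable at the default noise level.
#'
#' @param sites Site identifiers.
#' @param distance_m Distance of each site from the mine, metres.
#' @param bank `"left"` or `"right"` per site.
#' @param vegetation `"abandoned"`, `"vegetable"` or `"paddy"` per site.
#' @param n_replicates Composite samples per site.
#' @param background A [background_ref()] giving cn and tr per metal.
#' @param decay_amplitude Named per-metal amplitude `A` of the exponential
#'   enrichment at distance 0 (in background units).
#' @param decay_lambda e-folding distance of the enrichment, metres.
#' @param bank_penalty Extra enrichment (background units) on the left bank.
#' @param noise_sd Standard deviation of the lognormal measurement noise on
#'   concentrations (0 = noise-free).
#' @param env_class_means,env_class_sd Named list per vegetation class of
#'   mean (and sd) for pH, MC (%), TOC (g/kg), TN (mg/kg), TP (mg/kg),
#'   AK (mg/kg).
#' @param n_taxa Number of taxa to simulate.
#' @param depth Sequencing depth per sample (reads).
#' @param effect_ph,effect_pn Standard deviation of the per-taxon log-linear
#'   response coefficients to standardized pH and true PN.
#' @param theta Dirichlet concentration (overdispersion: smaller = noisier;
#'   `Inf` = plain multinomial).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(
    sites = paste0("S", 1:7),
    distance_m = c(100, 300, 600, 1200, 400, 900, 2000),
    bank = c("left", "left", "left", "left", "right", "right", "right"),
    vegetation = c("abandoned", "vegetable", "paddy", "paddy",
                   "vegetable", "paddy", "paddy"),
    n_replicates = 3,
    background = default_background(),
    decay_amplitude = c(Cu = 10, Zn = 3.5, Pb = 2.5, Cd = 14, Ni = 1.2),
    decay_lambda = 600,
    bank_penalty = 0.4,
    noise_sd = 0.15,
    env_class_means = list(
      abandoned = c(pH = 6.2, MC = 15, TOC = 3.7, TN = 980, TP = 800, AK = 53),
      vegetable = c(pH = 7.4, MC = 18, TOC = 10, TN = 1400, TP = 370, AK = 120),
      paddy     = c(pH = 6.2, MC = 28, TOC = 14, TN = 2000, TP = 370, AK = 140)),
    env_class_sd = list(
      abandoned = c(pH = 0.10, MC = 2, TOC = 0.5, TN = 100, TP = 80, AK = 8),
      vegetable = c(pH = 0.30, MC = 2, TOC = 1.5, TN = 200, TP = 70, AK = 20),
      paddy     = c(pH = 0.15, MC = 3, TOC = 2.0, TN = 300, TP = 70, AK = 25)),
    n_taxa = 120,
    depth = 20000,
    effect_ph = 0.8,
    effect_pn = 0.5,
    theta = 200) {
  stopifnot(length(distance_m) == length(sites),
            length(bank) == length(sites),
            length(vegetation) == length(sites))
  if (depth < 1) abort("depth must be >= 1.")
  if (!all(bank %in% c("left", "right"))) abort("bank must be 'left' or 'right'.")
  if (!all(vegetation %in% names(env_class_means))) {
    abort("Every vegetation class needs an entry in env_class_means.")
  }
  metals <- background$metal
  if (!all(metals %in% names(decay_amplitude))) {
    abort("decay_amplitude must cover every background metal.")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a synthetic scenario
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; recorded in the result and its manifest.
#' @return A `synthetic_scenario`: list with `panel` ([metal_panel()],
#'   replicate-level), `background`, `env` (tibble, one row per composite
#'   sample), `otu` (`otu_tbl` with phylum-bearing lineages), and `truth`
#'   (noise-free per-site concentrations, PN/RI, decay parameters, taxon
#'   response coefficients, expected per-sample proportions, seed).
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  cfg <- config
  metals <- cfg$background$metal
  n_site <- length(cfg$sites)
  reps <- cfg$n_replicates

  # --- metals: expected enrichment, then lognormal noise per replicate
  enrich <- vapply(metals, function(m) {
    1 + cfg$decay_amplitude[[m]] * exp(-cfg$distance_m / cfg$decay_lambda) +
      cfg$bank_penalty * (cfg$bank == "left")
  }, numeric(n_site))  # site x metal
  cn <- setNames(cfg$background$cn, metals)
  expected_conc <- sweep(enrich, 2, cn[metals], "*")
  rownames(expected_conc) <- cfg$sites

  sample_ids <- as.vector(t(outer(cfg$sites, seq_len(reps), paste, sep = "-")))
  site_of <- rep(cfg$sites, each = reps)
  noise <- matrix(rlnorm(length(sample_ids) * length(metals),
                         meanlog = 0, sdlog = cfg$noise_sd),
                  nrow = length(sample_ids))
  conc <- expected_conc[site_of, , drop = FALSE] * noise
  panel <- metal_panel(as_tibble(cbind(
    tibble(site = site_of, sample = sample_ids),
    as_tibble(conc, .name_repair = "minimal"))))

  # --- ground-truth indices from the noise-free concentrations
  tr <- setNames(cfg$background$tr, metals)
  cf_true <- sweep(expected_conc, 2, cn[metals], "/")
  pn_true <- apply(cf_true, 1, nemerow_index)
  ri_true <- drop(sweep(cf_true, 2, tr[metals], "*") %*% rep(1, length(metals)))

  # --- environment covariates per vegetation class
  env_vars <- names(cfg$env_class_means[[1]])
  env_draw <- vapply(seq_along(sample_ids), function(i) {
    cls <- cfg$vegetation[match(site_of[i], cfg$sites)]
    mu <- cfg$env_class_means[[cls]]
    sdv <- cfg$env_class_sd[[cls]]
    pmax(rnorm(length(mu), mu, sdv), 0.01)
  }, numeric(length(env_vars)))
  env <- tibble(sample = sample_ids, site = site_of,
                bank = cfg$bank[match(site_of, cfg$sites)],
                vegetation = cfg$vegetation[match(site_of, cfg$sites)]) |>
    dplyr::bind_cols(as_tibble(t(env_draw), .name_repair = ~env_vars)) |>
    mutate(PN = pn_true[.data$site], RI = ri_true[.data$site])

  # --- community: log-linear taxon response to standardized pH and true PN
  phyla <- c("Proteobacteria", "Acidobacteria", "Chloroflexi", "Bacteroidetes",
             "Verrucomicrobia", "Planctomycetes", "Gemmatimonadetes",
             "Actinobacteria", "Nitrospirae", "Patescibacteria",
             "Thaumarchaeota", "Crenarchaeota")
  domain_of <- c(rep("Bacteria", 10), rep("Archaea", 2))
  taxon_phylum <- sample(seq_along(phyla), cfg$n_taxa, replace = TRUE,
                         prob = c(rep(1, 10), 0.4, 0.4))
  base_log <- rnorm(cfg$n_taxa, mean = 0, sd = 1.2)
  beta_ph <- rnorm(cfg$n_taxa, 0, cfg$effect_ph)
  beta_pn <- rnorm(cfg$n_taxa, 0, cfg$effect_pn)
  z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  z_ph <- z(env$pH)
  z_pn <- z(env$PN)
  expected_props <- vapply(seq_along(sample_ids), function(i) {
    lp <- base_log + beta_ph * z_ph[i] + beta_pn * z_pn[i]
    w <- exp(lp - max(lp))
    w / sum(w)
  }, numeric(cfg$n_taxa))  # taxa x samples

  counts <- vapply(seq_along(sample_ids), function(i) {
    p <- expected_props[, i]
    if (is.finite(cfg$theta)) {
      g <- rgamma(length(p), shape = cfg$theta * p, rate = 1)
      if (sum(g) <= 0) g <- p
      p <- g / sum(g)
    }
    drop(rmultinom(1, size = cfg$depth, prob = p))
  }, integer(cfg$n_taxa))
  colnames(counts) <- sample_ids
  lineages <- paste0("k__", domain_of[taxon_phylum],
                     ";p__", phyla[taxon_phylum])
  otu <- as_otu_tbl(dplyr::bind_cols(
    tibble(otu_id = sprintf("OTU_%04d", seq_len(cfg$n_taxa)),
           lineage = lineages),
    as_tibble(counts, .name_repair = "minimal")))

  structure(list(
    panel = panel, background = cfg$background, env = env, otu = otu,
    truth = list(seed = seed,
                 expected_conc = expected_conc,
                 cf_true = cf_true,
                 pn_true = pn_true, ri_true = ri_true,
                 decay_amplitude = cfg$decay_amplitude,
                 decay_lambda = cfg$decay_lambda,
                 bank_penalty = cfg$bank_penalty,
                 beta_ph = beta_ph, beta_pn = beta_pn,
                 taxon_phylum = phyla[taxon_phylum],
                 expected_props = expected_props),
    config = cfg), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario:", length(x$config$sites), "sites x",
      x$config$n_replicates, "replicates,", x$config$n_taxa, "taxa, depth",
      x$config$depth, "(seed", paste0(x$truth$seed, ")"), "\n")
  invisible(x)
}

#' Write a synthetic scenario to disk
#'
#' Emits exactly the formats the readers consume: `metals.csv`,
#' `background.csv`, `env.csv`, a classic `otu_table.tsv` with a taxonomy
#' column, and a `truth.json` manifest carrying the seed, a digest of the
#' configuration, and the ground-truth record.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) abort(paste0("Cannot write to '", dir, "'."))
  write_metal_table(scenario$panel, file.path(dir, "metals.csv"))
  write_background_table(scenario$background, file.path(dir, "background.csv"))
  write_env_table(scenario$env, file.path(dir, "env.csv"))
  write_otu_table(scenario$otu, file.path(dir, "otu_table.tsv"))
  cfg <- scenario$config
  cfg_plain <- lapply(unclass(cfg), function(v) if (is.data.frame(v)) as.list(v) else v)
  manifest <- list(
    seed = scenario$truth$seed,
    config_hash = rlang::hash(cfg_plain),
    truth = list(
      sites = cfg$sites,
      pn_true = unname(scenario$truth$pn_true),
      ri_true = unname(scenario$truth$ri_true),
      decay_amplitude = as.list(scenario$truth$decay_amplitude),
      decay_lambda = scenario$truth$decay_lambda,
      bank_penalty = scenario$truth$bank_penalty,
      beta_ph = scenario$truth$beta_ph,
      beta_pn = scenario$truth$beta_pn))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
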