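# Stage orchestration: one entry point that chains the analysis in the
# order a survey would report it — pollution scoring, alpha diversity and
# rarefaction, beta diversity and ordination, constrained ordination with
# permutation tests and variance partitioning, and correlation tables —
# writing plain-text TSV/CSV/JSON artifacts plus a manifest per run.
# A thin command-line wrapper over this function is installed at
# `system.file("scripts", "run_pipeline.R", package = "minemicro")`.

#' Run the analysis pipeline
#'
#' Stages: `"simulate"` (generate and write a synthetic scenario when no
#' input paths are given), `"pollution"`, `"alpha"`, `"beta"`, `"rda"`,
#' `"vpa"`, `"correlate"`, or `"all"`. Each stage writes its outputs under
#' `out_dir` and registers them in `manifest.json` together with the seed
#' and parameters, so a rerun with the same inputs and seed is
#' byte-identical.
#'
#' @param out_dir Output directory.
#' @param stages Character vector of stages, or `"all"`.
#' @param metal_path,background_path,otu_path,env_path Input files; when
#'   all are `NULL` a synthetic scenario is generated into
#'   `out_dir/inputs` (stage `"simulate"`).
#' @param seed Integer seed for every stochastic stage.
#' @param config [scenario_config()] for the simulate stage.
#' @param n_perm Permutations for RDA significance and forward selection.
#' @param abundance_threshold Mean relative-abundance cut before
#'   correlation (default 0.01).
#' @param shannon_base Logarithm base for Shannon diversity.
#' @param collapse_rank Rank at which the community is summarised for
#'   correlation and RDA (default `"phylum"`).
#' @param vpa_groups Named list of env-column groups for the VPA stage;
#'   default groups pH + pollution (`PN`) against nutrient/physical
#'   variables.
#' @param env_vars Environment variables offered to the RDA stage.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         stages = "all",
                         metal_path = NULL, background_path = NULL,
                         otu_path = NULL, env_path = NULL,
                         seed = 1,
                         config = scenario_config(),
                         n_perm = 999,
                         abundance_threshold = 0.01,
                         shannon_base = 2,
                         collapse_rank = "phylum",
                         vpa_groups = NULL,
                         env_vars = c("pH", "MC", "TOC", "TN", "TP", "AK", "PN")) {
  all_stages <- c("simulate", "pollution", "alpha", "beta", "rda", "vpa", "correlate")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) abort(paste0("Unknown stage(s): ", paste(unknown, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(metal = metal_path, background = background_path,
                otu = otu_path, env = env_path)
  simulate_needed <- "simulate" %in% stages ||
    all(vapply(paths, is.null, logical(1)))

  results <- list()
  artifacts <- character(0)
  note <- function(...) artifacts <<- c(artifacts, file.path(out_dir, paste0(...)))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  if (simulate_needed) {
    run_stage("simulate", {
      sc <- generate_scenario(config, seed = seed)
      in_dir <- file.path(out_dir, "inputs")
      write_scenario(sc, in_dir)
      paths <- list(metal = file.path(in_dir, "metals.csv"),
                    background = file.path(in_dir, "background.csv"),
                    otu = file.path(in_dir, "otu_table.tsv"),
                    env = file.path(in_dir, "env.csv"))
      results$scenario <- sc
    })
  }
  for (p in names(paths)) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
      abort(paste0("Missing input for '", p, "': ",
                   paths[[p]] %||% "<not given>"))
    }
  }
  panel <- read_metal_table(paths$metal)
  background <- read_background_table(paths$background)
  otu <- read_otu_table(paths$otu)
  env <- read_env_table(paths$env)

  if ("pollution" %in% stages) {
    run_stage("pollution", {
      scores <- assess_pollution(panel, background)
      readr::write_tsv(tidy(scores), file.path(out_dir, "pollution_cf.tsv"))
      readr::write_tsv(pollution_sites(scores) |> arrange(.data$rank_pn),
                       file.path(out_dir, "pollution_sites.tsv"))
      note("pollution_cf.tsv"); note("pollution_sites.tsv")
      results$pollution <- scores
    })
  }
  if ("alpha" %in% stages) {
    run_stage("alpha", {
      ad <- alpha_diversity(otu, base = shannon_base)
      rc <- rarefaction_curve(otu)
      readr::write_tsv(ad, file.path(out_dir, "alpha_diversity.tsv"))
      readr::write_tsv(rc, file.path(out_dir, "rarefaction.tsv"))
      note("alpha_diversity.tsv"); note("rarefaction.tsv")
      results$alpha <- ad; results$rarefaction <- rc
    })
  }
  if ("beta" %in% stages) {
    run_stage("beta", {
      d <- bray_curtis(otu)
      ord <- pcoa_ord(d)
      dm <- as.matrix(d)
      readr::write_tsv(as_tibble(dm) |> mutate(sample = rownames(dm), .before = 1),
                       file.path(out_dir, "bray_curtis.tsv"))
      readr::write_tsv(tidy(ord), file.path(out_dir, "pcoa_scores.tsv"))
      venn <- shared_otu_sets(otu, setNames(env$site %||% env$sample, env$sample))
      readr::write_tsv(tidy(venn), file.path(out_dir, "venn_counts.tsv"))
      note("bray_curtis.tsv"); note("pcoa_scores.tsv"); note("venn_counts.tsv")
      results$pcoa <- ord; results$venn <- venn
      results$cluster <- similarity_cluster(d)
    })
  }

  needs_community <- any(c("rda", "vpa", "correlate") %in% stages)
  if (needs_community) {
    comm <- collapse_taxa(otu, collapse_rank)
    ra <- relative_abundance(comm)
    env_use <- env[match(colnames(ra), env$sample), , drop = FALSE]
    ev <- intersect(env_vars, names(env_use))
    env_num <- env_numeric(env_use, ev)
  }
  if ("rda" %in% stages) {
    run_stage("rda", {
      fit <- rda_fit(t(ra), env_num)
      sel <- forward_select(t(ra), env_num, n_perm = n_perm, seed = seed)
      pt <- permutation_test(t(ra), env_num, n_perm = n_perm, seed = seed)
      readr::write_tsv(tidy(fit), file.path(out_dir, "rda_scores.tsv"))
      bip <- as_tibble(fit$biplot) |> mutate(variable = rownames(fit$biplot), .before = 1)
      readr::write_tsv(bip, file.path(out_dir, "rda_biplot.tsv"))
      readr::write_tsv(glance(pt), file.path(out_dir, "rda_permutation.tsv"))
      readr::write_tsv(sel, file.path(out_dir, "forward_selection.tsv"))
      note("rda_scores.tsv"); note("rda_biplot.tsv")
      note("rda_permutation.tsv"); note("forward_selection.tsv")
      results$rda <- fit; results$forward <- sel; results$perm <- pt
    })
  }
  if ("vpa" %in% stages) {
    run_stage("vpa", {
      groups <- vpa_groups %||% list(
        ph_pollution = intersect(c("pH", "PN"), names(env_num)),
        nutrients = intersect(c("MC", "TOC", "TN", "TP", "AK"), names(env_num)))
      groups <- groups[vapply(groups, length, integer(1)) > 0]
      part <- vpa(t(ra), env_num, groups)
      readr::write_tsv(tidy(part), file.path(out_dir, "vpa_fractions.tsv"))
      note("vpa_fractions.tsv")
      results$vpa <- part
    })
  }
  if ("correlate" %in% stages) {
    run_stage("correlate", {
      filt <- abundance_filter(ra, abundance_threshold)
      cors <- spearman_matrix(filt, env_num)
      readr::write_tsv(as_tibble(cors), file.path(out_dir, "spearman_taxa_env.tsv"))
      pear <- pearson_matrix(env_num)
      readr::write_tsv(as_tibble(pear), file.path(out_dir, "pearson_env.tsv"))
      ord <- cluster_order(cors)
      readr::write_tsv(tibble(kind = c(rep("row", length(ord$row_order)),
                                       rep("col", length(ord$col_order))),
                              label = c(ord$row_order, ord$col_order)),
                       file.path(out_dir, "heatmap_order.tsv"))
      note("spearman_taxa_env.tsv"); note("pearson_env.tsv"); note("heatmap_order.tsv")
      results$spearman <- cors; results$pearson <- pear
    })
  }

  manifest <- list(
    package = "minemicro",
    version = as.character(packageVersion("minemicro")),
    stages = stages,
    seed = seed,
    parameters = list(n_perm = n_perm,
                      abundance_threshold = abundance_threshold,
                      shannon_base = shannon_base,
                      collapse_rank = collapse_rank),
    inputs = lapply(paths, function(p) {
      # record generated inputs relative to out_dir so reruns are identical
      prefix <- paste0(normalizePath(out_dir, mustWork = FALSE), "/")
      pn <- normalizePath(p, mustWork = FALSE)
      if (startsWith(pn, prefix)) substring(pn, nchar(prefix) + 1) else p
    }),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
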