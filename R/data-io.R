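# Readers, writers and validated tabular containers.
#
# Everything user-facing is a tibble: a metal panel is one row per measured
# sample (site x {Cu, Zn, Pb, Cd, Ni}, mg/kg), an OTU table is one row per
# taxon with one integer column per sample, an environment table is one row
# per sample. Units are carried verbatim (mg/kg, %, g/kg); nothing converts.

#' Validate a metal concentration panel
#'
#' A metal panel holds measured heavy-metal concentrations (mg/kg) with one
#' row per sample. A `site` column is mandatory; an optional `sample` column
#' distinguishes replicate composite samples from the same site (e.g.
#' `S1-1`, `S1-2`). Every other column is taken to be a metal.
#'
#' @param x A data frame with a `site` column, an optional `sample` column,
#'   and one numeric column per metal.
#' @return A `metal_panel` tibble.
#' @examples
#' metal_panel(data.frame(site = c("S1", "S2"), Cu = c(140, 60), Cd = c(2.1, 0.9)))
#' @export
metal_panel <- function(x) {
  x <- as_tibble(x)
  if (!"site" %in% names(x)) {
    abort("A metal panel needs a 'site' column.")
  }
  id_cols <- intersect(c("site", "sample"), names(x))
  metals <- setdiff(names(x), id_cols)
  if (length(metals) == 0) abort("A metal panel needs at least one metal column.")
  if (nrow(x) == 0) abort("A metal panel needs at least one row.")
  key <- if ("sample" %in% names(x)) x$sample else x$site
  if (anyDuplicated(key)) {
    abort(paste0("Duplicated ", if ("sample" %in% names(x)) "sample" else "site",
                 " identifiers: ", paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (anyDuplicated(metals)) abort("Metal names must be unique.")
  for (m in metals) {
    v <- x[[m]]
    if (!is.numeric(v)) {
      abort(paste0("Non-numeric concentration in column '", m, "'."))
    }
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      abort(paste0("Non-positive or missing concentration for metal '", m,
                   "' at site ", paste(x$site[bad], collapse = ", "),
                   " (concentrations must be finite and > 0 mg/kg)."))
    }
  }
  structure(x[c(id_cols, metals)], class = c("metal_panel", class(x)))
}

#' Metal names of a panel
#' @param x A `metal_panel`.
#' @return Character vector of metal column names.
#' @export
panel_metals <- function(x) setdiff(names(x), c("site", "sample"))

#' Read a metal concentration table
#'
#' Comma- or tab-separated, first column the site (or sample) identifier,
#' remaining header cells metal names, cells concentrations in mg/kg.
#'
#' @param path File path.
#' @return A [metal_panel()] tibble.
#' @export
read_metal_table <- function(path) {
  x <- read_delim_auto(path)
  nm1 <- tolower(names(x)[1])
  names(x)[1] <- if (nm1 %in% c("sample", "sample_id")) "sample" else "site"
  if (names(x)[1] == "sample" && !"site" %in% names(x)) {
    # derive site as the prefix before a replicate suffix ("S1-2" -> "S1")
    x$site <- sub("[-_.][^-_.]*$", "", x$sample)
    x <- x[c("site", setdiff(names(x), "site"))]
  }
  metal_panel(x)
}

#' Write a metal panel
#' @param x A `metal_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metal_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Background reference values for pollution indices
#'
#' Per-metal regional background concentration `cn` (mg/kg) and Hakanson
#' toxic-response factor `tr` (dimensionless). Both are inputs, not
#' constants of the package: backgrounds are region-specific and the
#' toxic-response weighting follows the Hakanson convention
#' (Cu = Pb = Ni = 5, Zn = 1, Cd = 30) unless overridden.
#'
#' @param x A data frame with columns `metal`, `cn`, `tr`.
#' @return A `background_ref` tibble.
#' @export
background_ref <- function(x) {
  x <- as_tibble(x)
  need <- c("metal", "cn", "tr")
  if (!all(need %in% names(x))) {
    abort("Background reference needs columns 'metal', 'cn', 'tr'.")
  }
  if (anyDuplicated(x$metal)) abort("Duplicated metal in background reference.")
  if (any(!is.finite(x$cn) | x$cn <= 0)) abort("Background values cn must be finite and > 0.")
  if (any(!is.finite(x$tr) | x$tr <= 0)) abort("Toxic-response factors tr must be finite and > 0.")
  structure(x[need], class = c("background_ref", class(x)))
}

#' Read a background reference table (CSV/TSV with metal, cn, tr columns)
#' @param path File path.
#' @return A [background_ref()] tibble.
#' @export
read_background_table <- function(path) {
  x <- read_delim_auto(path)
  names(x) <- tolower(names(x))
  background_ref(x)
}

#' Write a background reference table
#' @param x A `background_ref`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_background_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Validate an OTU count table
#'
#' One row per OTU: an `otu_id` column, an optional `lineage` column of
#' semicolon-separated, rank-prefixed taxonomy strings
#' (`k__Bacteria;p__Proteobacteria;...`), and one integer count column per
#' sample. Samples whose counts are all zero are dropped with a warning
#' (a common artifact of subsetting), never kept.
#'
#' @param x A data frame as described.
#' @return An `otu_tbl` tibble.
#' @export
as_otu_tbl <- function(x) {
  x <- as_tibble(x)
  if (!"otu_id" %in% names(x)) abort("OTU table needs an 'otu_id' column.")
  if (anyDuplicated(x$otu_id)) {
    abort(paste0("Duplicated OTU IDs: ",
                 paste(unique(x$otu_id[duplicated(x$otu_id)]), collapse = ", ")))
  }
  samples <- setdiff(names(x), c("otu_id", "lineage"))
  if (length(samples) == 0) abort("OTU table needs at least one sample column.")
  if (anyDuplicated(samples)) abort("Duplicated sample names.")
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort(paste0("Counts in sample '", s, "' must be finite, non-negative numbers."))
    }
    r <- round(v)
    if (any(abs(v - r) > 1e-9)) {
      abort(paste0("Non-integer abundance in sample '", s, "'."))
    }
    x[[s]] <- as.integer(r)
  }
  zero <- samples[vapply(samples, function(s) sum(x[[s]]) == 0L, logical(1))]
  if (length(zero)) {
    warn(paste0("Dropping all-zero sample(s): ", paste(zero, collapse = ", ")))
    x <- x[setdiff(names(x), zero)]
    samples <- setdiff(samples, zero)
    if (length(samples) == 0) abort("All samples were all-zero.")
  }
  keep <- c("otu_id", if ("lineage" %in% names(x)) "lineage", samples)
  structure(x[keep], class = c("otu_tbl", class(x)))
}

#' Sample names of an OTU table
#' @param x An `otu_tbl`.
#' @return Character vector of sample column names.
#' @export
otu_samples <- function(x) setdiff(names(x), c("otu_id", "lineage"))

#' Counts of an OTU table as a taxa-by-samples integer matrix
#' @param x An `otu_tbl`.
#' @return Integer matrix with OTU IDs as row names.
#' @export
otu_counts <- function(x) {
  s <- otu_samples(x)
  m <- as.matrix(x[s])
  rownames(m) <- x$otu_id
  m
}

#' Read a classic tab-separated OTU table
#'
#' Accepts the classic dialect whose first header cell is `#OTU ID`, or a
#' plain table whose first column holds the OTU identifiers (assumed
#' taxa-in-rows, with a warning). A trailing `taxonomy` column (any case)
#' becomes the `lineage` field.
#'
#' @param path File path.
#' @return An [as_otu_tbl()] tibble.
#' @export
read_otu_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  classic <- startsWith(first, "#OTU ID")
  x <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                       name_repair = "minimal")
  if (!classic) {
    warn("First header cell is not '#OTU ID'; assuming taxa-in-rows.")
  }
  names(x)[1] <- "otu_id"
  tax <- which(tolower(names(x)) == "taxonomy")
  if (length(tax)) {
    names(x)[tax[1]] <- "lineage"
    x$lineage <- stringr::str_trim(x$lineage)
  }
  as_otu_tbl(x)
}

#' Write an OTU table in the classic dialect
#'
#' Tab-separated, header `#OTU ID`, one column per sample, and a trailing
#' `taxonomy` column when lineages are present.
#'
#' @param x An `otu_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  samples <- otu_samples(x)
  out <- x[c("otu_id", samples)]
  names(out)[1] <- "#OTU ID"
  if ("lineage" %in% names(x)) out$taxonomy <- x$lineage
  readr::write_tsv(out, path)
  invisible(path)
}

# rank prefixes of the QIIME/greengenes lineage convention
.rank_prefixes <- c(domain = "k", phylum = "p", class = "c",
                    order = "o", family = "f", genus = "g")

#' Extract one taxonomic rank from lineage strings
#'
#' @param lineage Character vector of semicolon-separated lineages, with or
#'   without `k__`/`p__`/... prefixes.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Character vector of rank labels; missing or empty assignments
#'   become `"Unassigned"`.
#' @export
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, names(.rank_prefixes))
  prefix <- paste0(.rank_prefixes[[rank]], "__")
  pos <- match(rank, names(.rank_prefixes))
  vapply(lineage, function(lin) {
    if (is.na(lin) || !nzchar(lin)) return("Unassigned")
    parts <- stringr::str_trim(strsplit(lin, ";", fixed = TRUE)[[1]])
    hit <- parts[startsWith(parts, prefix)]
    lab <- if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE)
           else if (!any(grepl("__", parts, fixed = TRUE)) && length(parts) >= pos)
             parts[pos]  # bare lineages: position = rank
           else ""
    if (nzchar(stringr::str_trim(lab))) stringr::str_trim(lab) else "Unassigned"
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Rows are summed within identical rank labels; OTUs whose lineage lacks
#' the rank are pooled under `"Unassigned"`, so per-sample totals are
#' conserved exactly.
#'
#' @param x An `otu_tbl` with lineages.
#' @param rank Taxonomic rank, `"domain"` through `"genus"`.
#' @return An `otu_tbl` whose `otu_id` holds rank labels.
#' @export
collapse_taxa <- function(x, rank) {
  if (!"lineage" %in% names(x)) abort("collapse_taxa() needs a 'lineage' column.")
  rank <- match.arg(rank, names(.rank_prefixes))
  labels <- lineage_rank(x$lineage, rank)
  if (all(labels == "Unassigned")) {
    abort(paste0("Rank '", rank, "' is absent from every lineage."))
  }
  samples <- otu_samples(x)
  out <- as_tibble(x[samples]) |>
    mutate(otu_id = labels) |>
    group_by(.data$otu_id) |>
    summarise(across(dplyr::all_of(samples), sum), .groups = "drop")
  as_otu_tbl(out)
}

#' Relative abundance matrix
#'
#' @param x An `otu_tbl` or a taxa-by-samples count matrix.
#' @return A taxa-by-samples matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_tbl")) otu_counts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  sweep(m, 2, tot, "/")
}

#' Read a sample environment table
#'
#' CSV/TSV with a `sample` (or first) column of sample identifiers, numeric
#' physicochemical columns (pH, MC, TOC, TN, TP, AK, appended indices such
#' as PN or RI), and optional categorical columns (`site`, `bank`,
#' `vegetation`).
#'
#' @param path File path.
#' @return A tibble, one row per sample.
#' @export
read_env_table <- function(path) {
  x <- read_delim_auto(path)
  nm1 <- tolower(names(x)[1])
  if (!"sample" %in% tolower(names(x))) names(x)[1] <- "sample"
  names(x)[tolower(names(x)) == "sample"] <- "sample"
  if (anyDuplicated(x$sample)) abort("Duplicated sample identifiers in environment table.")
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  for (v in num) {
    if (any(!is.finite(x[[v]]))) abort(paste0("Non-finite value in environment column '", v, "'."))
  }
  x
}

#' Write a sample environment table
#' @param x Environment tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Numeric environment variables as a samples-by-variables data frame
#'
#' @param env Environment tibble with a `sample` column.
#' @param vars Optional character vector restricting the variables.
#' @return Data frame of numeric columns, row names the sample identifiers.
#' @export
env_numeric <- function(env, vars = NULL) {
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  vars <- vars %||% num
  missing <- setdiff(vars, names(env))
  if (length(missing)) abort(paste0("Unknown environment variable(s): ",
                                    paste(missing, collapse = ", ")))
  out <- as.data.frame(env[vars])
  rownames(out) <- env$sample
  out
}

# sniff comma vs tab from the header line
read_delim_auto <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    name_repair = "minimal", comment = "")
}
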