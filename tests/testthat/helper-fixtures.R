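# Small in-code fixtures shared across test files.

toy_otu <- function() {
  as_otu_tbl(tibble::tibble(
    otu_id = c("OTU_1", "OTU_2", "OTU_3"),
    lineage = c("k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria",
                "k__Bacteria;p__Proteobacteria;c__Deltaproteobacteria",
                "k__Bacteria;p__Acidobacteria"),
    A = c(3L, 4L, 1L),
    B = c(0L, 2L, 6L)))
}

toy_panel <- function() {
  metal_panel(tibble::tibble(
    site = c("S1", "S2", "S3"),
    Cu = c(140, 60, 30),
    Cd = c(2.2, 0.8, 0.3),
    Zn = c(180, 120, 70)))
}

toy_background <- function() {
  background_ref(tibble::tibble(
    metal = c("Cu", "Cd", "Zn"),
    cn = c(24.4, 0.186, 66.5),
    tr = c(5, 30, 1)))
}

# random small OTU tibble (counts only) under the local RNG
random_otu <- function(n_otu = 12, n_sample = 4, lambda = 6) {
  counts <- matrix(rpois(n_otu * n_sample, lambda), n_otu)
  colnames(counts) <- paste0("smp", seq_len(n_sample))
  as_otu_tbl(dplyr::bind_cols(
    tibble::tibble(otu_id = paste0("o", seq_len(n_otu))),
    tibble::as_tibble(counts)))
}

# Euclidean distances of a random point configuration
random_config_dist <- function(n = 6, k = 3) {
  pts <- matrix(rnorm(n * k), n, dimnames = list(paste0("s", 1:n), NULL))
  list(points = pts, d = dist(pts))
}
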