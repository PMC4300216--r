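# small in-code fixtures shared across the suite

# tiny percent matrix with fixed values
tiny_percent <- function() {
  pollen_matrix(rbind(c(50, 25, 25),
                      c(20, 30, 50)),
                ids = c("s1", "s2"),
                taxa = c("Ambrosia", "Quercus", "Pinus"),
                kind = "percent")
}

# small random percent calibration set (not from the synth module, so
# transfer-function tests don't depend on the generator)
random_cal <- function(n_sites, n_taxa, seed) {
  set.seed(seed)
  counts <- matrix(rpois(n_sites * n_taxa, lambda = 20) + 1, n_sites, n_taxa)
  ids <- sprintf("r%02d", seq_len(n_sites))
  taxa <- sprintf("tax%02d", seq_len(n_taxa))
  dimnames(counts) <- list(ids, taxa)
  pm <- to_percentages(pollen_matrix(counts, kind = "counts"))
  # climate correlated with composition so fits are non-degenerate
  x <- as.vector(scale(counts %*% seq_len(n_taxa))) * 3 +
    rnorm(n_sites, 0, 0.5)
  calibration_set(pm, climate_table(ids, feb_mean_temp = x), label = "random")
}

# default synthetic world used by the heavier experiments
synth_world <- function(seed, n_sites = 133, n_taxa = 24) {
  pool <- make_species_pool(n_taxa, seed = seed)
  cal <- generate_calibration(pool, n_sites = n_sites, seed = seed + 1000)
  list(pool = pool, cal = cal)
}
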