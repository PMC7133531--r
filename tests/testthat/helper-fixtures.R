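# shared fixtures and independent oracles

# brute-force Bray-Curtis, written as the naive definition loop so it stays
# independent of the vectorised implementation it checks
bray_curtis_ref <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

subset_contribution_ref <- function(x, y, idx) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    if (i %in% idx) num <- num + abs(x[i] - y[i])
    den <- den + abs(x[i] - y[i])
  }
  num / den
}

# small paired fixture: 2 mesocosms x 2 weeks, 4 OTUs, equal depth 100
toy_pair <- function() {
  otus <- paste0("OTU", 1:4)
  samples <- c("M01_W04", "M01_W10", "M02_W04", "M02_W10")
  dna <- matrix(c(
    50, 30, 20,  0,
    50, 30, 20,  0,
    40, 40, 10, 10,
    10, 20, 30, 40), 4, 4, byrow = TRUE,
    dimnames = list(samples, otus))
  rna <- matrix(c(
    80, 10, 10,  0,
    20, 60, 20,  0,
    60, 20, 10, 10,
     5, 10, 40, 45), 4, 4, byrow = TRUE,
    dimnames = list(samples, otus))
  meta <- data.frame(
    sample_id = samples,
    mesocosm_id = rep(c("M01", "M02"), each = 2),
    treatment = rep(c("control", "disturbance"), each = 2),
    week = rep(c(4L, 10L), 2),
    temperature_C = c(14, 14, 14, 60))
  pair_counts(otu_table(dna, "DNA"), otu_table(rna, "RNA"), meta)
}

# scaled-down simulator configuration for fast unit tests (community and
# sequencing depth reduced ~4x; rarefaction depth 12000)
tiny_sim_config <- function(...) {
  sim_config(n_sensitive = 40L, n_immigrant = 6L, n_generalist = 4L,
             n_early = 4L, n_late = 8L, n_opportunist = 5L,
             n_dormant = 10L, n_relic = 8L,
             K = 2.9e7, depth_meanlog = log(15000), depth_sdlog = 0.12,
             ...)
}

tiny_press_config <- function(seed = 1L, ...) {
  press_config(sim = tiny_sim_config(), depth = 12000, seed = seed, ...)
}

run_quiet <- function(config) {
  suppressWarnings(suppressMessages(run_press_analysis(config)))
}

# archetype scaling note: abundances per taxon are unchanged, so per-taxon
# detectability at the reduced depth is roughly preserved (both community
# size and depth shrink ~4x)
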