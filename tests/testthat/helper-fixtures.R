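# Small fixture builders used across the test files.

# Abundance table from a counts matrix and species labels; genus/family
# default to a shared lineage unless given.
make_table <- function(counts, species = NULL, genus = NULL, family = NULL,
                       platform = "shotgun", named = NULL,
                       genome_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(species)) species <- sprintf("Genus_A sp%02d", seq_len(ncol(counts)))
  colnames(counts) <- species
  if (is.null(genus)) genus <- sub("\\s+\\S+$", "", species)
  if (is.null(family)) family <- rep("Family_A", length(species))
  lin <- data.frame(
    taxon_id = species,
    phylum = "Phylum_A", class = "Class_A", order = "Order_A",
    family = family, genus = genus, species = species,
    named = if (is.null(named)) rep(TRUE, length(species)) else named,
    stringsAsFactors = FALSE)
  abundance_table(counts, lin, platform = platform,
                  genome_lengths = genome_lengths)
}

# Random sparse count table
random_table <- function(n = 6, s = 8, depth = 200, platform = "shotgun",
                         seed = 1) {
  set.seed(seed)
  p <- exp(rnorm(s))
  counts <- t(stats::rmultinom(n, depth, p))
  make_table(counts, platform = platform)
}

# Tiny paired study with exactly matching sample sets
small_paired <- function(seed = 1, ...) {
  cfg <- generator_config(n_control = 12, n_hrl = 12, n_crc = 12,
                          n_species = 80, depth_shotgun = 8000,
                          depth_16s = 1200, seed = seed, ...)
  simulate_paired_study(cfg)
}
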