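#' Configuration for the paired-platform study generator
#'
#' The generator emulates the statistical structure of a paired 16S/shotgun
#' colorectal-screening study: a shared latent community observed through
#' two platforms with very different depths, platform-specific taxon
#' detectability (16S sees only a fraction of the species, plus some taxa
#' absent from the shotgun catalogue), slash-named ambiguous 16S species,
#' genome-length bias in shotgun counts, 16S copy-number bias, higher 16S
#' sparsity, and a planted diagnosis effect (control/HRL/CRC) on a subset of
#' signature species, with the HRL shift half the CRC shift (the
#' adenoma-carcinoma continuum).
#'
#' @param n_control,n_hrl,n_crc samples per diagnosis class (defaults
#'   51/54/51, the screening-study design).
#' @param n_species number of species in the shotgun catalogue (default
#'   300).
#' @param species_per_genus,genera_per_family taxonomy shape (defaults 3
#'   and 4).
#' @param depth_shotgun,depth_16s mean reads per sample (defaults 50000 and
#'   5000, a scaled-down 10:1 depth ratio).
#' @param detect_frac_16s fraction of species detectable by 16S (default
#'   0.6).
#' @param frac_16s_only extra species observed only by 16S, as a fraction
#'   of `n_species` (default 0.15).
#' @param ambiguity_rate fraction of detectable 16S species collapsed into
#'   slash-named candidate groups (default 0.2; groups form within genera).
#' @param coupling platform abundance-correlation control in \[0, 1\]: 1
#'   means the 16S layer adds no distortion beyond depth/detection, 0 means
#'   full platform-specific bias and noise.
#' @param n_signature number of differentially abundant species (default
#'   10).
#' @param effect_size log-scale (clr-like) shift of signature species in
#'   CRC; HRL receives half of it (default 1.5).
#' @param genome_length_range genome length range in bases (default 2-8
#'   Mb).
#' @param copy_number_range 16S rRNA copy-number range (default 1-10).
#' @param unnamed_frac fraction of species carrying only a database
#'   accession label (default 0.1).
#' @param sigma_taxon sd of baseline log abundances across taxa (default
#'   2).
#' @param sigma_sample sd of per-sample log-abundance noise (default 0.6).
#' @param sigma_platform sd of the 16S platform bias/noise, scaled by
#'   `1 - coupling` (default 1).
#' @param depth_sdlog lognormal sd of per-sample depths (default 0.3).
#' @param seed integer seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_control = 51, n_hrl = 54, n_crc = 51,
                             n_species = 300, species_per_genus = 3,
                             genera_per_family = 4,
                             depth_shotgun = 50000, depth_16s = 5000,
                             detect_frac_16s = 0.6, frac_16s_only = 0.15,
                             ambiguity_rate = 0.2, coupling = 0.8,
                             n_signature = 10, effect_size = 1.5,
                             genome_length_range = c(2e6, 8e6),
                             copy_number_range = c(1, 10),
                             unnamed_frac = 0.1,
                             sigma_taxon = 2, sigma_sample = 0.6,
                             sigma_platform = 1, depth_sdlog = 0.3,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(detect_frac_16s > 0, detect_frac_16s <= 1,
            frac_16s_only >= 0, frac_16s_only <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            coupling >= 0, coupling <= 1,
            depth_shotgun > 0, depth_16s > 0, effect_size >= 0)
  class(cfg) <- "generator_config"
  cfg
}

# Hierarchical taxonomy for n species: genus/family/order/class/phylum.
build_taxonomy <- function(n_species, species_per_genus, genera_per_family,
                           prefix = "") {
  g <- ceiling(seq_len(n_species) / species_per_genus)
  f <- ceiling(g / genera_per_family)
  o <- ceiling(f / 3)
  cl <- ceiling(o / 3)
  ph <- ceiling(cl / 2)
  genus <- sprintf("Genus%s_%03d", prefix, g)
  data.frame(
    phylum = sprintf("Phylum%s_%02d", prefix, ph),
    class = sprintf("Class%s_%02d", prefix, cl),
    order = sprintf("Order%s_%02d", prefix, o),
    family = sprintf("Family%s_%03d", prefix, f),
    genus = genus,
    species = sprintf("%s sp%03d", genus, seq_len(n_species)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic paired-platform study
#'
#' Draws a latent log-normal community per sample, adds the planted class
#' effects on signature species, and observes it twice: shotgun counts are
#' multinomial with probabilities proportional to latent abundance times
#' genome length; 16S counts are multinomial over the detectable subset
#' with probabilities proportional to latent abundance times 16S copy
#' number, distorted by platform bias/noise scaled by `1 - coupling`, then
#' collapsed into slash-named ambiguity groups and augmented with
#' 16S-only species absent from the shotgun catalogue.
#'
#' @param config a [generator_config()].
#' @return list with `study` (a [paired_study()]) and `truth` (latent
#'   abundances, signature species, ambiguity map, detectable set, biases).
#' @export
simulate_paired_study <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_control + cfg$n_hrl + cfg$n_crc
  diagnosis <- factor(rep(c("control", "HRL", "CRC"),
                          c(cfg$n_control, cfg$n_hrl, cfg$n_crc)),
                      levels = c("control", "HRL", "CRC"))
  sample_ids <- sprintf("S%03d", seq_len(n))

  ## shotgun catalogue taxonomy
  lin <- build_taxonomy(cfg$n_species, cfg$species_per_genus,
                        cfg$genera_per_family)
  unnamed <- rep(FALSE, cfg$n_species)
  if (cfg$unnamed_frac > 0) {
    unnamed[sample(cfg$n_species, round(cfg$unnamed_frac * cfg$n_species))] <- TRUE
    lin$species[unnamed] <- sprintf("MGYG%06d", which(unnamed))
  }
  lin$named <- !unnamed
  lin$taxon_id <- lin$species

  ## detectability and planted signature (signature must be seen by both)
  n_detect <- max(1, round(cfg$detect_frac_16s * cfg$n_species))
  detectable <- sort(sample(cfg$n_species, n_detect))
  candidates <- intersect(detectable, which(!unnamed))
  if (length(candidates) < cfg$n_signature)
    stop("too few named detectable species for the requested signature")
  signature <- sort(sample(candidates, cfg$n_signature))

  ## latent community
  mu <- stats::rnorm(cfg$n_species, 0, cfg$sigma_taxon)
  shift <- c(control = 0, HRL = 0.5, CRC = 1)[as.character(diagnosis)]
  latent <- matrix(stats::rnorm(n * cfg$n_species, 0, cfg$sigma_sample),
                   n, cfg$n_species)
  latent <- sweep(latent, 2, mu, `+`)
  latent[, signature] <- latent[, signature] + cfg$effect_size * shift

  ## shotgun observation: genome-length bias + multinomial depth
  genome_lengths <- stats::runif(cfg$n_species, cfg$genome_length_range[1],
                                 cfg$genome_length_range[2])
  names(genome_lengths) <- lin$taxon_id
  depth_sg <- round(stats::rlnorm(n, log(cfg$depth_shotgun), cfg$depth_sdlog))
  counts_sg <- matrix(0L, n, cfg$n_species,
                      dimnames = list(sample_ids, lin$taxon_id))
  for (i in seq_len(n)) {
    p <- exp(latent[i, ]) * genome_lengths
    counts_sg[i, ] <- stats::rmultinom(1, depth_sg[i], p)
  }

  ## 16S observation over detectable species + 16S-only species
  n_extra <- round(cfg$frac_16s_only * cfg$n_species)
  lin16_shared <- lin[detectable, , drop = FALSE]
  extra_lin <- NULL
  if (n_extra > 0) {
    extra_lin <- build_taxonomy(n_extra, cfg$species_per_genus,
                                cfg$genera_per_family, prefix = "16S")
    extra_lin$named <- TRUE
    extra_lin$taxon_id <- extra_lin$species
  }
  copy_number <- stats::runif(nrow(lin16_shared) + n_extra,
                              cfg$copy_number_range[1],
                              cfg$copy_number_range[2])
  bias <- stats::rnorm(nrow(lin16_shared) + n_extra, 0, cfg$sigma_platform)
  mu_extra <- stats::rnorm(n_extra, 0, cfg$sigma_taxon)
  depth_16 <- round(stats::rlnorm(n, log(cfg$depth_16s), cfg$depth_sdlog))
  lin16 <- rbind(lin16_shared[c(TAXO_RANKS, "named", "taxon_id")],
                 if (n_extra > 0) extra_lin[c(TAXO_RANKS, "named", "taxon_id")])
  d16 <- nrow(lin16)
  counts_16 <- matrix(0L, n, d16, dimnames = list(sample_ids, lin16$taxon_id))
  s_noise <- 1 - cfg$coupling
  for (i in seq_len(n)) {
    lat16 <- c(latent[i, detectable],
               if (n_extra > 0)
                 mu_extra + stats::rnorm(n_extra, 0, cfg$sigma_sample))
    noise <- stats::rnorm(d16, 0, cfg$sigma_platform)
    p <- exp(lat16 + s_noise * (bias + noise)) * copy_number
    counts_16[i, ] <- stats::rmultinom(1, depth_16[i], p)
  }

  ## ambiguity: collapse within-genus groups of detectable named species
  x16 <- abundance_table(counts_16, lin16, platform = "16S")
  ambiguity_groups <- list()
  if (cfg$ambiguity_rate > 0) {
    named_idx <- which(lin16$named)
    by_genus <- split(named_idx, lin16$genus[named_idx])
    by_genus <- by_genus[lengths(by_genus) >= 2]
    target <- round(cfg$ambiguity_rate * length(named_idx))
    pooled <- 0
    for (gname in sample(names(by_genus))) {
      if (pooled >= target) break
      ix <- by_genus[[gname]]
      gsize <- min(length(ix), sample(2:3, 1))
      grp <- sort(sample(ix, gsize))
      ambiguity_groups[[length(ambiguity_groups) + 1]] <- lin16$taxon_id[grp]
      pooled <- pooled + gsize
    }
    if (length(ambiguity_groups)) {
      lab <- lin16$taxon_id
      for (grp in ambiguity_groups) {
        joined <- merge_label(grp)
        lab[lab %in% grp] <- joined
      }
      groups <- split(seq_along(lab), factor(lab, levels = unique(lab)))
      counts_16 <- sum_groups(counts_16, groups)
      first <- vapply(groups, `[`, integer(1), 1L)
      lin16 <- lin16[first, , drop = FALSE]
      lin16$taxon_id <- names(groups)
      lin16$species <- names(groups)
      x16 <- abundance_table(counts_16, lin16, platform = "16S")
    }
  }

  shotgun <- abundance_table(counts_sg, lin, platform = "shotgun",
                             genome_lengths = genome_lengths)
  metadata <- data.frame(sample_id = sample_ids,
                         diagnosis = as.character(diagnosis),
                         stringsAsFactors = FALSE)
  study <- paired_study(shotgun, x16, metadata)
  truth <- list(
    config = cfg,
    latent = `dimnames<-`(latent, list(sample_ids, lin$taxon_id)),
    signature_species = lin$taxon_id[signature],
    detectable_16s = lin$taxon_id[detectable],
    ambiguity_groups = ambiguity_groups,
    genome_lengths = genome_lengths,
    copy_number = stats::setNames(copy_number,
                                  c(lin$taxon_id[detectable],
                                    if (n_extra > 0) extra_lin$taxon_id)),
    depth_shotgun = stats::setNames(depth_sg, sample_ids),
    depth_16s = stats::setNames(depth_16, sample_ids))
  list(study = study, truth = truth)
}

#' Write a synthetic study to plain-text files
#'
#' Emits exactly the input dialects the pipeline consumes: two abundance
#' tables (`sample_id` first column, taxa as remaining columns), a combined
#' lineage table, genome lengths, sample metadata and a JSON truth
#' manifest. Byte-identical under a fixed generator seed.
#'
#' @param sim result of [simulate_paired_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- sim$study
  paths <- c(
    shotgun = file.path(dir, "counts_shotgun.tsv"),
    x16s = file.path(dir, "counts_16s.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    genome_lengths = file.path(dir, "genome_lengths.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  write_counts <- function(tab, path) {
    df <- data.frame(sample_id = rownames(tab$counts), tab$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_counts(study$shotgun, paths["shotgun"])
  write_counts(study$x16s, paths["x16s"])
  lin <- unique(rbind(study$shotgun$lineage[c("taxon_id", TAXO_RANKS, "named")],
                      study$x16s$lineage[c("taxon_id", TAXO_RANKS, "named")]))
  utils::write.table(lin, paths["lineage"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gl <- study$shotgun$genome_lengths
  utils::write.table(
    data.frame(taxon_id = names(gl), length_bp = unname(gl)),
    paths["genome_lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$latent <- NULL  # large; regenerable from config + seed
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a paired study from files written by [write_study()]
#'
#' @param dir directory containing `counts_shotgun.tsv`, `counts_16s.tsv`,
#'   `lineage.tsv`, `genome_lengths.tsv` and `metadata.tsv`.
#' @param transposed set `TRUE` if the count tables are taxa x samples.
#' @return a [paired_study()].
#' @export
read_study <- function(dir, transposed = FALSE) {
  read_counts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (transposed) m <- t(m)
    m
  }
  lin <- utils::read.delim(file.path(dir, "lineage.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  gl_df <- utils::read.delim(file.path(dir, "genome_lengths.tsv"),
                             stringsAsFactors = FALSE)
  gl <- stats::setNames(gl_df$length_bp, gl_df$taxon_id)
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  sg <- read_counts(file.path(dir, "counts_shotgun.tsv"))
  s16 <- read_counts(file.path(dir, "counts_16s.tsv"))
  paired_study(
    abundance_table(sg, lin, platform = "shotgun", genome_lengths = gl),
    abundance_table(s16, lin, platform = "16S"),
    meta)
}
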