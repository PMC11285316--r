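# Canonical rank order used throughout (highest to lowest).
TAXO_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Sample-by-taxon abundance table
#'
#' The basic container of the package: a samples x taxa count matrix together
#' with the taxonomic lineage of every taxon, a platform tag and optional
#' per-taxon genome lengths (for shotgun data). Column names of `counts` are
#' the taxon labels at the table's `rank`; 16S species labels may contain
#' "/"-joined sets of candidate species (slash-taxa).
#'
#' @param counts numeric matrix, samples in rows (unique rownames), taxa in
#'   columns (unique colnames), non-negative entries.
#' @param lineage data.frame with one row per taxon (aligned with
#'   `colnames(counts)`), columns `taxon_id`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species` and logical `named`. Missing ranks are `NA`
#'   and are only allowed below the deepest assigned rank.
#' @param platform `"shotgun"` or `"16S"`.
#' @param rank the taxonomic rank of the table's columns (default
#'   `"species"`).
#' @param genome_lengths optional named numeric vector of genome lengths in
#'   bases, names matching taxon ids.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, lineage, platform = c("shotgun", "16S"),
                            rank = "species", genome_lengths = NULL) {
  platform <- match.arg(platform)
  rank <- match.arg(rank, TAXO_RANKS)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("'counts' needs sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated taxon ids")
  if (any(counts < 0))
    stop("negative entries in 'counts'")
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(lineage))
    stop("lineage needs a 'taxon_id' column")
  if (!all(colnames(counts) %in% lineage$taxon_id))
    stop("every taxon must have a lineage row")
  lineage <- lineage[match(colnames(counts), lineage$taxon_id), , drop = FALSE]
  rownames(lineage) <- NULL
  if (!"named" %in% names(lineage))
    lineage$named <- !is_unnamed(lineage$taxon_id)
  if (!is.null(genome_lengths)) {
    genome_lengths <- genome_lengths[colnames(counts)]
    names(genome_lengths) <- colnames(counts)
  }
  structure(
    list(counts = counts, lineage = lineage, platform = platform,
         rank = rank, genome_lengths = genome_lengths),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s, rank=%s]: %d samples x %d taxa\n",
              x$platform, x$rank, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts: %.6g; zero fraction: %.3f\n",
              sum(x$counts), mean(x$counts == 0)))
  if (!is.null(x$genome_lengths))
    cat("  genome lengths attached\n")
  invisible(x)
}

n_samples <- function(x) nrow(x$counts)
n_taxa <- function(x) ncol(x$counts)

#' Taxon labels of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of taxon ids (column labels).
#' @export
taxa_names <- function(x) colnames(x$counts)

#' Candidate species sets of slash-named taxa
#'
#' 16S lineages that could not be resolved to a single species are labelled
#' with all candidate species joined by "/" in alphabetical order, the
#' shared genus written once (e.g. "Blautia obeum/wexlerae" for the
#' candidates Blautia obeum and Blautia wexlerae). This helper expands such
#' labels back into full candidate names: parts after the first inherit the
#' first part's genus prefix unless they already contain one.
#'
#' @param labels character vector of species labels.
#' @return list of character vectors (one full-name set per label).
#' @export
candidate_sets <- function(labels) {
  lapply(strsplit(labels, "/", fixed = TRUE), function(parts) {
    if (length(parts) == 1L || !grepl(" ", parts[1])) return(parts)
    genus <- sub("\\s+\\S+$", "", parts[1])
    rest <- parts[-1]
    bare <- !grepl(" ", rest)
    rest[bare] <- paste(genus, rest[bare])
    c(parts[1], rest)
  })
}

#' Label for a merged set of candidate species
#'
#' Inverse of [candidate_sets()]: joins full candidate names into a
#' slash-label, writing a shared genus prefix once and sorting the epithets
#' alphabetically ("Blautia obeum/wexlerae"). Candidates without a common
#' genus (or without a genus at all) are simply sorted and joined.
#'
#' @param candidates character vector of full candidate species names.
#' @return a single slash-joined label.
#' @export
merge_label <- function(candidates) {
  candidates <- sort(unique(candidates))
  if (length(candidates) == 1L) return(candidates)
  if (all(grepl(" ", candidates))) {
    genus <- sub("\\s+\\S+$", "", candidates)
    if (length(unique(genus)) == 1L) {
      epithets <- sort(sub("^.*\\s", "", candidates))
      return(paste0(genus[1], " ", paste(epithets, collapse = "/")))
    }
  }
  paste(candidates, collapse = "/")
}

#' Flag taxa identified only by database accession codes
#'
#' Reference databases contain taxa without a Linnean name, identified only
#' by an accession (for instance genome catalogue codes starting "MGYG").
#' These cannot be matched across platforms and are flagged unnamed.
#'
#' @param labels character vector of taxon labels.
#' @param patterns character vector of accession-prefix regular expressions.
#' @return logical vector, `TRUE` where the label matches any pattern.
#' @export
is_unnamed <- function(labels, patterns = c("^MGYG")) {
  out <- rep(FALSE, length(labels))
  for (p in patterns) out <- out | grepl(p, labels)
  out
}

# Rebuild an abundance_table with new counts/lineage, keeping other fields.
replace_table <- function(x, counts, lineage, genome_lengths = x$genome_lengths,
                          rank = x$rank) {
  if (!is.null(genome_lengths))
    genome_lengths <- genome_lengths[intersect(names(genome_lengths),
                                               colnames(counts))]
  if (length(genome_lengths) == 0L) genome_lengths <- NULL
  abundance_table(counts, lineage, platform = x$platform, rank = rank,
                  genome_lengths = genome_lengths)
}

#' Paired two-platform study
#'
#' Bundles the two sample-matched abundance tables (shotgun and 16S) with the
#' per-sample diagnosis labels (three-level factor: control, HRL = advanced
#' colorectal lesion, CRC).
#'
#' @param shotgun,x16s `abundance_table`s with identical sample sets.
#' @param metadata data.frame with columns `sample_id` and `diagnosis`.
#' @return an object of class `paired_study`.
#' @export
paired_study <- function(shotgun, x16s, metadata) {
  stopifnot(inherits(shotgun, "abundance_table"),
            inherits(x16s, "abundance_table"))
  if (shotgun$platform != "shotgun" || x16s$platform != "16S")
    stop("platform tags must be 'shotgun' and '16S'")
  ids <- rownames(shotgun$counts)
  if (!setequal(ids, rownames(x16s$counts)))
    stop("sample ids differ between platforms: ",
         paste(union(setdiff(ids, rownames(x16s$counts)),
                     setdiff(rownames(x16s$counts), ids)), collapse = ", "))
  x16s$counts <- x16s$counts[ids, , drop = FALSE]
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "diagnosis") %in% names(metadata)))
    stop("metadata needs 'sample_id' and 'diagnosis' columns")
  if (!setequal(metadata$sample_id, ids))
    stop("metadata sample ids do not match the abundance tables")
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata$diagnosis <- factor(as.character(metadata$diagnosis),
                               levels = c("control", "HRL", "CRC"))
  if (anyNA(metadata$diagnosis))
    stop("diagnosis labels must be control/HRL/CRC")
  structure(list(shotgun = shotgun, x16s = x16s, metadata = metadata),
            class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf(
    "paired_study: %d samples (%s)\n", nrow(x$metadata),
    paste(sprintf("%s=%d", levels(x$metadata$diagnosis),
                  table(x$metadata$diagnosis)), collapse = ", ")))
  cat(sprintf("  shotgun: %d taxa | 16S: %d taxa (rank %s)\n",
              n_taxa(x$shotgun), n_taxa(x$x16s), x$shotgun$rank))
  invisible(x)
}
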