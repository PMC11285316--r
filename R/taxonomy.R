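#' Synonym map for taxonomy harmonization
#'
#' 16S and shotgun profiles typically come from different reference databases
#' (SILVA-derived vs genome catalogues) whose taxon names drift apart, mostly
#' through outdated synonyms. A synonym map lists, per rank, old names and
#' their canonical replacements; it is supplied by the user as a file rather
#' than queried live so that analyses are reproducible offline.
#'
#' The map must be idempotent: applying it twice equals applying it once,
#' i.e. no canonical name is itself remapped. Chains and cycles are rejected.
#'
#' @param old_name,canonical_name,rank equal-length character vectors.
#' @return an object of class `synonym_map` (a data.frame).
#' @export
synonym_map <- function(old_name, canonical_name, rank) {
  m <- data.frame(old_name = as.character(old_name),
                  canonical_name = as.character(canonical_name),
                  rank = as.character(rank),
                  stringsAsFactors = FALSE)
  if (!all(m$rank %in% TAXO_RANKS))
    stop("unknown rank in synonym map")
  if (anyDuplicated(m[c("old_name", "rank")]))
    stop("duplicated old_name within a rank")
  # idempotency: canonical names must not appear as old names at the same
  # rank with a different target (this also rules out cycles)
  for (r in unique(m$rank)) {
    mr <- m[m$rank == r, , drop = FALSE]
    bad <- mr$canonical_name %in% mr$old_name[mr$old_name != mr$canonical_name]
    if (any(bad))
      stop("synonym map is not idempotent (chain or cycle) at rank ", r,
           ": ", paste(unique(mr$canonical_name[bad]), collapse = ", "))
  }
  class(m) <- c("synonym_map", "data.frame")
  m
}

#' Read a synonym map from a tab-separated file
#'
#' Expected columns: `old_name`, `canonical_name`, `rank`.
#'
#' @param path file path.
#' @return a `synonym_map`.
#' @export
read_synonym_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  synonym_map(m$old_name, m$canonical_name, m$rank)
}

apply_synonyms <- function(values, map, rank) {
  mr <- map[map$rank == rank, , drop = FALSE]
  i <- match(values, mr$old_name)
  hit <- !is.na(i)
  values[hit] <- mr$canonical_name[i[hit]]
  values
}

#' Harmonize taxon names with a synonym map
#'
#' Replaces outdated names at every rank by their canonical forms and merges
#' taxa whose full lineages become identical after renaming (their counts are
#' summed), so each harmonized lineage appears exactly once. Per-sample count
#' totals are preserved exactly.
#'
#' @param table an `abundance_table`.
#' @param map a `synonym_map` (an empty map leaves the table unchanged).
#' @return a harmonized `abundance_table`.
#' @export
normalize_names <- function(table, map) {
  stopifnot(inherits(table, "abundance_table"))
  if (!inherits(map, "synonym_map"))
    map <- synonym_map(map$old_name, map$canonical_name, map$rank)
  lin <- table$lineage
  for (r in TAXO_RANKS)
    if (r %in% names(lin))
      lin[[r]] <- apply_synonyms(lin[[r]], map, r)
  # taxon label follows the table's rank name
  new_id <- lin[[table$rank]]
  new_id[is.na(new_id)] <- lin$taxon_id[is.na(new_id)]
  lin$taxon_id <- new_id
  collapse_by_lineage(table, lin)
}

# Column-group sums; always returns a samples x groups matrix.
sum_groups <- function(counts, groups) {
  out <- matrix(0, nrow(counts), length(groups),
                dimnames = list(rownames(counts), names(groups)))
  for (k in seq_along(groups))
    out[, k] <- rowSums(counts[, groups[[k]], drop = FALSE])
  out
}

# Merge columns whose lineage rows are identical; counts summed.
collapse_by_lineage <- function(table, lin) {
  key <- do.call(paste, c(lin[c("taxon_id", intersect(TAXO_RANKS, names(lin)))],
                          sep = "\r"))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  counts <- sum_groups(table$counts, groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  new_lin <- lin[first, , drop = FALSE]
  colnames(counts) <- new_lin$taxon_id
  gl <- table$genome_lengths
  if (!is.null(gl)) {
    gl <- vapply(groups, function(ix) mean(gl[ix]), numeric(1))
    names(gl) <- new_lin$taxon_id
  }
  replace_table(table, counts, new_lin, genome_lengths = gl)
}

#' Aggregate counts to a higher taxonomic rank
#'
#' Columns are grouped by their name at the requested rank and summed;
#' per-sample totals are unchanged. Slash-named ambiguous species contribute
#' to the genus shared by all their candidates. Taxa lacking the requested
#' rank are collected in an explicit `unassigned@<rank>` bucket which keeps
#' compositions closed but is flagged unnamed, so it drops out of
#' cross-platform overlap statistics.
#'
#' @param table an `abundance_table`.
#' @param rank target rank, one of phylum...species.
#' @return an `abundance_table` at `rank`.
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank, TAXO_RANKS)
  if (rank == table$rank) return(table)
  ri <- match(rank, TAXO_RANKS)
  if (ri > match(table$rank, TAXO_RANKS))
    stop("cannot disaggregate from ", table$rank, " to ", rank)
  lin <- table$lineage
  name_at_rank <- lin[[rank]]
  unassigned <- is.na(name_at_rank) | name_at_rank == ""
  name_at_rank[unassigned] <- paste0("unassigned@", rank)
  groups <- split(seq_along(name_at_rank),
                  factor(name_at_rank, levels = unique(name_at_rank)))
  counts <- sum_groups(table$counts, groups)
  keep_ranks <- TAXO_RANKS[seq_len(ri)]
  first <- vapply(groups, `[`, integer(1), 1L)
  new_lin <- data.frame(taxon_id = names(groups), stringsAsFactors = FALSE)
  for (r in keep_ranks) new_lin[[r]] <- lin[[r]][first]
  new_lin[[rank]] <- names(groups)
  new_lin$named <- !is_unnamed(names(groups)) &
    !startsWith(names(groups), "unassigned@")
  for (r in keep_ranks)
    new_lin[[r]][startsWith(new_lin$taxon_id, "unassigned@")] <- NA
  colnames(counts) <- names(groups)
  replace_table(table, counts, new_lin, genome_lengths = NULL, rank = rank)
}

#' Merge 16S taxa with overlapping candidate-species sets
#'
#' A candidate species can appear in more than one slash-named amplicon
#' taxon. Taxa whose candidate sets intersect are merged transitively
#' (union-find over shared candidates); the merged taxon is named by the
#' alphabetically sorted union of candidates joined with "/", and counts are
#' summed. Applying the operation twice equals applying it once.
#'
#' @param table an `abundance_table` (16S species table).
#' @return an `abundance_table` with merged ambiguous taxa.
#' @export
merge_ambiguous <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  labels <- taxa_names(table)
  sets <- candidate_sets(labels)
  # union-find over candidate names
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- new.env(parent = emptyenv())
  for (i in seq_along(sets)) {
    for (cand in sets[[i]]) {
      j <- get0(cand, envir = owner)
      if (is.null(j)) assign(cand, i, envir = owner)
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_along(labels), find, integer(1))
  groups <- split(seq_along(labels), root)
  if (all(lengths(groups) == 1L)) return(table)
  lin <- table$lineage
  counts <- sum_groups(table$counts, groups)
  new_names <- vapply(groups, function(ix)
    merge_label(unlist(sets[ix])), character(1))
  first <- vapply(groups, `[`, integer(1), 1L)
  new_lin <- lin[first, , drop = FALSE]
  new_lin$taxon_id <- new_names
  if ("species" %in% names(new_lin)) new_lin$species <- new_names
  new_lin$named <- !is_unnamed(new_names)
  colnames(counts) <- new_names
  # keep original column order by first member
  ord <- order(first)
  replace_table(table, counts[, ord, drop = FALSE],
                new_lin[ord, , drop = FALSE], genome_lengths = NULL)
}

#' Drop taxa identified only by accession codes
#'
#' Taxa without a proper name (flagged `named = FALSE`, e.g. genome-catalogue
#' accessions such as "MGYG...") cannot be matched between platforms and are
#' excluded from cross-platform comparisons.
#'
#' @param table an `abundance_table`.
#' @return the table restricted to named taxa (sample order unchanged).
#' @export
exclude_unnamed <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- which(table$lineage$named)
  if (length(keep) == 0L) {
    warning("no named taxa remain")
  }
  replace_table(table, table$counts[, keep, drop = FALSE],
                table$lineage[keep, , drop = FALSE])
}
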