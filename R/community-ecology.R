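# Community-ecology summaries for taxa count tables: relative abundance,
# aggregation to a taxonomic rank, minor-taxon lumping, richness and
# Shannon diversity.

#' Relative abundances
#'
#' @param counts samples x taxa count matrix.
#' @return proportions matrix with rows summing to 1; empty samples
#'   (total 0) are excluded and listed in the `excluded` attribute.
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  empty <- tot == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty sample(s)")
  }
  out <- sweep(counts[!empty, , drop = FALSE], 1, tot[!empty], `/`)
  attr(out, "excluded") <- rownames(counts)[empty]
  out
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label; taxa without an
#' assignment at that rank are collected into `"Other"`. Per-sample totals
#' are preserved.
#'
#' @param counts samples x taxa count matrix (columns = taxon ids).
#' @param lineage data frame with `taxon_id` and one column per rank.
#' @param rank rank column name (e.g. `"phylum"`, `"genus"`).
#' @return samples x rank-labels matrix.
#' @export
aggregate_rank <- function(counts, lineage, rank) {
  if (!rank %in% names(lineage)) stop("unknown rank: ", rank)
  lab <- lineage[[rank]][match(colnames(counts), lineage$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "Other"
  groups <- sort(unique(lab))
  out <- sapply(groups, function(g) {
    rowSums(counts[, lab == g, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), groups))
  stopifnot(all(abs(rowSums(out) - rowSums(counts)) < 1e-8))
  out
}

#' Lump minor taxa
#'
#' A taxon is relabelled `"Minor"` when its group-mean relative abundance
#' is below the cut in every group. Defaults follow common stacked-bar
#' conventions: minor phyla below 0.1% in all groups, minor genera below
#' 2% in all groups.
#'
#' @param proportions samples x taxa relative-abundance matrix.
#' @param groups grouping factor aligned with the rows.
#' @param cut relative-abundance threshold (e.g. 0.001 for phyla, 0.02 for
#'   genera).
#' @return list: `proportions` with minor columns summed into `"Minor"`,
#'   `minor` (lumped taxon names), `group_means`.
#' @export
lump_minor <- function(proportions, groups, cut = 0.02) {
  groups <- factor(groups)
  gm <- apply(proportions, 2, function(v) tapply(v, groups, mean))
  gm <- matrix(gm, nrow = nlevels(groups),
               dimnames = list(levels(groups), colnames(proportions)))
  minor <- colnames(proportions)[apply(gm < cut, 2, all)]
  keep <- setdiff(colnames(proportions), minor)
  out <- proportions[, keep, drop = FALSE]
  if (length(minor)) {
    out <- cbind(out, Minor = rowSums(proportions[, minor, drop = FALSE]))
  }
  stopifnot(all(abs(rowSums(out) - rowSums(proportions)) < 1e-8))
  list(proportions = out, minor = minor, group_means = gm)
}

#' Richness
#'
#' Number of taxa observed (count > 0) in a sample.
#'
#' @param sample_counts count vector or samples x taxa matrix.
#' @return integer (per sample when a matrix is given).
#' @export
richness <- function(sample_counts) {
  if (is.matrix(sample_counts)) return(rowSums(sample_counts > 0))
  sum(sample_counts > 0)
}

#' Shannon diversity
#'
#' `H = -sum(p_i * log(p_i))` over the taxa present in the sample,
#' natural logarithm.
#'
#' @param sample_counts count (or proportion) vector, or a samples x taxa
#'   matrix.
#' @return numeric H (per sample for a matrix); `NA` with a warning for an
#'   empty sample.
#' @export
shannon <- function(sample_counts) {
  if (is.matrix(sample_counts)) {
    return(apply(sample_counts, 1, shannon))
  }
  tot <- sum(sample_counts)
  if (tot <= 0) {
    warning("Shannon undefined for an empty sample")
    return(NA_real_)
  }
  p <- sample_counts[sample_counts > 0] / tot
  -sum(p * log(p))
}

#' Group diversity summary
#'
#' Richness and Shannon diversity per sample with the group attached;
#' convenience wrapper for group comparisons.
#'
#' @param counts samples x taxa count matrix.
#' @param groups grouping factor aligned with rows.
#' @return data frame: sample_id, group, richness, shannon.
#' @export
diversity_summary <- function(counts, groups) {
  data.frame(sample_id = rownames(counts), group = groups,
             richness = richness(counts), shannon = shannon(counts),
             row.names = NULL)
}
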