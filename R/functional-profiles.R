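# Functional (KEGG-Ortholog) profiles: TMM normalization and aggregation
# to BRITE level-B / level-C pathway tables.

#' TMM normalization factors
#'
#' Trimmed mean of M-values with the canonical parameters (30% trim on
#' log-ratios, 5% on average log-abundance, precision weighting, reference
#' chosen as the sample whose upper quartile is closest to the mean upper
#' quartile), computed with edgeR. Factors multiply to 1 across samples
#' (geometric-mean centered).
#'
#' @param counts samples x features count matrix.
#' @return named per-sample normalization factors.
#' @export
tmm_factors <- function(counts) {
  if (nrow(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(rowSums(counts) <= 0)) stop("all-zero sample(s) cannot be normalized")
  d <- edgeR::DGEList(counts = t(counts))
  d <- edgeR::calcNormFactors(d, method = "TMM")
  stats::setNames(d$samples$norm.factors, rownames(counts))
}

#' TMM-normalized abundances
#'
#' Counts scaled to counts-per-million of the effective library size
#' (library size times TMM factor).
#'
#' @param counts samples x features count matrix.
#' @return normalized abundance matrix of the same shape.
#' @export
tmm_normalize <- function(counts) {
  f <- tmm_factors(counts)
  eff <- rowSums(counts) * f
  sweep(counts, 1, eff, `/`) * 1e6
}

#' Aggregate a KO table over the BRITE hierarchy
#'
#' Pathway count = sum of member-KO counts. A KO mapped to several
#' entries at the requested level contributes to each (the duplicated
#' mass is reported); observed KOs absent from the map are collected into
#' an `"Unmapped"` row.
#'
#' @param ko_counts samples x KO count matrix.
#' @param brite_map data frame `ko`, `level_b`, `level_c` (one row per
#'   membership).
#' @param level `"B"` or `"C"`.
#' @return list: `table` (samples x pathways), `multiplicity` (KOs counted
#'   more than once), `duplicated_mass` (total count mass added by
#'   multiple membership).
#' @export
aggregate_brite <- function(ko_counts, brite_map, level = c("B", "C")) {
  level <- match.arg(level)
  col <- if (level == "B") "level_b" else "level_c"
  map <- unique(brite_map[, c("ko", col)])
  names(map) <- c("ko", "pathway")
  kos <- colnames(ko_counts)
  mapped <- map[map$ko %in% kos, , drop = FALSE]
  pathways <- sort(unique(mapped$pathway))
  out <- matrix(0, nrow = nrow(ko_counts), ncol = length(pathways),
                dimnames = list(rownames(ko_counts), pathways))
  for (pw in pathways) {
    members <- mapped$ko[mapped$pathway == pw]
    out[, pw] <- rowSums(ko_counts[, members, drop = FALSE])
  }
  unmapped <- setdiff(kos, map$ko)
  if (length(unmapped)) {
    out <- cbind(out, Unmapped = rowSums(ko_counts[, unmapped, drop = FALSE]))
  }
  mult <- table(mapped$ko)
  mult <- mult[mult > 1L]
  dup_mass <- sum(rowSums(out)) - sum(rowSums(ko_counts))
  list(table = out, multiplicity = mult, duplicated_mass = dup_mass)
}
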