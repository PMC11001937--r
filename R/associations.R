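# Taxa-metabolite association by Spearman correlation with BH control,
# and hypergeometric pathway over-representation for significant
# metabolite sets.

# all permutations of 1..n (lexicographic), as a matrix n! x n
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1] <- i
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The p-value uses the exact permutation distribution of rho for n <= 9
#' (two-sided: proportion of permutations at least as extreme in
#' magnitude), and the t-approximation otherwise.
#'
#' @param x,y paired numeric vectors, n >= 4 after removing incomplete
#'   pairs.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Correlate taxa with metabolites over requested pairs
#'
#' One Spearman correlation per requested (taxon, metabolite) pair, with
#' BH q-values across the whole table. Samples are aligned by id; a
#' mismatch is an error listing the offending ids.
#'
#' @param taxa_abund samples x taxa abundance matrix (counts or
#'   proportions), rownames = sample ids.
#' @param metabolite_matrix samples x metabolites matrix, rownames =
#'   sample ids.
#' @param pairs data frame with columns `taxon` and `metabolite`.
#' @return data frame: taxon, metabolite, rho, p, q, n.
#' @export
correlate_blocks <- function(taxa_abund, metabolite_matrix, pairs) {
  if (!nrow(pairs)) {
    return(data.frame(taxon = character(), metabolite = character(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      n = integer()))
  }
  common <- intersect(rownames(taxa_abund), rownames(metabolite_matrix))
  only_t <- setdiff(rownames(taxa_abund), common)
  only_m <- setdiff(rownames(metabolite_matrix), common)
  if (length(only_t) || length(only_m)) {
    stop("sample sets differ between blocks; unmatched ids: ",
         paste(utils::head(c(only_t, only_m), 10), collapse = ", "))
  }
  ta <- taxa_abund[common, , drop = FALSE]
  mm <- metabolite_matrix[common, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tx <- pairs$taxon[i]; mb <- pairs$metabolite[i]
    if (!tx %in% colnames(ta)) stop("unknown taxon: ", tx)
    if (!mb %in% colnames(mm)) stop("unknown metabolite: ", mb)
    r <- suppressWarnings(spearman_cor(ta[, tx], mm[, mb]))
    data.frame(taxon = tx, metabolite = mb, rho = r$rho, p = r$p, n = r$n)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[, c("taxon", "metabolite", "rho", "p", "q", "n")]
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of observing `k = |hits inside the
#' pathway|` when `|hits|` metabolites are drawn without replacement from
#' a universe of size `N` containing `K` pathway members.
#'
#' @param hits character vector of significant metabolites (subset of the
#'   universe).
#' @param members pathway member metabolites.
#' @param universe background metabolite universe.
#' @return list: `p`, `k` (overlap), `K`, `n` (number of hits), `N`.
#' @export
hypergeom_ora <- function(hits, members, universe) {
  if (!all(hits %in% universe)) {
    stop("hits outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  }
  members <- intersect(members, universe)
  N <- length(unique(universe))
  K <- length(unique(members))
  n <- length(unique(hits))
  k <- length(intersect(unique(hits), members))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, K = K, n = n, N = N)
}

#' Pathway enrichment over a collection of sets
#'
#' Hypergeometric upper-tail p per pathway and BH q across pathways,
#' sorted by q then p.
#'
#' @param hits significant metabolites.
#' @param pathway_sets named list of member vectors.
#' @param universe background universe (default: union of all pathway
#'   members and hits — in practice, all annotated measured metabolites).
#' @return data frame: pathway, k, K, n, N, p, q.
#' @export
enrich_all <- function(hits, pathway_sets,
                       universe = unique(c(unlist(pathway_sets), hits))) {
  if (!length(pathway_sets)) {
    return(data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  }
  rows <- lapply(names(pathway_sets), function(pw) {
    r <- hypergeom_ora(hits, pathway_sets[[pw]], universe)
    data.frame(pathway = pw, k = r$k, K = r$K, n = r$n, N = r$N, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$q, out$p, out$pathway), , drop = FALSE]
}

#' Build pathway sets from a feature annotation table
#'
#' @param annotation data frame with `feature_id` (or `name`) and
#'   `pathway`.
#' @param id_col which column identifies the metabolite.
#' @return named list of member vectors (features without a pathway are
#'   skipped).
#' @export
pathway_sets_from_annotation <- function(annotation, id_col = "feature_id") {
  ann <- annotation[!is.na(annotation$pathway), , drop = FALSE]
  split(ann[[id_col]], ann$pathway)
}
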