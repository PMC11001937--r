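# Per-feature differential abundance by linear mixed models with a family
# random intercept, pairwise generation contrasts, BH FDR control, Venn
# partitioning of the significant sets, and the linear-model test used for
# functional (KO / BRITE) tables.

#' Fit the family-random-intercept mixed model for one feature
#'
#' Model: value = mu + generation (fixed) + family (random intercept) +
#' residual, fitted by REML. The overall generation effect is tested by a
#' likelihood-ratio test of maximum-likelihood fits against the
#' intercept-only model; pairwise contrasts are Wald tests with
#' Satterthwaite degrees of freedom. A singular fit (family variance
#' estimated at the boundary) is returned with `singular = TRUE`, never as
#' a silent failure.
#'
#' @param values numeric response vector.
#' @param generation factor with levels Infant / Mother / Grandmother (or
#'   any >= 2-level grouping).
#' @param family_id family identifier (random-intercept grouping).
#' @return one-row data frame: overall LRT p, per-contrast estimates and
#'   p-values, variance components, flags.
#' @export
fit_lmm_feature <- function(values, generation, family_id) {
  generation <- droplevels(factor(generation))
  if (nlevels(generation) < 2L) stop("need at least 2 generations")
  if (length(unique(family_id)) < 2L) stop("need at least 2 families")
  dat <- data.frame(y = values, g = generation, fam = factor(family_id))
  dat <- dat[stats::complete.cases(dat), ]
  lv <- levels(generation)
  contrast_names <- utils::combn(lv, 2, function(z) paste(z[1], z[2], sep = "-"))
  empty <- data.frame(p_overall = NA_real_, var_family = NA_real_,
                      var_resid = NA_real_, singular = NA, failed = TRUE)
  for (cn in contrast_names) {
    empty[[paste0("est_", cn)]] <- NA_real_
    empty[[paste0("p_", cn)]] <- NA_real_
  }
  if (nrow(dat) < 4L || stats::sd(dat$y) == 0) return(empty)

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      y ~ g + (1 | fam), data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit)) return(empty)
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_family <- vc$vcov[vc$grp == "fam"]
  var_resid <- vc$vcov[vc$grp == "Residual"]

  # overall generation effect: LRT of nested ML fits
  m1 <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ g + (1 | fam), data = dat, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)
  m0 <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ 1 + (1 | fam), data = dat, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)
  p_overall <- if (!is.null(m1) && !is.null(m0)) {
    lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0))))
    stats::pchisq(lr, df = nlevels(generation) - 1L, lower.tail = FALSE)
  } else NA_real_

  out <- data.frame(p_overall = p_overall, var_family = var_family,
                    var_resid = var_resid, singular = singular, failed = FALSE)
  # pairwise contrasts on the fixed effects (treatment coding, level 1 ref)
  nb <- length(lme4::fixef(fit))
  for (ci in seq_along(contrast_names)) {
    pair <- utils::combn(lv, 2)[, ci]
    L <- numeric(nb)
    i1 <- match(pair[1], lv); i2 <- match(pair[2], lv)
    if (i1 > 1L) L[i1] <- 1
    if (i2 > 1L) L[i2] <- -1
    ct <- tryCatch(lmerTest::contest1D(fit, L, ddf = "Satterthwaite"),
                   error = function(e) NULL)
    cn <- contrast_names[ci]
    if (is.null(ct)) {
      out[[paste0("est_", cn)]] <- NA_real_
      out[[paste0("p_", cn)]] <- NA_real_
    } else {
      out[[paste0("est_", cn)]] <- ct$Estimate
      out[[paste0("p_", cn)]] <- ct$`Pr(>|t|)`
    }
  }
  out
}

#' Mixed-model differential abundance across all features
#'
#' Fits [fit_lmm_feature()] per feature and applies BH FDR per contrast
#' (and to the overall test) across features.
#'
#' @param matrix samples x features matrix.
#' @param generation,family_id aligned sample annotations.
#' @param alpha FDR significance threshold used for the reported
#'   significant sets.
#' @return object of class `lmm_results`: results data frame (one row per
#'   feature), `significant` sets per contrast at `alpha`, the threshold.
#' @export
lmm_all_features <- function(matrix, generation, family_id, alpha = 0.05) {
  stopifnot(nrow(matrix) == length(generation),
            nrow(matrix) == length(family_id))
  rows <- lapply(seq_len(ncol(matrix)), function(j) {
    r <- fit_lmm_feature(matrix[, j], generation, family_id)
    r$feature_id <- colnames(matrix)[j]
    r
  })
  res <- do.call(rbind, rows)
  res <- res[, c("feature_id", setdiff(names(res), "feature_id"))]
  res$q_overall <- bh_fdr(res$p_overall)
  pcols <- grep("^p_(?!overall)", names(res), perl = TRUE, value = TRUE)
  sig <- list()
  for (pc in pcols) {
    qc <- sub("^p_", "q_", pc)
    res[[qc]] <- bh_fdr(res[[pc]])
    sig[[sub("^p_", "", pc)]] <-
      res$feature_id[!is.na(res[[qc]]) & res[[qc]] < alpha]
  }
  structure(list(results = res, significant = sig, alpha = alpha),
            class = "lmm_results")
}

#' @export
print.lmm_results <- function(x, ...) {
  cat("Mixed-model differential abundance:", nrow(x$results), "features\n")
  cat("  significant overall (q <", x$alpha, "):",
      sum(x$results$q_overall < x$alpha, na.rm = TRUE), "\n")
  for (cn in names(x$significant)) {
    cat(sprintf("  %-24s %d\n", cn, length(x$significant[[cn]])))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` entries are passed through.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values, monotone in p.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Venn partition of three significant sets
#'
#' @param sets named list of three character vectors over a common
#'   universe.
#' @return named integer vector with the 7 region counts (`A_only`, ...,
#'   `ABC`), plus the per-set totals as an attribute check.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3L)
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
  u <- unique(c(a, b, c))
  inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
  region <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""), ifelse(inC, "C", ""))
  counts <- c(A_only = sum(region == "A"), B_only = sum(region == "B"),
              C_only = sum(region == "C"), AB = sum(region == "AB"),
              AC = sum(region == "AC"), BC = sum(region == "BC"),
              ABC = sum(region == "ABC"))
  # reconciliation: region sums must rebuild the set sizes
  stopifnot(counts[["A_only"]] + counts[["AB"]] + counts[["AC"]] + counts[["ABC"]] == length(unique(a)),
            counts[["B_only"]] + counts[["AB"]] + counts[["BC"]] + counts[["ABC"]] == length(unique(b)),
            counts[["C_only"]] + counts[["AC"]] + counts[["BC"]] + counts[["ABC"]] == length(unique(c)))
  attr(counts, "set_names") <- names(sets)
  counts
}

#' Linear-model test for functional tables
#'
#' Per-column ordinary linear model with a generation term (the test used
#' for TMM-normalized KO / BRITE abundance tables), overall F-test p-value,
#' BH adjustment and a significance flag at `max_sig`. Constant columns
#' are excluded with a flag.
#'
#' @param table samples x features (KO or pathway) numeric matrix.
#' @param generation aligned grouping factor.
#' @param max_sig adjusted-p significance ceiling (default 0.10).
#' @return data frame: feature_id, p, q, significant, constant.
#' @export
lm_test_functional <- function(table, generation, max_sig = 0.10) {
  generation <- droplevels(factor(generation))
  stopifnot(nrow(table) == length(generation))
  p <- vapply(seq_len(ncol(table)), function(j) {
    y <- table[, j]
    if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0) return(NA_real_)
    fit <- stats::lm(y ~ generation)
    f <- summary(fit)$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }, numeric(1))
  q <- bh_fdr(p)
  data.frame(feature_id = colnames(table), p = p, q = q,
             significant = !is.na(q) & q <= max_sig,
             constant = is.na(p), row.names = NULL)
}
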