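# Chemometric latent-variable models: unit-variance scaling, PCA with
# per-component explained variance, NIPALS PLS-DA with cross-validated Q2,
# and a QC-dispersion diagnostic for pooled-QC clustering.

#' Unit-variance (UV) autoscaling
#'
#' Centers every feature to mean 0 and scales to standard deviation 1.
#' Zero-variance features cannot be scaled and are dropped with a warning.
#'
#' @param x samples x features matrix.
#' @return scaled matrix with `center`/`scale` attributes.
#' @export
uv_scale <- function(x) {
  x <- as.matrix(x)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s): ",
            paste(utils::head(colnames(x)[zero], 5), collapse = ", "))
    x <- x[, !zero, drop = FALSE]
    sdv <- sdv[!zero]
  }
  mu <- colMeans(x, na.rm = TRUE)
  out <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

# fix component signs so the largest-|loading| entry is positive
fix_signs <- function(scores, loadings) {
  for (h in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, h]))
    if (loadings[i, h] < 0) {
      loadings[, h] <- -loadings[, h]
      scores[, h] <- -scores[, h]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis
#'
#' Thin wrapper around the singular value decomposition of the centered
#' (optionally UV-scaled) matrix, reporting per-component explained
#' variance fractions. Component signs are fixed so that the
#' largest-magnitude loading of each component is positive.
#'
#' @param x samples x features matrix, no missing values.
#' @param ncomp number of components (<= min(n-1, p)).
#' @param scale UV-scale the matrix first (default TRUE).
#' @return object of class `triomics_pca`: `scores`, `loadings`, `r2`
#'   (explained-variance fractions).
#' @export
pca_model <- function(x, ncomp = 2L, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA input must not contain missing values")
  maxc <- min(nrow(x) - 1L, ncol(x))
  if (ncomp > maxc) stop("ncomp must be <= ", maxc)
  xs <- if (scale) uv_scale(x) else sweep(x, 2, colMeans(x))
  sv <- svd(xs, nu = ncomp, nv = ncomp)
  scores <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(xs), paste0("PC", seq_len(ncomp)))
  fs <- fix_signs(scores, loadings)
  r2 <- sv$d[seq_len(ncomp)]^2 / sum(sv$d^2)
  structure(list(scores = fs$scores, loadings = fs$loadings,
                 r2 = stats::setNames(r2, paste0("PC", seq_len(ncomp))),
                 center = attr(xs, "center"), scale = attr(xs, "scale")),
            class = "triomics_pca")
}

#' @export
print.triomics_pca <- function(x, ...) {
  cat("PCA model:", nrow(x$scores), "samples,", nrow(x$loadings), "features\n")
  cat("  R2 per component:", paste(sprintf("%.3f", x$r2), collapse = ", "), "\n")
  invisible(x)
}

# NIPALS PLS2 on centered matrices; returns W, P, C (Y-weights), scores
nipals_pls <- function(X, Y, ncomp, tol = 1e-9, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  Xr <- X; Yr <- Y
  for (h in seq_len(ncomp)) {
    u <- Yr[, which.max(apply(Yr, 2, stats::var)), drop = FALSE]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xr, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- Xr %*% w
      cc <- crossprod(Yr, tt)[, 1] / sum(tt^2)
      u <- Yr %*% cc / sum(cc^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    tt <- Xr %*% w
    pp <- crossprod(Xr, tt)[, 1] / sum(tt^2)
    cc <- crossprod(Yr, tt)[, 1] / sum(tt^2)
    Xr <- Xr - tt %*% t(pp)
    Yr <- Yr - tt %*% t(cc)
    W[, h] <- w; P[, h] <- pp; C[, h] <- cc; TT[, h] <- tt
  }
  list(W = W, P = P, C = C, scores = TT, Xres = Xr, Yres = Yr)
}

# regression coefficients mapping centered X to centered Y
pls_coef <- function(fit, ncomp) {
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  C <- fit$C[, seq_len(ncomp), drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))
  Wstar %*% t(C)
}

dummy_code <- function(labels) {
  f <- factor(labels)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  Y
}

# stratified fold ids: venetian blinds within each class stratum
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  id
}

#' PLS discriminant analysis with cross-validated Q2
#'
#' NIPALS PLS2 on a dummy-coded class response. R2Y is the fraction of
#' response variance explained by the fitted model; Q2 is the
#' cross-validated `1 - PRESS/TSS`, with stratified venetian-blind folds
#' (class strata interleaved deterministically, or shuffled when `shuffle`
#' is TRUE so that repeated CV varies).
#'
#' @param x samples x features matrix.
#' @param labels class labels (>= 2 classes, each at least `folds` members
#'   for cross-validation).
#' @param ncomp number of latent components.
#' @param folds number of CV folds (default 7).
#' @param repeats CV repeats (fold assignment reshuffled when > 1).
#' @param scale UV-scale within the model (and within each training fold).
#' @param shuffle randomize the within-class sample order before blinds.
#' @return object of class `triomics_plsda`: scores, loadings, `r2y`,
#'   `r2x`, `q2` (mean over repeats), `q2_repeats`, class assignments.
#' @export
plsda <- function(x, labels, ncomp = 2L, folds = 7L, repeats = 1L,
                  scale = TRUE, shuffle = repeats > 1L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("PLS-DA needs at least 2 classes")
  loo <- folds == length(labels)
  if (!loo && min(table(labels)) < folds) {
    stop("every class needs at least `folds` members (or folds = n for leave-one-out)")
  }
  xs <- if (scale) uv_scale(x) else sweep(x, 2, colMeans(x))
  Y <- dummy_code(labels)
  Yc <- sweep(Y, 2, colMeans(Y))
  fit <- nipals_pls(xs, Yc, ncomp)
  # explained variance
  ssx <- sum(xs^2); ssy <- sum(Yc^2)
  r2x <- 1 - sum(fit$Xres^2) / ssx
  r2y <- 1 - sum(fit$Yres^2) / ssy
  # cross-validated Q2
  q2r <- numeric(repeats)
  for (r in seq_len(repeats)) {
    ord <- seq_along(labels)
    if (shuffle) ord <- sample(ord)
    fold_id <- integer(length(labels))
    if (loo) fold_id <- seq_along(labels)
    else fold_id[ord] <- stratified_folds(labels[ord], folds)
    press <- tss <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- if (scale) apply(x[tr, , drop = FALSE], 2, stats::sd) else rep(1, ncol(x))
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
      Xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, `/`)
      Ymu <- colMeans(Y[tr, , drop = FALSE])
      Ytr <- sweep(Y[tr, , drop = FALSE], 2, Ymu)
      B <- pls_coef(nipals_pls(Xtr, Ytr, ncomp), ncomp)
      Yhat <- Xte %*% B
      press <- press + sum((sweep(Y[te, , drop = FALSE], 2, Ymu) - Yhat)^2)
      tss <- tss + sum(sweep(Y[te, , drop = FALSE], 2, Ymu)^2)
    }
    q2r[r] <- 1 - press / tss
  }
  scores <- fit$scores
  loadings <- fit$P
  dimnames(scores) <- list(rownames(x), paste0("comp", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(xs), paste0("comp", seq_len(ncomp)))
  fs <- fix_signs(scores, loadings)
  structure(list(scores = fs$scores, loadings = fs$loadings,
                 weights = fit$W, y_weights = fit$C, labels = labels,
                 r2x = r2x, r2y = r2y, q2 = mean(q2r), q2_repeats = q2r,
                 ncomp = ncomp, folds = folds),
            class = "triomics_plsda")
}

#' @export
print.triomics_plsda <- function(x, ...) {
  cat("PLS-DA model:", nrow(x$scores), "samples,",
      nlevels(x$labels), "classes,", x$ncomp, "components\n")
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 (%d-fold CV) = %.3f\n",
              x$r2x, x$r2y, x$folds, x$q2))
  invisible(x)
}

#' QC-dispersion ratio in score space
#'
#' Mean squared distance of QC scores to the QC centroid divided by the
#' same quantity for study samples. Values well below 1 indicate the tight
#' central QC cluster expected after successful normalization.
#'
#' @param model a `triomics_pca` (or any object with a `scores` matrix).
#' @param roles character vector aligned with score rows; `"qc"` rows are
#'   the pooled QCs, `"study"` rows the biological samples.
#' @return the dispersion ratio (numeric scalar).
#' @export
qc_dispersion <- function(model, roles) {
  scores <- model$scores
  stopifnot(length(roles) == nrow(scores))
  qc <- roles == "qc"; st <- roles == "study"
  if (sum(qc) < 2L) stop("need at least 2 QC injections in the scores")
  msd <- function(s) {
    ctr <- colMeans(s)
    mean(rowSums(sweep(s, 2, ctr)^2))
  }
  msd(scores[qc, , drop = FALSE]) / msd(scores[st, , drop = FALSE])
}
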