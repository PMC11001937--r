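# Multiblock sparse PLS-DA integration (DIABLO-style): alternating
# maximization of design-weighted covariance among block scores and the
# class-indicator scores, with exact-cardinality sparsity per block, block
# deflation, repeated cross-validation, per-block one-vs-all AUROC, a
# similarity (circos) matrix over the selected variables, and clustered
# image maps.

# keep the keepx largest-|v| entries, soft-thresholded; ties at the
# threshold broken by position (first index wins) for determinism
soft_threshold_keep <- function(v, keepx) {
  if (keepx >= length(v)) return(v)
  av <- abs(v)
  ord <- order(av, seq_along(av), decreasing = TRUE)
  lambda <- av[ord[keepx + 1L]]
  keep_idx <- ord[seq_len(keepx)]
  out <- numeric(length(v))
  out[keep_idx] <- sign(v[keep_idx]) * (av[keep_idx] - lambda)
  # a tie across the threshold can zero a kept entry; fall back to hard
  # selection of the top keepx in that degenerate case
  if (sum(out != 0) < min(keepx, sum(av > 0))) {
    out <- numeric(length(v))
    out[keep_idx] <- v[keep_idx]
  }
  out
}

build_design <- function(design, n_blocks) {
  if (is.matrix(design)) {
    stopifnot(nrow(design) == n_blocks + 1L, ncol(design) == n_blocks + 1L)
    return(design)
  }
  d <- matrix(1, n_blocks + 1L, n_blocks + 1L)
  diag(d) <- 0
  if (identical(design, "null")) {
    d[seq_len(n_blocks), seq_len(n_blocks)] <- 0
  } else if (!identical(design, "full")) {
    stop("design must be 'full', 'null' or a (B+1) x (B+1) matrix")
  }
  d
}

#' Multiblock sparse PLS discriminant analysis
#'
#' Latent components are found by alternating maximization of the
#' design-weighted covariance among block scores and the score of the
#' dummy-coded outcome; sparsity is enforced by retaining exactly `keepX`
#' largest-magnitude loading entries per block and component
#' (soft-thresholded, ties broken by variable order). Blocks are deflated
#' by their own scores after each component, so successive scores within a
#' block are orthogonal.
#'
#' @param blocks named list of samples x variables matrices sharing row
#'   order (sample ids).
#' @param labels class labels (>= 2 classes).
#' @param ncomp number of components.
#' @param keepX variables to keep per block per component; scalar or
#'   vector over blocks; capped at the block width.
#' @param design `"full"` (all blocks connected to each other and to the
#'   outcome, weight 1 — the default), `"null"` (blocks connected to the
#'   outcome only), or an explicit (B+1) x (B+1) weight matrix with the
#'   outcome last.
#' @param scale UV-scale each block (default TRUE).
#' @param tol convergence tolerance on the loading change.
#' @param max_iter maximum alternating iterations per component.
#' @return object of class `block_splsda`: per-block `loadings`, `scores`,
#'   `selected` variable sets, deflation loadings, centers/scales, the
#'   outcome weights, design matrix, and per-component cross-block score
#'   correlations.
#' @export
block_splsda <- function(blocks, labels, ncomp = 2L, keepX = 25L,
                         design = "full", scale = TRUE, tol = 1e-6,
                         max_iter = 500L) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  n <- nrow(blocks[[1]])
  ids <- rownames(blocks[[1]])
  for (b in names(blocks)) {
    if (nrow(blocks[[b]]) != n) stop("blocks have different sample counts")
    if (!is.null(ids) && !identical(rownames(blocks[[b]]), ids)) {
      stop("blocks must share the same sample ids in the same order")
    }
  }
  B <- length(blocks)
  keepX <- rep_len(keepX, B)
  C <- build_design(design, B)

  Xs <- vector("list", B); names(Xs) <- names(blocks)
  centers <- scales <- vector("list", B)
  for (b in seq_len(B)) {
    x <- as.matrix(blocks[[b]])
    mu <- colMeans(x)
    sdv <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xs[[b]] <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
    centers[[b]] <- mu; scales[[b]] <- sdv
    keepX[b] <- min(keepX[b], ncol(x))
  }
  Y <- dummy_code(labels)
  Y <- sweep(Y, 2, colMeans(Y))
  Y <- sweep(Y, 2, apply(Y, 2, stats::sd), `/`)

  loadings <- lapply(Xs, function(x) matrix(0, ncol(x), ncomp,
                                            dimnames = list(colnames(x), NULL)))
  defl <- lapply(Xs, function(x) matrix(0, ncol(x), ncomp))
  scores <- lapply(Xs, function(x) matrix(0, n, ncomp,
                                          dimnames = list(ids, NULL)))
  y_load <- matrix(0, ncol(Y), ncomp)
  y_scores <- matrix(0, n, ncomp)
  Xr <- Xs
  converged <- logical(ncomp)

  lead_sv <- function(x) {
    v <- svd(x, nu = 0, nv = 1)$v[, 1]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    v
  }

  for (h in seq_len(ncomp)) {
    a <- lapply(Xr, lead_sv)
    ay <- lead_sv(Y)
    obj_old <- -Inf
    for (it in seq_len(max_iter)) {
      tb <- mapply(function(x, v) as.numeric(x %*% v), Xr, a, SIMPLIFY = FALSE)
      u <- as.numeric(Y %*% ay)
      a_new <- a
      for (b in seq_len(B)) {
        inner <- numeric(n)
        for (k in seq_len(B)) if (k != b) inner <- inner + C[b, k] * tb[[k]]
        inner <- inner + C[b, B + 1L] * u
        v <- as.numeric(crossprod(Xr[[b]], inner))
        v <- soft_threshold_keep(v, keepX[b])
        nv <- sqrt(sum(v^2))
        if (nv > 0) v <- v / nv
        a_new[[b]] <- v
        tb[[b]] <- as.numeric(Xr[[b]] %*% v)
      }
      inner_y <- numeric(n)
      for (k in seq_len(B)) inner_y <- inner_y + C[B + 1L, k] * tb[[k]]
      ay_new <- as.numeric(crossprod(Y, inner_y))
      ay_new <- ay_new / sqrt(sum(ay_new^2))
      delta <- max(c(mapply(function(x, y) sqrt(sum((x - y)^2)), a, a_new),
                     sqrt(sum((ay - ay_new)^2))))
      # near-tied variables at the sparsity threshold can swap in and out
      # indefinitely while the criterion value sits at its maximum;
      # stagnation of the maximized objective (design-weighted covariance
      # of the block and outcome scores) is then the meaningful criterion
      u_new <- as.numeric(Y %*% ay_new)
      obj <- 0
      for (b in seq_len(B)) {
        for (k in seq_len(B)) if (k > b) obj <- obj + C[b, k] * sum(tb[[b]] * tb[[k]])
        obj <- obj + C[b, B + 1L] * sum(tb[[b]] * u_new)
      }
      obj_delta <- if (is.finite(obj_old)) {
        abs(obj - obj_old) / max(abs(obj_old), 1e-12)
      } else Inf
      obj_old <- obj
      a <- a_new; ay <- ay_new
      if (delta < tol || obj_delta < tol) { converged[h] <- TRUE; break }
    }
    if (!converged[h]) {
      stop("multiblock sPLS-DA did not converge for component ", h,
           " within ", max_iter, " iterations (last change ",
           format(delta, digits = 3), ")")
    }
    # deterministic joint sign: anchor block 1 (largest |loading| positive),
    # other blocks aligned so their scores correlate positively with it
    t1 <- as.numeric(Xr[[1]] %*% a[[1]])
    i <- which.max(abs(a[[1]]))
    if (a[[1]][i] < 0) { a[[1]] <- -a[[1]]; t1 <- -t1 }
    for (b in seq_len(B)) {
      tbv <- as.numeric(Xr[[b]] %*% a[[b]])
      if (b > 1L && sum(tbv * t1) < 0) { a[[b]] <- -a[[b]]; tbv <- -tbv }
      scores[[b]][, h] <- tbv
      loadings[[b]][, h] <- a[[b]]
      p <- as.numeric(crossprod(Xr[[b]], tbv)) / sum(tbv^2)
      defl[[b]][, h] <- p
      Xr[[b]] <- Xr[[b]] - tbv %*% t(p)
    }
    u <- as.numeric(Y %*% ay)
    if (sum(u * t1) < 0) { ay <- -ay; u <- -u }
    y_load[, h] <- ay
    y_scores[, h] <- u
  }
  selected <- lapply(loadings, function(L) {
    lapply(seq_len(ncomp), function(h) rownames(L)[L[, h] != 0])
  })
  # cross-block score correlations per component
  cors <- lapply(seq_len(ncomp), function(h) {
    s <- sapply(scores, function(s) s[, h])
    stats::cor(s)
  })
  structure(list(loadings = loadings, scores = scores, selected = selected,
                 deflation = defl, centers = centers, scales = scales,
                 y_loadings = y_load, y_scores = y_scores, design = C,
                 labels = labels, keepX = keepX, ncomp = ncomp,
                 block_names = names(blocks), scale = scale,
                 score_correlations = cors),
            class = "block_splsda")
}

#' @export
print.block_splsda <- function(x, ...) {
  cat("Multiblock sparse PLS-DA:", length(x$block_names), "blocks,",
      x$ncomp, "components, keepX =", paste(x$keepX, collapse = "/"), "\n")
  c1 <- x$score_correlations[[1]]
  cat("  component-1 cross-block score correlations:\n")
  for (i in seq_len(nrow(c1) - 1L)) for (j in (i + 1L):ncol(c1)) {
    cat(sprintf("    %s ~ %s: %.3f\n", rownames(c1)[i], colnames(c1)[j], c1[i, j]))
  }
  invisible(x)
}

# project new blocks through the stored deflation sequence
project_blocks <- function(model, newblocks) {
  B <- length(model$block_names)
  out <- vector("list", B); names(out) <- model$block_names
  for (b in seq_len(B)) {
    x <- as.matrix(newblocks[[model$block_names[b]]])
    x <- sweep(sweep(x, 2, model$centers[[b]]), 2, model$scales[[b]], `/`)
    tt <- matrix(0, nrow(x), model$ncomp)
    for (h in seq_len(model$ncomp)) {
      tt[, h] <- x %*% model$loadings[[b]][, h]
      x <- x - tt[, h] %*% t(model$deflation[[b]][, h])
    }
    out[[b]] <- tt
  }
  out
}

#' Predict classes from a multiblock model
#'
#' Test samples are projected through the per-block deflation sequence;
#' each block votes for the class whose training score centroid is
#' nearest (Euclidean); the majority vote wins, ties broken by the
#' smallest mean distance across blocks.
#'
#' @param object a `block_splsda` model.
#' @param newblocks named list of new block matrices (same variables).
#' @param ... unused.
#' @return list: `class` (factor), `votes` (samples x blocks),
#'   `scores` (projected per block).
#' @export
predict.block_splsda <- function(object, newblocks, ...) {
  proj <- project_blocks(object, newblocks)
  lv <- levels(object$labels)
  centroids <- lapply(object$scores, function(s) {
    ctr <- vapply(lv, function(cl) colMeans(s[object$labels == cl, , drop = FALSE]),
                  numeric(object$ncomp))
    t(matrix(ctr, nrow = object$ncomp, dimnames = list(NULL, lv)))
  })
  n <- nrow(proj[[1]])
  votes <- matrix("", n, length(proj),
                  dimnames = list(NULL, object$block_names))
  dists <- array(0, c(n, length(lv), length(proj)))
  for (b in seq_along(proj)) {
    d <- sapply(lv, function(cl) {
      sqrt(rowSums(sweep(proj[[b]], 2, centroids[[b]][cl, ])^2))
    })
    d <- matrix(d, nrow = n)
    dists[, , b] <- d
    votes[, b] <- lv[apply(d, 1, which.min)]
  }
  cls <- character(n)
  mean_d <- apply(dists, c(1, 2), mean)
  for (i in seq_len(n)) {
    tab <- table(factor(votes[i, ], levels = lv))
    top <- lv[tab == max(tab)]
    cls[i] <- if (length(top) == 1L) top else top[which.min(mean_d[i, match(top, lv)])]
  }
  list(class = factor(cls, levels = lv), votes = votes, scores = proj)
}

#' Repeated stratified cross-validation of a multiblock model
#'
#' Stratified `folds`-fold cross-validation repeated `repeats` times;
#' per-repeat overall classification error (majority vote across blocks)
#' and its mean and standard deviation. Fold assignment is drawn from the
#' current RNG state, so a fixed seed reproduces folds exactly.
#'
#' @param blocks,labels,ncomp,keepX,design,scale as [block_splsda()].
#' @param folds,repeats CV layout (every class needs >= `folds` members).
#' @param seed optional integer seed for the fold draws.
#' @return object of class `block_splsda_perf`: `error_rates` per repeat,
#'   `mean_error`, `sd_error`, per-class error means.
#' @export
perf_cv <- function(blocks, labels, ncomp = 2L, keepX = 25L,
                    design = "full", scale = TRUE, folds = 5L,
                    repeats = 10L, seed = NULL) {
  labels <- factor(labels)
  if (min(table(labels)) < folds) {
    stop("every class needs at least `folds` (", folds, ") members")
  }
  if (!is.null(seed)) set.seed(seed)
  err <- numeric(repeats)
  class_err <- matrix(0, repeats, nlevels(labels),
                      dimnames = list(NULL, levels(labels)))
  for (r in seq_len(repeats)) {
    fold_id <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- block_splsda(lapply(blocks, function(x) x[tr, , drop = FALSE]),
                        labels[tr], ncomp = ncomp, keepX = keepX,
                        design = design, scale = scale)
      pr <- predict(m, lapply(blocks, function(x) x[!tr, , drop = FALSE]))
      pred[!tr] <- pr$class
    }
    err[r] <- mean(pred != labels)
    for (cl in levels(labels)) {
      class_err[r, cl] <- mean(pred[labels == cl] != cl)
    }
  }
  structure(list(error_rates = err, mean_error = mean(err),
                 sd_error = stats::sd(err),
                 class_error = colMeans(class_err),
                 folds = folds, repeats = repeats),
            class = "block_splsda_perf")
}

#' @export
print.block_splsda_perf <- function(x, ...) {
  cat(sprintf("Multiblock CV (%d-fold x %d): error %.3f +/- %.3f\n",
              x$folds, x$repeats, x$mean_error,
              ifelse(is.na(x$sd_error), 0, x$sd_error)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Mid-rank normalized Mann-Whitney U statistic: ties contribute half.
#'
#' @param score numeric classifier score (larger = more positive).
#' @param positive logical vector marking the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-block one-vs-all AUROC of a multiblock model
#'
#' For every block and class, samples are scored by their projection onto
#' the direction from the rest-centroid to the class centroid in the
#' block's component space, and the mid-rank AUC of that one-vs-all
#' contrast is reported.
#'
#' @param model a `block_splsda` model.
#' @return data frame: block, contrast, auc.
#' @export
model_auroc <- function(model) {
  lv <- levels(model$labels)
  rows <- list()
  for (b in model$block_names) {
    s <- model$scores[[b]]
    for (cl in lv) {
      pos <- model$labels == cl
      dir <- colMeans(s[pos, , drop = FALSE]) - colMeans(s[!pos, , drop = FALSE])
      sc <- as.numeric(s %*% dir)
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, contrast = paste(cl, "vs Others"),
        auc = auroc(sc, pos))
    }
  }
  do.call(rbind, rows)
}

#' Similarity matrix over the selected variables
#'
#' Association between selected variables i (block b) and j (block k) is
#' the sum over components of the products of their correlations with the
#' averaged block-pair score `z_h = (t_bh + t_kh) / 2` — the
#' similarity-matrix construction behind circos displays of multiblock
#' models. Only pairs with `|similarity| > cutoff` are returned, signed;
#' the diagonal (a variable with itself) is excluded.
#'
#' @param model a `block_splsda` model.
#' @param blocks the original block matrices the model was fitted on.
#' @param cutoff absolute-similarity threshold (default 0.65).
#' @return data frame: var1, block1, var2, block2, similarity.
#' @export
similarity_matrix <- function(model, blocks, cutoff = 0.65) {
  B <- length(model$block_names)
  sel <- lapply(seq_len(B), function(b) {
    unique(unlist(model$selected[[b]]))
  })
  scaled <- lapply(seq_len(B), function(b) {
    x <- as.matrix(blocks[[model$block_names[b]]])[, sel[[b]], drop = FALSE]
    sweep(sweep(x, 2, model$centers[[b]][sel[[b]]]), 2,
          model$scales[[b]][sel[[b]]], `/`)
  })
  edges <- list()
  for (b in seq_len(B)) for (k in b:B) {
    # correlations with the averaged pair scores, per component
    simsum <- 0
    for (h in seq_len(model$ncomp)) {
      z <- (model$scores[[b]][, h] + model$scores[[k]][, h]) / 2
      cb <- as.numeric(stats::cor(scaled[[b]], z))
      ck <- as.numeric(stats::cor(scaled[[k]], z))
      simsum <- simsum + outer(cb, ck)
    }
    dimnames(simsum) <- list(sel[[b]], sel[[k]])
    for (i in seq_along(sel[[b]])) {
      jstart <- if (b == k) i + 1L else 1L
      if (jstart > length(sel[[k]])) next
      for (j in jstart:length(sel[[k]])) {
        if (abs(simsum[i, j]) > cutoff) {
          edges[[length(edges) + 1L]] <- data.frame(
            var1 = sel[[b]][i], block1 = model$block_names[b],
            var2 = sel[[k]][j], block2 = model$block_names[k],
            similarity = simsum[i, j])
        }
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(var1 = character(), block1 = character(),
                      var2 = character(), block2 = character(),
                      similarity = numeric()))
  }
  do.call(rbind, edges)
}

#' Clustered image map of the selected variables
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' samples x selected-variables matrix on both axes. Leaf order is
#' deterministic: rows and columns are sorted by id before clustering so
#' equal-distance merges resolve identically across runs.
#'
#' @param model a `block_splsda` model.
#' @param blocks the original block matrices.
#' @return object of class `triomics_cim`: ordered `matrix`,
#'   `row_hclust` (samples), `col_hclust` (variables).
#' @export
cim_cluster <- function(model, blocks) {
  mats <- lapply(seq_along(model$block_names), function(b) {
    sel <- unique(unlist(model$selected[[b]]))
    x <- as.matrix(blocks[[model$block_names[b]]])[, sel, drop = FALSE]
    x <- sweep(sweep(x, 2, model$centers[[b]][sel]), 2,
               model$scales[[b]][sel], `/`)
    colnames(x) <- paste(model$block_names[b], sel, sep = ":")
    x
  })
  m <- do.call(cbind, mats)
  if (nrow(m) < 2L) stop("need at least 2 samples to cluster")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  row_hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                          method = "complete")
  col_hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                          method = "complete")
  structure(list(matrix = m[row_hc$order, col_hc$order],
                 row_hclust = row_hc, col_hclust = col_hc),
            class = "triomics_cim")
}

#' @export
print.triomics_cim <- function(x, ...) {
  cat("Clustered image map:", nrow(x$matrix), "samples x",
      ncol(x$matrix), "selected variables (Euclidean, complete linkage)\n")
  invisible(x)
}

#' Cut the sample dendrogram of a CIM
#'
#' @param cim a `triomics_cim`.
#' @param k number of clusters.
#' @return named integer cluster assignment per sample.
#' @export
cim_cut <- function(cim, k = 2L) {
  stats::cutree(cim$row_hclust, k = k)
}
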