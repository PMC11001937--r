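# Intra-batch drift correction by support-vector regression on the
# interspersed QC injections (QC-SVRC), inter-batch QC-median scaling
# (QC-Norm), and K-nearest-neighbour imputation.

#' Fit per-feature QC drift curves for one batch
#'
#' For every feature, a radial-basis support-vector regression of the
#' interspersed-QC intensity against injection order (normalized to the
#' batch's injection range). Hyperparameters (cost, epsilon as a fraction
#' of the QC median absolute deviation) are chosen by leave-one-QC-out
#' squared error over a small grid. Equilibrium QCs are excluded from the
#' fit. Features whose fitted curve is not strictly positive over the
#' batch fall back to a flat batch-median model and are flagged.
#'
#' @param batch_matrix injections x features matrix for one batch.
#' @param qc_mask logical vector marking the interspersed QC rows.
#' @param injection_orders injection order of every row.
#' @param cost_grid,eps_frac_grid hyperparameter grids.
#' @param gamma RBF kernel width on the normalized order.
#' @param min_qc minimum number of interspersed QCs required.
#' @return object of class `drift_model`: per-feature fits, reference
#'   levels (batch QC medians), order range and flags.
#' @export
qc_svrc_fit <- function(batch_matrix, qc_mask, injection_orders,
                        cost_grid = c(1, 10, 100),
                        eps_frac_grid = c(0.02, 0.1),
                        gamma = 1, min_qc = 5L) {
  stopifnot(length(qc_mask) == nrow(batch_matrix),
            length(injection_orders) == nrow(batch_matrix))
  n_qc <- sum(qc_mask)
  if (n_qc < min_qc) {
    stop("QC-SVRC needs at least ", min_qc, " interspersed QCs per batch; got ", n_qc)
  }
  rng <- range(injection_orders)
  xq <- (injection_orders[qc_mask] - rng[1]) / diff(rng)
  fits <- vector("list", ncol(batch_matrix))
  names(fits) <- colnames(batch_matrix)
  ref <- flat <- numeric(ncol(batch_matrix))
  for (j in seq_len(ncol(batch_matrix))) {
    yq <- batch_matrix[qc_mask, j]
    ok <- !is.na(yq)
    ref[j] <- stats::median(yq[ok])
    if (sum(ok) < min_qc || !is.finite(ref[j]) || ref[j] <= 0 ||
        stats::sd(yq[ok]) == 0) {
      fits[j] <- list(NULL)        # flat model (constant QCs or unusable)
      flat[j] <- TRUE
      next
    }
    x <- xq[ok]; y <- yq[ok] / ref[j]
    md <- stats::mad(y)
    if (md == 0) md <- 1e-3
    best <- NULL; best_err <- Inf
    for (cc in cost_grid) for (ef in eps_frac_grid) {
      eps <- ef * md
      err <- 0
      for (i in seq_along(x)) {
        f <- e1071::svm(x = matrix(x[-i]), y = y[-i], kernel = "radial",
                        gamma = gamma, cost = cc, epsilon = eps,
                        scale = FALSE, type = "eps-regression")
        err <- err + (y[i] - stats::predict(f, matrix(x[i])))^2
      }
      if (err < best_err) {
        best_err <- err
        best <- c(cost = cc, epsilon = eps)
      }
    }
    fit <- e1071::svm(x = matrix(x), y = y, kernel = "radial", gamma = gamma,
                      cost = best[["cost"]], epsilon = best[["epsilon"]],
                      scale = FALSE, type = "eps-regression")
    # the curve must stay positive over the whole batch
    grid <- matrix(seq(0, 1, length.out = 50))
    if (any(stats::predict(fit, grid) <= 0)) {
      fits[j] <- list(NULL)
      flat[j] <- TRUE
    } else {
      fits[[j]] <- fit
    }
  }
  structure(list(fits = fits, reference = stats::setNames(ref, colnames(batch_matrix)),
                 flat = stats::setNames(as.logical(flat), colnames(batch_matrix)),
                 order_range = rng, qc_orders = injection_orders[qc_mask]),
            class = "drift_model")
}

#' Predict the fitted drift factor
#'
#' @param model a `drift_model`.
#' @param feature feature id.
#' @param order injection orders; orders outside the fitted QC range are
#'   clamped to the nearest edge.
#' @return multiplicative drift factor relative to the batch QC median.
#' @export
drift_predict <- function(model, feature, order) {
  f <- model$fits[[feature]]
  if (is.null(f)) return(rep(1, length(order)))
  rng <- model$order_range
  qr <- range(model$qc_orders)
  order <- pmin(pmax(order, qr[1]), qr[2])   # nearest-edge outside QC span
  x <- (order - rng[1]) / diff(rng)
  as.numeric(stats::predict(f, matrix(x)))
}

#' Apply a fitted drift model to one batch
#'
#' Every intensity is divided by the predicted drift factor at its
#' injection order (predicted curve / batch QC median), so corrected
#' values sit on the batch reference level.
#'
#' @param batch_matrix injections x features matrix for one batch.
#' @param model the [qc_svrc_fit()] output for that batch.
#' @param injection_orders injection order per row.
#' @return corrected matrix of the same shape.
#' @export
qc_svrc_apply <- function(batch_matrix, model, injection_orders) {
  stopifnot(inherits(model, "drift_model"))
  missing_f <- setdiff(colnames(batch_matrix), names(model$fits))
  if (length(missing_f)) stop("model does not cover feature(s): ",
                              paste(missing_f, collapse = ", "))
  out <- batch_matrix
  for (j in colnames(batch_matrix)) {
    d <- drift_predict(model, j, injection_orders)
    out[, j] <- batch_matrix[, j] / d
  }
  out
}

#' QC-SVRC over all batches of a study
#'
#' Fits and applies the per-batch drift models on all non-blank
#' injections.
#'
#' @param intensities injections x features matrix.
#' @param injections aligned metadata with `role`, `batch`,
#'   `injection_order`.
#' @param ... passed to [qc_svrc_fit()].
#' @return list: corrected `intensities`, per-batch `models`.
#' @export
svrc_normalize <- function(intensities, injections, ...) {
  check_alignment(intensities, injections)
  out <- intensities
  models <- list()
  for (b in sort(unique(injections$batch))) {
    rows <- injections$batch == b & injections$role != "blank"
    m <- qc_svrc_fit(intensities[rows, , drop = FALSE],
                     qc_mask = injections$role[rows] == "qc",
                     injection_orders = injections$injection_order[rows], ...)
    out[rows, ] <- qc_svrc_apply(intensities[rows, , drop = FALSE], m,
                                 injections$injection_order[rows])
    models[[as.character(b)]] <- m
  }
  list(intensities = out, models = models)
}

#' Inter-batch QC-Norm scaling
#'
#' Per feature, each batch is multiplied by (grand median of all
#' interspersed-QC intensities) / (batch QC median), so the per-feature QC
#' medians agree across batches afterwards. Features with a non-positive
#' QC median in some batch cannot be scaled and are dropped with a flag.
#'
#' @param intensities injections x features matrix (typically the
#'   QC-SVRC-corrected matrix of all batches).
#' @param injections aligned metadata.
#' @return list: `intensities` (scaled, flagged features removed),
#'   `factors` (features x batches scale factors), `excluded`.
#' @export
qc_norm <- function(intensities, injections) {
  check_alignment(intensities, injections)
  qc <- injections$role == "qc"
  if (!any(qc)) stop("no interspersed QC injections present")
  batches <- sort(unique(injections$batch))
  batch_med <- sapply(batches, function(b) {
    apply(intensities[qc & injections$batch == b, , drop = FALSE], 2,
          stats::median, na.rm = TRUE)
  })
  batch_med <- matrix(batch_med, ncol = length(batches),
                      dimnames = list(colnames(intensities), paste0("batch", batches)))
  grand <- apply(intensities[qc, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  bad <- apply(batch_med, 1, function(v) any(!is.finite(v) | v <= 0)) |
    !is.finite(grand) | grand <= 0
  factors <- grand / batch_med           # features x batches
  out <- intensities[, !bad, drop = FALSE]
  for (bi in seq_along(batches)) {
    rows <- injections$batch == batches[bi]
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, factors[!bad, bi], `*`)
  }
  list(intensities = out, factors = factors,
       excluded = colnames(intensities)[bad])
}

#' K-nearest-neighbour imputation
#'
#' Missing entries are replaced by the mean of the `k` nearest samples
#' (Euclidean distance on unit-variance-scaled, mutually observed
#' features); observed entries are untouched.
#'
#' @param matrix samples x features numeric matrix with `NA` gaps.
#' @param k number of neighbours (default 5; must be < number of samples).
#' @return completed matrix.
#' @export
knn_impute <- function(matrix, k = 5L) {
  n <- nrow(matrix)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (any(colSums(!is.na(matrix)) == 0L)) {
    stop("feature(s) missing in all samples cannot be imputed")
  }
  if (any(rowSums(!is.na(matrix)) == 0L)) {
    stop("sample(s) with no observed values cannot be imputed")
  }
  if (!anyNA(matrix)) return(matrix)
  mu <- colMeans(matrix, na.rm = TRUE)
  sdv <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(matrix, 2, mu), 2, sdv, `/`)
  out <- matrix
  for (i in which(rowSums(is.na(matrix)) > 0L)) {
    for (j in which(is.na(matrix[i, ]))) {
      # distance to every other sample over mutually observed features
      d <- vapply(seq_len(n), function(r) {
        if (r == i || is.na(matrix[r, j])) return(Inf)
        shared <- !is.na(z[i, ]) & !is.na(z[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((z[i, shared] - z[r, shared])^2))
      }, numeric(1))
      nb <- order(d)[seq_len(k)]
      nb <- nb[is.finite(d[nb])]
      if (!length(nb)) stop("no usable neighbours for sample ", i, ", feature ", j)
      out[i, j] <- mean(matrix[nb, j])
    }
  }
  out
}
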