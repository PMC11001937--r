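make_batch <- function(n = 60, n_qc = 8, drift = function(o) rep(1, length(o)),
                       base = 100, noise_sd = 0, seed = 1) {
  set.seed(seed)
  lay <- worklist_layout(n, n_equilibrium = 2, n_interspersed = n_qc,
                         n_blanks = 0)
  o <- lay$injection_order
  y <- base * drift(o) * exp(rnorm(length(o), 0, noise_sd))
  m <- matrix(y, ncol = 1, dimnames = list(NULL, "f1"))
  list(m = m, lay = lay, qc = lay$role == "qc", orders = o)
}

test_that("constant QCs give an identity correction", {
  b <- make_batch()
  fit <- qc_svrc_fit(b$m, b$qc, b$orders)
  expect_true(fit$flat[["f1"]])                        # zero-variance QCs
  out <- qc_svrc_apply(b$m, fit, b$orders)
  expect_equal(out, b$m)
})

test_that("the fitted curve recovers exact linear drift at QC positions", {
  b <- make_batch(drift = function(o) 1 + 0.01 * o)
  fit <- qc_svrc_fit(b$m, b$qc, b$orders)
  pred <- drift_predict(fit, "f1", b$orders[b$qc]) * fit$reference[["f1"]]
  truth <- 100 * (1 + 0.01 * b$orders[b$qc])
  expect_true(all(abs(pred / truth - 1) < 0.01))
  # correction flattens the drift on every injection
  out <- qc_svrc_apply(b$m, fit, b$orders)
  rsd_post <- compute_rsd(out[b$qc, "f1"])
  expect_lt(rsd_post, compute_rsd(b$m[b$qc, "f1"]))
})

test_that("too few QCs is an error naming the minimum", {
  b <- make_batch()
  qc2 <- b$qc & cumsum(b$qc) <= 2
  expect_error(qc_svrc_fit(b$m, qc2, b$orders), "at least 5")
})

test_that("drifted data with 2% noise corrects to low QC RSD", {
  b <- make_batch(drift = function(o) 1 - 0.6 * (o / max(o)),
                  noise_sd = sqrt(log(1 + 0.02^2)), seed = 42)
  pre <- compute_rsd(b$m[b$qc, "f1"])
  expect_gt(pre, 20)                                  # drift-broken
  fit <- qc_svrc_fit(b$m, b$qc, b$orders)
  out <- qc_svrc_apply(b$m, fit, b$orders)
  expect_lt(compute_rsd(out[b$qc, "f1"]), 5)
  # corrected values sit on the batch QC reference level
  expect_equal(median(out[b$qc, "f1"]), fit$reference[["f1"]],
               tolerance = 0.05)
})

test_that("QC-Norm equalizes per-feature QC medians across batches", {
  inj <- toy_injections(n_study = 6, n_qc = 5, batches = 1:2)
  m <- toy_matrix(inj, list(f1 = list(study = 1, qc = 1, blank = 0)))
  m[inj$batch == 1, "f1"] <- 200
  m[inj$batch == 2, "f1"] <- 100
  res <- qc_norm(m, inj)
  expect_equal(unname(res$factors["f1", ]), c(150 / 200, 150 / 100))
  qc <- inj$role == "qc"
  med <- tapply(res$intensities[qc, "f1"], inj$batch[qc], median)
  expect_equal(unname(diff(med)), 0)
  # equal batch medians -> identity
  m2 <- toy_matrix(inj, list(f1 = list(study = 3, qc = 5, blank = 0)))
  expect_equal(qc_norm(m2, inj)$intensities, m2)
})

test_that("QC-Norm commutes with per-feature positive rescaling", {
  st <- simulate_study(cohort_config(n_per_generation = c(8, 8, 8),
                                     n_families = 8, seed = 17),
                       n_features = 35, n_taxa = 30, n_ko = 40)
  m <- st$metabolome$intensities
  inj <- st$metabolome$injections
  scl <- seq(0.5, 2, length.out = ncol(m))
  a <- qc_norm(sweep(m, 2, scl, `*`), inj)$intensities
  b <- sweep(qc_norm(m, inj)$intensities, 2, scl, `*`)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("normalization preserves sample order and metadata", {
  st <- simulate_study(cohort_config(n_per_generation = c(8, 8, 8),
                                     n_families = 8, seed = 23),
                       n_features = 35, n_taxa = 30, n_ko = 40)
  inj <- st$metabolome$injections
  sv <- svrc_normalize(st$metabolome$intensities, inj,
                       cost_grid = 10, eps_frac_grid = 0.1)
  expect_identical(rownames(sv$intensities),
                   rownames(st$metabolome$intensities))
  expect_identical(dim(sv$intensities), dim(st$metabolome$intensities))
})

test_that("KNN imputation matches the brute-force neighbour table", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(1.1, 2.1, NA), s3 = c(10, 12, 30),
             s4 = c(1.05, 2.05, 3.3))
  colnames(m) <- paste0("f", 1:3)
  out <- knn_impute(m, k = 2)
  # brute force: UV-scale, Euclidean over shared-observed features
  mu <- colMeans(m, na.rm = TRUE); sdv <- apply(m, 2, sd, na.rm = TRUE)
  z <- sweep(sweep(m, 2, mu), 2, sdv, `/`)
  d <- sapply(c("s1", "s3", "s4"), function(r) {
    shared <- !is.na(z["s2", ]) & !is.na(z[r, ])
    sqrt(mean((z["s2", shared] - z[r, shared])^2))
  })
  nb <- names(sort(d))[1:2]
  expect_equal(out["s2", "f3"], mean(m[nb, "f3"]))
  # observed entries untouched
  expect_identical(out[!is.na(m)], m[!is.na(m)])
})

test_that("KNN imputation handles identity and degenerate cases", {
  m <- matrix(1:6, 2, 3)
  expect_identical(knn_impute(m, k = 1), m)
  dup <- rbind(a = c(1, 2, 3), b = c(1, 2, NA), c = c(9, 9, 9))
  out <- knn_impute(dup, k = 1)
  expect_equal(unname(out["b", 3]), 3)                       # nearest is its duplicate
  allna <- rbind(c(1, NA), c(2, NA), c(1, NA))
  expect_error(knn_impute(allna, k = 1), "missing in all")
  expect_error(knn_impute(m, k = 2), "smaller than")
})
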