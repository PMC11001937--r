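make_blocks <- function(n = 60, p = c(40, 30, 50), informative = 8, eff = 2.5,
                        seed = 1) {
  set.seed(seed)
  lab <- rep(c("Infant", "Mother", "Grandmother"), length.out = n)
  lab <- lab[order(lab)]
  blocks <- lapply(seq_along(p), function(b) {
    x <- matrix(rnorm(n * p[b]), n, p[b],
                dimnames = list(sprintf("s%02d", 1:n),
                                sprintf("b%d_v%03d", b, seq_len(p[b]))))
    x[lab == "Infant", seq_len(informative)] <-
      x[lab == "Infant", seq_len(informative)] + eff
    x
  })
  names(blocks) <- c("metab", "taxa", "ko")[seq_along(p)]
  list(blocks = blocks, labels = factor(lab, levels = c("Infant", "Mother",
                                                        "Grandmother")))
}

test_that("keepX is enforced exactly and planted variables are recovered", {
  d <- make_blocks()
  m <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 25)
  for (b in seq_along(d$blocks)) {
    expect_equal(colSums(m$loadings[[b]] != 0), c(25, 25))
    planted <- colnames(d$blocks[[b]])[1:8]
    expect_gte(sum(planted %in% m$selected[[b]][[1]]), 7)
  }
})

test_that("identical blocks under the full design give perfectly correlated scores", {
  set.seed(70)
  x <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("v%02d", 1:12)))
  lab <- rep(c("A", "B"), 20)
  m <- block_splsda(list(one = x, two = x), lab, ncomp = 1, keepX = 12)
  expect_equal(m$score_correlations[[1]]["one", "two"], 1, tolerance = 1e-6)
})

test_that("successive scores within a block are orthogonal", {
  d <- make_blocks()
  m <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 10)
  for (b in seq_along(d$blocks)) {
    s <- m$scores[[b]]
    expect_equal(sum(s[, 1] * s[, 2]) / sqrt(sum(s[, 1]^2) * sum(s[, 2]^2)),
                 0, tolerance = 1e-6)
  }
})

test_that("a single block with no cross-block design reduces to sparse PLS-DA", {
  skip_if_not_installed("mixOmics")
  d <- make_blocks(p = 30)
  m <- block_splsda(d$blocks["metab"], d$labels, ncomp = 2, keepX = 10)
  ref <- mixOmics::splsda(d$blocks$metab, d$labels, ncomp = 2,
                          keepX = c(10, 10))
  for (h in 1:2) {
    expect_gt(abs(cor(m$scores[[1]][, h], ref$variates$X[, h])), 0.95)
  }
  expect_gte(length(intersect(
    m$selected[[1]][[1]],
    mixOmics::selectVar(ref, comp = 1)$name)), 8)
})

test_that("the multiblock model agrees with the reference implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_blocks()
  m <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 15)
  suppressMessages(
    ref <- mixOmics::block.splsda(d$blocks, d$labels, ncomp = 2,
                                  keepX = lapply(d$blocks, function(x) c(15, 15)),
                                  design = "full"))
  for (b in names(d$blocks)) {
    expect_gt(abs(cor(m$scores[[b]][, 1], ref$variates[[b]][, 1])), 0.9)
    ours <- m$selected[[match(b, names(d$blocks))]][[1]]
    theirs <- mixOmics::selectVar(ref, block = b, comp = 1)[[b]]$name
    expect_gte(length(intersect(ours, theirs)) / 15, 0.6)
  }
})

test_that("cross-validated performance tracks class separation", {
  d <- make_blocks(n = 45, eff = 4)
  # infants separate perfectly; the two adult groups are indistinguishable,
  # so the floor is the adult confusion, not total error
  pf <- perf_cv(d$blocks, d$labels, ncomp = 2, keepX = 10, folds = 5,
                repeats = 2, seed = 3)
  expect_lt(pf$class_error[["Infant"]], 0.1)
  set.seed(4)
  d2 <- make_blocks(n = 45, eff = 0)
  pf2 <- perf_cv(d2$blocks, sample(d2$labels), ncomp = 1, keepX = 10,
                 folds = 5, repeats = 2, seed = 5)
  expect_gt(pf2$mean_error, 0.4)                     # ~ 1 - max class prior
  # identical seed reproduces the fold draws exactly
  pf3 <- perf_cv(d$blocks, d$labels, ncomp = 2, keepX = 10, folds = 5,
                 repeats = 2, seed = 3)
  expect_identical(pf$error_rates, pf3$error_rates)
})

test_that("AUROC matches exhaustive pair counting with ties", {
  expect_equal(auroc(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  s <- c(1, 2, 2, 3); pos <- c(FALSE, FALSE, TRUE, TRUE)
  # pairs: (1,2)->1, (1,3)->1, (2,2)->0.5, (2,3)->1  => 3.5/4
  expect_equal(auroc(s, pos), 3.5 / 4)
  set.seed(71)
  r <- replicate(200, auroc(rnorm(40), rep(c(TRUE, FALSE), 20)))
  expect_equal(mean(r), 0.5, tolerance = 0.03)
  expect_error(auroc(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("per-block one-vs-all AUROC finds the infant contrast", {
  d <- make_blocks(eff = 3)
  m <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 10)
  a <- model_auroc(m)
  inf <- a[a$contrast == "Infant vs Others", ]
  expect_true(all(inf$auc > 0.95))
})

test_that("similarity matrix applies the cutoff and skips the diagonal", {
  set.seed(72)
  n <- 50
  latent <- rnorm(n)
  lab <- rep(c("A", "B"), 25)[order(rep(c("A", "B"), 25))]
  latent <- latent + ifelse(lab == "A", 2, -2)
  mk <- function(p, prefix) {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n),
                                paste0(prefix, seq_len(p))))
    x[, 1] <- latent + rnorm(n, 0, 0.3)              # co-regulated pair
    x
  }
  blocks <- list(a = mk(10, "a"), b = mk(10, "b"))
  m <- block_splsda(blocks, lab, ncomp = 1, keepX = 5)
  sim <- similarity_matrix(m, blocks, cutoff = 0.65)
  expect_false(any(sim$var1 == sim$var2 & sim$block1 == sim$block2))
  expect_true(all(abs(sim$similarity) > 0.65))
  link <- sim[(sim$var1 == "a1" & sim$var2 == "b1") |
                (sim$var1 == "b1" & sim$var2 == "a1"), ]
  expect_equal(nrow(link), 1L)
  expect_gt(link$similarity, 0.65)
  # raising the cutoff suppresses weaker edges
  sim99 <- similarity_matrix(m, blocks, cutoff = 0.99)
  expect_lt(nrow(sim99), nrow(sim))
})

test_that("CIM clustering reproduces hand-computed complete linkage", {
  # 4-point toy on one axis: merge order is (a,b), (c,d), then the pair
  x <- matrix(c(0, 1, 10, 12), 4, 1, dimnames = list(letters[1:4], "v"))
  hc <- hclust(dist(x), method = "complete")
  expect_equal(hc$height, c(1, 2, 12))
  lab <- c("A", "A", "B", "B")
  blocks <- list(m = cbind(x, v2 = c(0, 1, 10, 12)))
  m <- block_splsda(blocks, lab, ncomp = 1, keepX = 2)
  cim <- cim_cluster(m, blocks)
  expect_equal(sort(cutree(cim$row_hclust, 2)[c("a", "b")]),
               sort(cutree(cim$row_hclust, 2)[c("a", "b")]))
  cl <- cim_cut(cim, 2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])
  # duplicate rows merge first at distance 0
  x2 <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc2 <- hclust(dist(x2), method = "complete")
  expect_equal(hc2$height[1], 0)
})

test_that("the model fit is deterministic", {
  d <- make_blocks()
  m1 <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 25)
  m2 <- block_splsda(d$blocks, d$labels, ncomp = 2, keepX = 25)
  expect_identical(m1$loadings, m2$loadings)
  expect_identical(m1$scores, m2$scores)
})
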