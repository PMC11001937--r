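test_that("cohort generation matches the configured design", {
  res <- generate_cohort(cohort_config(seed = 11))
  meta <- res$metadata
  expect_equal(unname(table(meta$generation)[c("Infant", "Mother", "Grandmother")]),
               c(67, 67, 63), ignore_attr = TRUE)
  # one generation per batch
  expect_equal(length(unique(meta$batch[meta$generation == "Mother"])), 1L)
  tab <- table(meta$generation, meta$batch)
  expect_true(all(rowSums(tab > 0) == 1))
  # linked triads: most families span all three generations
  fam3 <- rowSums(res$family_map > 0)
  expect_gt(sum(fam3 == 3), 50)
})

test_that("cohort generation is deterministic and validates its config", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  tiny <- generate_cohort(cohort_config(n_per_generation = c(1, 1, 1),
                                        n_families = 1, seed = 1,
                                        missing_family_rate = 0))
  expect_equal(nrow(tiny$metadata), 3L)
  expect_equal(length(unique(tiny$metadata$family)), 1L)
  expect_error(cohort_config(n_per_generation = c(10, 5, 5), n_families = 4),
               "n_families")
  expect_error(cohort_config(n_per_generation = c(0, 1, 1), n_families = 3),
               ">= 1")
})

test_that("worklist layout places equilibrium and interspersed QCs correctly", {
  lay <- worklist_layout(67)
  expect_equal(lay$injection_order, seq_len(nrow(lay)))
  expect_equal(sum(lay$role == "eqc"), 3L)
  expect_equal(sum(lay$role == "qc"), 8L)
  expect_equal(sum(lay$role == "study"), 67L)
  # interspersed QCs arrive after runs of about 9-10 study samples
  qc_pos <- which(lay$role == "qc")
  gaps <- diff(c(max(which(lay$role == "eqc")), qc_pos))
  expect_true(all(gaps >= 8 & gaps <= 11))
})

test_that("metabolome generator honours the truth parameters", {
  set.seed(3)
  cohort <- generate_cohort(cohort_config(
    n_per_generation = c(12, 12, 12), n_families = 12,
    missing_family_rate = 0, seed = 3))
  ann <- feature_panel <- triomics:::feature_panel(40)
  truth <- drift_truth(ann, noise_cv = 0.02, censor_fraction = 0)
  # zero drift, zero effects, zero noise -> QCs within a batch identical
  t0 <- truth
  t0$drift_amp[] <- 0
  t0$noise_cv <- 0
  t0$batch_factor[] <- 1
  gm <- generate_metabolome(t0, cohort$metadata)
  qc1 <- gm$intensities[gm$injections$role == "qc" & gm$injections$batch == 1, ]
  expect_true(all(apply(qc1, 2, function(v) diff(range(v)) < 1e-9)))
  # blanks contain only the designed background
  bl <- gm$intensities[gm$injections$role == "blank", ]
  expect_true(all(bl[, !truth$contaminant] == 0))
  expect_true(all(bl[, truth$contaminant] > 0))
})

test_that("the truth drift curve evaluates exactly on linear drift", {
  ann <- triomics:::feature_panel(35)
  truth <- drift_truth(ann)
  # pure linear component with amplitude 1 over orders 0..100 reproduces
  # 1 + 0.01 * order: the factor at order 50 is 1.5x the order-0 baseline
  truth$drift_amp[1, 1] <- 1
  truth$drift_mix[1, 1] <- 1
  d <- drift_curve(truth, 1, c(0, 50, 100), order_range = c(0, 100))
  expect_equal(unname(d[1, ] / d[1, 1]), c(1, 1.5, 2), tolerance = 1e-12)
  expect_true(all(drift_curve(truth, 2, 0:100, c(0, 100)) > 0))
})

test_that("QC intensities track drift exactly when noise is off", {
  set.seed(9)
  cohort <- generate_cohort(cohort_config(
    n_per_generation = c(10, 10, 10), n_families = 10,
    missing_family_rate = 0, seed = 9))
  truth <- drift_truth(triomics:::feature_panel(35), noise_cv = 0,
                       censor_fraction = 0)
  gm <- generate_metabolome(truth, cohort$metadata)
  inj <- gm$injections
  qc <- inj$role == "qc" & inj$batch == 1
  f <- truth$feature_id[1]
  expected <- truth$base[f] * mean(exp(truth$effects[f, ])) *
    drift_curve(truth, 1, inj$injection_order[qc],
                order_range = range(inj$injection_order[inj$batch == 1]))[f, ] *
    truth$batch_factor[f, 1]
  expect_equal(unname(gm$intensities[qc, f]), unname(expected), tolerance = 1e-10)
})

test_that("taxa generator produces the designed compositional contrast", {
  lineage <- triomics:::default_taxa_table(80)
  base <- base_compositions(lineage)
  expect_equal(colSums(base), c(Infant = 1, Mother = 1, Grandmother = 1))
  top3 <- c("Bifidobacterium", "Escherichia/Shigella", "Veillonella")
  idx <- lineage$taxon_id[match(top3, lineage$genus)]
  expect_gt(sum(base[idx, "Infant"]), 0.5)
  # closed-form expected Shannon on the base proportions
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  expect_gt(H(base[, "Mother"]), H(base[, "Infant"]))
  expect_gt(H(base[, "Grandmother"]), H(base[, "Infant"]))

  set.seed(21)
  meta <- generate_cohort(cohort_config(n_per_generation = c(15, 15, 15),
                                        n_families = 15, seed = 21,
                                        missing_family_rate = 0))$metadata
  taxa <- generate_taxa(meta)
  prop <- relative_abundance(taxa$counts)
  inf_share <- rowSums(prop[meta$generation == "Infant", idx])
  expect_gt(mean(inf_share), 0.5)
  expect_error(generate_taxa(meta, concentration = c(Infant = -1, Mother = 1,
                                                     Grandmother = 1)),
               "negative")
})

test_that("Dirichlet overdispersion vanishes in the high-concentration limit", {
  set.seed(4)
  alpha <- c(0.5, 0.3, 0.2) * 1e9
  draws <- triomics:::r_dirichlet(50, alpha)
  expect_true(all(abs(sweep(draws, 2, c(0.5, 0.3, 0.2))) < 1e-3))
})

test_that("KO counts follow the taxa-weighted genome mixture", {
  lineage <- triomics:::default_taxa_table(25)[1:2, ]
  # disjoint two-taxon profiles
  profiles <- rbind(c(rep(0.25, 4), rep(0, 4)),
                    c(rep(0, 4), rep(0.25, 4)))
  dimnames(profiles) <- list(lineage$taxon_id, sprintf("K%05d", 1:8))
  brite <- data.frame(ko = colnames(profiles), level_b = "B-01",
                      level_c = "C-001")
  counts <- matrix(c(500L, 500L), 1, 2,
                   dimnames = list("s1", lineage$taxon_id))
  taxa <- list(counts = counts, lineage = lineage)
  set.seed(8)
  ko <- generate_ko(taxa, genomes = list(profiles = profiles, brite_map = brite),
                    mean_depth = 2e5)
  prop <- ko$counts[1, ] / sum(ko$counts[1, ])
  # expected proportions are the 50/50 average of the two profiles
  expect_equal(unname(prop), rep(0.125, 8), tolerance = 0.02)

  # single-taxon community reproduces that genome profile
  counts1 <- matrix(c(1000L, 0L), 1, 2,
                    dimnames = list("s1", lineage$taxon_id))
  ko1 <- generate_ko(list(counts = counts1, lineage = lineage),
                     genomes = list(profiles = profiles, brite_map = brite),
                     mean_depth = 2e5)
  expect_equal(unname(ko1$counts[1, ] / sum(ko1$counts[1, ])),
               unname(profiles[1, ]), tolerance = 0.02)

  bad <- profiles; bad[1, 1] <- 0.9
  expect_error(generate_ko(taxa, genomes = list(profiles = bad, brite_map = brite)),
               "sum to 1")
})

test_that("whole-study simulation is byte-identical under a fixed seed", {
  a <- simulate_study(cohort_config(n_per_generation = c(8, 8, 8),
                                    n_families = 8, seed = 13),
                      n_features = 35, n_taxa = 30, n_ko = 60)
  b <- simulate_study(cohort_config(n_per_generation = c(8, 8, 8),
                                    n_families = 8, seed = 13),
                      n_features = 35, n_taxa = 30, n_ko = 60)
  expect_identical(a$metabolome$intensities, b$metabolome$intensities)
  expect_identical(a$taxa$counts, b$taxa$counts)
  expect_identical(a$ko$counts, b$ko$counts)
})

test_that("null features have equal group means in expectation", {
  set.seed(99)
  cohort <- generate_cohort(cohort_config(n_per_generation = c(40, 40, 40),
                                          n_families = 40, seed = 99,
                                          missing_family_rate = 0))
  truth <- drift_truth(triomics:::feature_panel(40), noise_cv = 0,
                       censor_fraction = 0, informative_fraction = 0)
  truth$drift_amp[] <- 0
  truth$batch_factor[] <- 1
  gm <- generate_metabolome(truth, cohort$metadata)
  st <- gm$injections$role == "study"
  nulls <- names(which(!truth$informative & !truth$contaminant))
  lm_ <- log(gm$intensities[st, nulls])
  gmn <- apply(lm_, 2, function(v) tapply(v, gm$injections$generation[st], mean))
  spread <- apply(gmn, 2, function(v) diff(range(v)))
  # group means agree within Monte Carlo error of the family/residual noise
  expect_lt(median(spread), 0.25)
})

test_that("study tables round-trip to disk", {
  st <- simulate_study(cohort_config(n_per_generation = c(5, 5, 5),
                                     n_families = 5, seed = 2),
                       n_features = 35, n_taxa = 30, n_ko = 40)
  dir <- tempfile()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), 15L)
  cfg <- readLines(file.path(dir, "config.txt"))
  expect_true(any(grepl("^seed: 2$", cfg)))
})
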