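test_that("RSD follows its definition and flags degenerate input", {
  expect_equal(compute_rsd(c(10, 10, 10)), 0)
  expect_equal(compute_rsd(c(8, 10, 12)), 20)        # sd 2, mean 10
  expect_warning(r <- compute_rsd(5), "fewer than 2")
  expect_true(is.na(r))
  expect_warning(r2 <- compute_rsd(c(-3, 1)), "mean")
  expect_true(is.na(r2))
})

test_that("blank subtraction removes background-dominated features only", {
  inj <- toy_injections()
  m <- toy_matrix(inj, list(
    contaminated = list(study = 100, qc = 100, blank = 90),
    clean        = list(study = 100, qc = 100, blank = 10),
    no_blank     = list(study = 50,  qc = 50,  blank = 0)))
  res <- subtract_blanks(m, inj, blank_ratio = 3)
  expect_equal(res$removed, "contaminated")          # 100 < 3 * 90
  expect_equal(colnames(res$intensities), c("clean", "no_blank"))
  # retained features are unchanged
  expect_identical(res$intensities[, "clean"], m[, "clean"])

  all_cont <- toy_matrix(inj, list(a = list(study = 1, qc = 1, blank = 1)))
  expect_warning(r2 <- subtract_blanks(all_cont, inj), "all features")
  expect_equal(ncol(r2$intensities), 0L)

  no_blanks <- inj[inj$role != "blank", ]
  expect_error(subtract_blanks(m[inj$role != "blank", ], no_blanks),
               "skip the blank-subtraction stage")
})

test_that("presence filter applies the QC/sample thresholds per batch", {
  inj <- toy_injections(n_study = 10, n_qc = 5, batches = 1)
  m <- toy_matrix(inj, list(
    kept    = list(study = 1, qc = 1, blank = 0),
    partial = list(study = 1, qc = 1, blank = 0),
    gone    = list(study = 1, qc = 1, blank = 0)))
  qc_rows <- which(inj$role == "qc")
  st_rows <- which(inj$role == "study")
  # kept: 60% of QCs, 80% of samples
  m[qc_rows[1:2], "kept"] <- 0
  m[st_rows[1:2], "kept"] <- 0
  # gone: 40% of QCs, 60% of samples
  m[qc_rows[1:3], "gone"] <- 0
  m[st_rows[1:4], "gone"] <- 0
  res <- presence_filter(m, inj)
  expect_true(all(c("kept", "partial") %in% colnames(res$intensities)))
  expect_equal(res$removed, "gone")
  # OR connective keeps the 40%/60% feature (60% of samples fails 70%,
  # but removal then requires both criteria to fail)
  m2 <- m
  m2[st_rows[1:2], "gone"] <- 0; m2[st_rows[3:4], "gone"] <- 1
  res_or <- presence_filter(m, inj, mode = "or")
  expect_true("gone" %in% res$removed)
  expect_false("kept" %in% res_or$removed)
  expect_error(presence_filter(m[inj$role != "qc", ], inj[inj$role != "qc", ]),
               "QC")
})

test_that("RSD filter keeps features passing in at least one batch", {
  inj <- toy_injections(n_study = 6, n_qc = 5, batches = 1:3)
  m <- toy_matrix(inj, list(
    one_good  = list(study = 10, qc = 10, blank = 0),
    all_bad   = list(study = 10, qc = 10, blank = 0),
    constant  = list(study = 10, qc = 10, blank = 0)))
  set_qc_rsd <- function(m, feature, batch, target_rsd) {
    rows <- which(inj$role == "qc" & inj$batch == batch)
    base <- c(8, 9, 10, 11, 12)                       # RSD 15.81% at mean 10
    v <- 10 + (base - 10) * target_rsd / compute_rsd(base)
    m[rows, feature] <- v
    m
  }
  m <- set_qc_rsd(m, "one_good", 1, 25); m <- set_qc_rsd(m, "one_good", 2, 40)
  m <- set_qc_rsd(m, "one_good", 3, 45)
  m <- set_qc_rsd(m, "all_bad", 1, 35); m <- set_qc_rsd(m, "all_bad", 2, 33)
  m <- set_qc_rsd(m, "all_bad", 3, 31)
  res <- rsd_filter(m, inj, threshold = 30)
  expect_true("one_good" %in% colnames(res$intensities))
  expect_equal(res$removed, "all_bad")
  expect_equal(unname(res$rsd["one_good", ]), c(25, 40, 45), tolerance = 1e-9)
  # zero RSD everywhere passes in both modes
  expect_true(res$pass_all[["constant"]])
  res_all <- rsd_filter(m, inj, threshold = 30, mode = "all")
  expect_equal(colnames(res_all$intensities), "constant")
})

test_that("total useful signal sums the observed intensities", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(NA, NA, NA))
  colnames(m) <- paste0("f", 1:3)
  tus <- compute_tus(m)
  expect_equal(tus$tus, c(6, 0))
  expect_equal(tus$all_missing, c(FALSE, TRUE))
})

test_that("internal-standard diagnostics report one RSD per IS per batch", {
  inj <- toy_injections(n_study = 6, n_qc = 5, batches = 1:2)
  m <- toy_matrix(inj, list(
    is1 = list(study = 10, qc = 10, blank = 0),
    is2 = list(study = 7, qc = 7, blank = 0)))
  rows <- which(inj$batch == 1 & inj$role != "blank")
  m[rows, "is2"] <- rep(c(8, 10, 12), length.out = length(rows))
  d <- is_diagnostics(m, inj, c("is1", "is2"))
  expect_equal(nrow(d), 4L)
  expect_equal(d$rsd[d$is_id == "is1" & d$batch == 1], 0)
  b1 <- m[rows, "is2"]
  expect_equal(d$rsd[d$is_id == "is2" & d$batch == 1], compute_rsd(b1))
  expect_error(is_diagnostics(m, inj, "nope"), "nope")
})

test_that("the QA pipeline reconciles counts and reason codes", {
  st <- simulate_study(cohort_config(n_per_generation = c(10, 10, 10),
                                     n_families = 10, seed = 31),
                       n_features = 50, n_taxa = 30, n_ko = 40)
  inj <- st$metabolome$injections
  rep <- qa_pipeline(st$metabolome$intensities, inj)
  expect_s3_class(rep, "qa_report")
  expect_true(all(diff(rep$stages$n_features) <= 0))
  removed <- setdiff(colnames(st$metabolome$intensities),
                     colnames(rep$intensities))
  expect_setequal(names(rep$reasons), removed)
  expect_false(any(duplicated(names(rep$reasons))))
  # blank subtraction removes exactly the designed contaminant set
  truth <- st$metabolome$truth
  expect_setequal(names(rep$reasons)[rep$reasons == "blank_background"],
                  names(which(truth$contaminant)))
  # stages are idempotent: re-running QA on its own output changes nothing
  rep2 <- qa_pipeline(rep$intensities, inj)
  expect_equal(ncol(rep2$intensities), ncol(rep$intensities))
})
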