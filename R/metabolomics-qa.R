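# Quality assurance for raw multi-batch feature matrices: blank
# subtraction, presence filter, QC-RSD filter and diagnostic summaries
# (total useful signal, internal-standard RSDs).
#
# Injections are classified by `role`: "study", "qc" (interspersed QC),
# "eqc" (equilibrium QC, excluded from all QC statistics) and "blank".

#' Relative standard deviation
#'
#' `100 * sd / mean` of the non-missing values.
#'
#' @param values numeric vector.
#' @param na_rm drop missing values first.
#' @return RSD in percent, or `NA` (with a warning) when fewer than two
#'   non-missing values remain or the mean is not positive.
#' @export
compute_rsd <- function(values, na_rm = TRUE) {
  v <- if (na_rm) values[!is.na(values)] else values
  if (length(v) < 2L) {
    warning("RSD undefined: fewer than 2 values")
    return(NA_real_)
  }
  m <- mean(v)
  if (!is.finite(m) || m <= 0) {
    warning("RSD undefined: mean <= 0")
    return(NA_real_)
  }
  100 * stats::sd(v) / m
}

#' Blank subtraction
#'
#' Removes features whose mean study-sample signal is below
#' `blank_ratio` times their mean blank signal (reagent/derivatization
#' background). Features with zero blank signal are always retained.
#'
#' @param intensities injections x features matrix.
#' @param injections data frame with a `role` column aligned to the rows.
#' @param blank_ratio required study-to-blank signal ratio (default 3).
#' @return list: `intensities` (retained features), `removed` (feature
#'   ids), `stats` (per-feature study and blank means).
#' @export
subtract_blanks <- function(intensities, injections, blank_ratio = 3) {
  check_alignment(intensities, injections)
  if (!any(injections$role == "blank")) {
    stop("no blank injections present; skip the blank-subtraction stage explicitly")
  }
  study_mean <- colMeans(intensities[injections$role == "study", , drop = FALSE],
                         na.rm = TRUE)
  blank_mean <- colMeans(intensities[injections$role == "blank", , drop = FALSE],
                         na.rm = TRUE)
  blank_mean[is.nan(blank_mean)] <- 0
  drop <- blank_mean > 0 & (is.nan(study_mean) | study_mean < blank_ratio * blank_mean)
  if (all(drop)) warning("all features flagged as contaminants")
  list(intensities = intensities[, !drop, drop = FALSE],
       removed = colnames(intensities)[drop],
       stats = data.frame(feature_id = colnames(intensities),
                          study_mean = study_mean, blank_mean = blank_mean,
                          removed = drop, row.names = NULL))
}

presence_fraction <- function(x) colMeans(!is.na(x) & x > 0)

#' Presence filter
#'
#' A feature passes within a batch when it appears (non-missing and
#' positive) in at least `qc_min` of the interspersed QCs and (mode
#' `"and"`) / or (mode `"or"`) at least `sample_min` of the study samples.
#' A feature is kept when it passes in at least one batch.
#'
#' @param intensities injections x features matrix.
#' @param injections aligned injection metadata with `role` and `batch`.
#' @param qc_min,sample_min presence thresholds (fractions).
#' @param mode `"and"` (keep requires both thresholds; default) or `"or"`.
#' @return list: `intensities`, `removed`, `detail` (per feature per batch
#'   presence fractions and pass flags).
#' @export
presence_filter <- function(intensities, injections, qc_min = 0.5,
                            sample_min = 0.7, mode = c("and", "or")) {
  mode <- match.arg(mode)
  check_alignment(intensities, injections)
  if (!any(injections$role == "qc")) stop("no interspersed QC injections present")
  batches <- sort(unique(injections$batch))
  detail <- do.call(rbind, lapply(batches, function(b) {
    qc <- injections$role == "qc" & injections$batch == b
    st <- injections$role == "study" & injections$batch == b
    if (!any(qc)) stop("batch ", b, " has no interspersed QCs")
    fq <- presence_fraction(intensities[qc, , drop = FALSE])
    fs <- presence_fraction(intensities[st, , drop = FALSE])
    pass <- if (mode == "and") fq >= qc_min & fs >= sample_min
            else fq >= qc_min | fs >= sample_min
    data.frame(feature_id = colnames(intensities), batch = b,
               qc_presence = fq, sample_presence = fs, pass = pass,
               row.names = NULL)
  }))
  keep_ids <- unique(detail$feature_id[detail$pass])
  keep <- colnames(intensities) %in% keep_ids
  list(intensities = intensities[, keep, drop = FALSE],
       removed = colnames(intensities)[!keep], detail = detail)
}

#' Per-batch QC RSDs
#'
#' @param intensities injections x features matrix.
#' @param injections aligned injection metadata.
#' @return matrix features x batches of interspersed-QC RSDs (percent).
#' @export
qc_rsd_by_batch <- function(intensities, injections) {
  check_alignment(intensities, injections)
  batches <- sort(unique(injections$batch))
  out <- sapply(batches, function(b) {
    qc <- injections$role == "qc" & injections$batch == b
    apply(intensities[qc, , drop = FALSE], 2, function(v) {
      suppressWarnings(compute_rsd(v))
    })
  })
  out <- matrix(out, ncol = length(batches),
                dimnames = list(colnames(intensities), paste0("batch", batches)))
  out
}

#' QC-RSD filter
#'
#' Keeps a feature when its interspersed-QC RSD is below `threshold` in at
#' least one batch (`mode = "any"`); the stricter all-batch rule is also
#' reported (and selectable with `mode = "all"`).
#'
#' @param intensities injections x features matrix.
#' @param injections aligned injection metadata.
#' @param threshold RSD threshold in percent (default 30).
#' @param mode `"any"` (default) or `"all"` batches below threshold.
#' @return list: `intensities`, `removed`, `rsd` (features x batches),
#'   `pass_any`, `pass_all` logical vectors.
#' @export
rsd_filter <- function(intensities, injections, threshold = 30,
                       mode = c("any", "all")) {
  mode <- match.arg(mode)
  rsd <- qc_rsd_by_batch(intensities, injections)
  below <- !is.na(rsd) & rsd < threshold
  pass_any <- rowSums(below) >= 1L
  pass_all <- rowSums(below) == ncol(rsd)
  keep <- if (mode == "any") pass_any else pass_all
  list(intensities = intensities[, keep, drop = FALSE],
       removed = colnames(intensities)[!keep],
       rsd = rsd, pass_any = pass_any, pass_all = pass_all)
}

#' Total useful signal
#'
#' Sum of the non-missing feature intensities of each injection.
#'
#' @param intensities injections x features matrix.
#' @return data frame: sample_id (rownames), tus, n_observed,
#'   all_missing flag.
#' @export
compute_tus <- function(intensities) {
  if (ncol(intensities) == 0L) stop("empty feature matrix")
  n_obs <- rowSums(!is.na(intensities))
  data.frame(sample_id = rownames(intensities),
             tus = rowSums(intensities, na.rm = TRUE),
             n_observed = n_obs,
             all_missing = n_obs == 0L, row.names = NULL)
}

#' Internal-standard diagnostics
#'
#' Per-batch RSD of each internal standard across all non-blank
#' injections (the IS is spiked into every sample and QC, so its scatter
#' tracks derivatization and instrument performance).
#'
#' @param intensities injections x features matrix.
#' @param injections aligned injection metadata.
#' @param is_feature_ids feature ids of the internal standards.
#' @return data frame: is_id, batch, rsd.
#' @export
is_diagnostics <- function(intensities, injections, is_feature_ids) {
  check_alignment(intensities, injections)
  missing_is <- setdiff(is_feature_ids, colnames(intensities))
  if (length(missing_is)) {
    stop("internal standard(s) not in the matrix: ", paste(missing_is, collapse = ", "))
  }
  batches <- sort(unique(injections$batch))
  out <- expand.grid(is_id = is_feature_ids, batch = batches,
                     stringsAsFactors = FALSE)
  out$rsd <- mapply(function(f, b) {
    rows <- injections$batch == b & injections$role != "blank"
    suppressWarnings(compute_rsd(intensities[rows, f]))
  }, out$is_id, out$batch)
  out
}

#' Run the full QA pipeline
#'
#' Blank subtraction, then presence filter, then QC-RSD filter, with a
#' reconciled report: per-stage feature counts and one reason code per
#' removed feature.
#'
#' @param intensities injections x features matrix.
#' @param injections aligned injection metadata.
#' @param blank_ratio,qc_min,sample_min,rsd_threshold stage parameters.
#' @param presence_mode `"and"` or `"or"` (see [presence_filter()]).
#' @param is_feature_ids optional internal standards for diagnostics.
#' @return object of class `qa_report`.
#' @export
qa_pipeline <- function(intensities, injections, blank_ratio = 3,
                        qc_min = 0.5, sample_min = 0.7, rsd_threshold = 30,
                        presence_mode = "and", is_feature_ids = NULL) {
  check_alignment(intensities, injections)
  n0 <- ncol(intensities)
  s1 <- subtract_blanks(intensities, injections, blank_ratio)
  s2 <- presence_filter(s1$intensities, injections, qc_min, sample_min,
                        mode = presence_mode)
  s3 <- rsd_filter(s2$intensities, injections, rsd_threshold, mode = "any")
  reasons <- c(stats::setNames(rep("blank_background", length(s1$removed)), s1$removed),
               stats::setNames(rep("low_presence", length(s2$removed)), s2$removed),
               stats::setNames(rep("high_qc_rsd", length(s3$removed)), s3$removed))
  stages <- data.frame(
    stage = c("input", "blank_subtraction", "presence_filter", "rsd_filter"),
    n_features = c(n0, ncol(s1$intensities), ncol(s2$intensities),
                   ncol(s3$intensities)))
  diag <- NULL
  if (!is.null(is_feature_ids)) {
    diag <- is_diagnostics(intensities, injections, is_feature_ids)
  }
  structure(list(intensities = s3$intensities, injections = injections,
                 stages = stages, reasons = reasons, rsd = s3$rsd,
                 pass_all_batches = s3$pass_all,
                 tus = compute_tus(intensities),
                 is_diagnostics = diag,
                 params = list(blank_ratio = blank_ratio, qc_min = qc_min,
                               sample_min = sample_min,
                               rsd_threshold = rsd_threshold,
                               presence_mode = presence_mode)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("Metabolomics QA report\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %d features\n", x$stages$stage[i], x$stages$n_features[i]))
  }
  cat(sprintf("  passing RSD < %g%% in all batches: %d\n",
              x$params$rsd_threshold, sum(x$pass_all_batches)))
  invisible(x)
}

check_alignment <- function(intensities, injections) {
  if (nrow(intensities) != nrow(injections)) {
    stop("intensity matrix and injection metadata have different numbers of rows")
  }
  invisible(TRUE)
}
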