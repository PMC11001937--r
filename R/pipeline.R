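# End-to-end pipeline: simulate -> QA -> normalize -> chemometrics ->
# mixed models -> ratios -> ecology -> functional -> associations ->
# integration, with a reconciled, checksummed run manifest.

#' Pipeline configuration
#'
#' A single seed is fanned out to per-stage substreams (fixed offsets), so
#' stages are individually reproducible.
#'
#' @param seed master seed.
#' @param n_features,n_taxa,n_ko synthetic block sizes.
#' @param blank_ratio,qc_min,sample_min,rsd_threshold QA parameters.
#' @param alpha FDR threshold for the metabolite mixed models.
#' @param keepX,ncomp,cutoff integration parameters.
#' @param cv_folds,cv_repeats integration cross-validation layout.
#' @param ... overrides stored verbatim (passed to [drift_truth()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_features = 150L, n_taxa = 80L,
                            n_ko = 300L, blank_ratio = 3, qc_min = 0.5,
                            sample_min = 0.7, rsd_threshold = 30,
                            alpha = 0.05, keepX = 25L, ncomp = 2L,
                            cutoff = 0.65, cv_folds = 5L, cv_repeats = 10L,
                            ...) {
  structure(list(seed = as.integer(seed), n_features = n_features,
                 n_taxa = n_taxa, n_ko = n_ko, blank_ratio = blank_ratio,
                 qc_min = qc_min, sample_min = sample_min,
                 rsd_threshold = rsd_threshold, alpha = alpha,
                 keepX = keepX, ncomp = ncomp, cutoff = cutoff,
                 cv_folds = cv_folds, cv_repeats = cv_repeats,
                 truth_args = list(...)),
            class = "pipeline_config")
}

write_stage <- function(obj, outdir, file) {
  path <- file.path(outdir, file)
  if (is.matrix(obj)) {
    obj <- data.frame(id = rownames(obj), obj, check.names = FALSE)
  }
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes all stages in their fixed order on a synthetic study, writes
#' every stage output as TSV under `outdir` and returns the results
#' together with a checksummed manifest. Re-running with the same
#' configuration reproduces all checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (default: a fresh temporary directory).
#' @return object of class `pipeline_run`: `results` per stage,
#'   `manifest` (stage, file, md5, rows, cols), `outdir`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("triomics_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list(); results <- list()
  add <- function(stage, name, obj) {
    files[[length(files) + 1L]] <<- data.frame(
      stage = stage, file = paste0(name, ".tsv"),
      rows = if (is.null(dim(obj))) length(obj) else nrow(obj),
      cols = if (is.null(dim(obj))) 1L else ncol(obj))
    write_stage(obj, outdir, paste0(name, ".tsv"))
  }

  # 1. simulate ---------------------------------------------------------
  study <- run_stage("simulate", {
    cfg <- cohort_config(seed = config$seed)
    do.call(simulate_study,
            c(list(config = cfg, n_features = config$n_features,
                   n_taxa = config$n_taxa, n_ko = config$n_ko),
              config$truth_args))
  })
  results$study <- study
  meta <- study$metadata
  inj <- study$metabolome$injections
  add("simulate", "metadata", meta)
  add("simulate", "injections", inj)
  add("simulate", "intensities_raw", study$metabolome$intensities)

  # 2. QA ---------------------------------------------------------------
  qa <- run_stage("qa", {
    is_ids <- study$metabolome$annotation$feature_id[study$metabolome$annotation$is_standard]
    qa_pipeline(study$metabolome$intensities, inj,
                blank_ratio = config$blank_ratio, qc_min = config$qc_min,
                sample_min = config$sample_min,
                rsd_threshold = config$rsd_threshold,
                is_feature_ids = is_ids)
  })
  results$qa <- qa
  add("qa", "qa_stages", qa$stages)
  add("qa", "qa_rsd", qa$rsd)

  # 3. normalize --------------------------------------------------------
  # blank and presence filters run pre-normalization; the RSD gate is
  # re-applied on the normalized data, which defines the final feature set
  norm <- run_stage("normalize", {
    s1 <- subtract_blanks(study$metabolome$intensities, inj, config$blank_ratio)
    s2 <- presence_filter(s1$intensities, inj, config$qc_min, config$sample_min)
    sv <- svrc_normalize(s2$intensities, inj)
    qn <- qc_norm(sv$intensities, inj)
    post <- rsd_filter(qn$intensities, inj, config$rsd_threshold)
    list(svrc = sv, qcnorm = qn, post_rsd = post)
  })
  results$normalized <- norm$post_rsd$intensities
  results$rsd_pass_all <- list(pre = sum(qa$pass_all_batches),
                               post = sum(norm$post_rsd$pass_all))
  add("normalize", "intensities_normalized", norm$post_rsd$intensities)

  # 4. chemometrics -----------------------------------------------------
  chem <- run_stage("chemometrics", {
    nonblank <- inj$role != "blank"
    complete_cols <- function(m, rows) {
      m[rows, colSums(is.na(m[rows, , drop = FALSE])) == 0, drop = FALSE]
    }
    pre <- pca_model(complete_cols(qa$intensities, nonblank), ncomp = 2)
    post <- pca_model(complete_cols(norm$post_rsd$intensities, nonblank), ncomp = 2)
    list(pca_pre = pre, pca_post = post,
         dispersion_pre = qc_dispersion(pre, inj$role[nonblank]),
         dispersion_post = qc_dispersion(post, inj$role[nonblank]))
  })
  results$chemometrics <- chem
  add("chemometrics", "pca_scores_post", chem$pca_post$scores)

  # 5. mixed-model stats -------------------------------------------------
  stats_res <- run_stage("stats", {
    st <- inj$role == "study"
    m <- results$normalized[st, , drop = FALSE]
    lmm_all_features(m, factor(inj$generation[st], levels = GENERATIONS),
                     ifelse(is.na(inj$family[st]), inj$sample_id[st], inj$family[st]),
                     alpha = config$alpha)
  })
  results$stats <- stats_res
  results$venn <- venn_partition(stats_res$significant[
    c("Infant-Mother", "Infant-Grandmother", "Mother-Grandmother")])
  add("stats", "lmm_results", stats_res$results)

  # 6. ratios ------------------------------------------------------------
  ratios <- run_stage("ratios", {
    st <- inj$role == "study"
    m <- results$normalized[st, , drop = FALSE]
    data.frame(sample_id = inj$sample_id[st],
               generation = factor(inj$generation[st], levels = GENERATIONS),
               scfa_bcfa = scfa_bcfa_ratio(m, annotation = study$metabolome$annotation),
               mufa_pufa = mufa_pufa_ratio(m, annotation = study$metabolome$annotation),
               row.names = NULL)
  })
  results$ratios <- ratios
  add("ratios", "ratios", ratios)

  # 7. ecology -----------------------------------------------------------
  eco <- run_stage("ecology", {
    div <- diversity_summary(study$taxa$counts, meta$generation)
    phy <- aggregate_rank(study$taxa$counts, study$taxa$lineage, "phylum")
    prop <- relative_abundance(study$taxa$counts)
    lump <- lump_minor(prop, meta$generation, cut = 0.02)
    list(diversity = div, phylum = phy, lumped = lump)
  })
  results$ecology <- eco
  add("ecology", "diversity", eco$diversity)

  # 8. functional --------------------------------------------------------
  fun <- run_stage("functional", {
    norm_ko <- tmm_normalize(study$ko$counts)
    bb <- aggregate_brite(study$ko$counts, study$ko$brite_map, "B")
    bc <- aggregate_brite(study$ko$counts, study$ko$brite_map, "C")
    list(ko_normalized = norm_ko,
         level_b = bb, level_c = bc,
         test_b = lm_test_functional(tmm_normalize(bb$table), meta$generation),
         test_ko = lm_test_functional(norm_ko, meta$generation))
  })
  results$functional <- fun
  add("functional", "brite_b_tests", fun$test_b)

  # 9. associations ------------------------------------------------------
  assoc <- run_stage("associations", {
    st <- inj$role == "study"
    m <- results$normalized[st, , drop = FALSE]
    rownames(m) <- inj$sample_id[st]
    prop <- relative_abundance(study$taxa$counts)
    gen <- aggregate_rank(prop, study$taxa$lineage, "genus")
    ann <- study$metabolome$annotation
    name_of <- stats::setNames(ann$feature_id, ann$name)
    pairs <- data.frame(
      taxon = c("Bifidobacterium", "Faecalibacterium", "Roseburia", "Blautia"),
      metabolite = unname(name_of[c("Acetic acid", "Butyric/Isobutyric acid",
                                    "Propionic acid", "Propionic acid")]))
    pairs <- pairs[pairs$metabolite %in% colnames(m), , drop = FALSE]
    cors <- correlate_blocks(gen[rownames(m), , drop = FALSE], m, pairs)
    sets <- pathway_sets_from_annotation(ann)
    hits <- stats_res$results$feature_id[
      !is.na(stats_res$results$q_overall) & stats_res$results$q_overall < config$alpha]
    universe <- intersect(ann$feature_id[!is.na(ann$pathway)], colnames(m))
    sets <- lapply(sets, intersect, universe)
    sets <- sets[vapply(sets, length, 1L) > 0]
    enr <- enrich_all(intersect(hits, universe), sets, universe)
    list(correlations = cors, enrichment = enr)
  })
  results$associations <- assoc
  add("associations", "enrichment", assoc$enrichment)

  # 10. integration ------------------------------------------------------
  integ <- run_stage("integrate", {
    st <- inj$role == "study"
    m <- results$normalized[st, , drop = FALSE]
    rownames(m) <- inj$sample_id[st]
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]     # complete features only
    ids <- meta$sample_id
    taxa_b <- log(relative_abundance(study$taxa$counts) + 1e-6)
    ko_b <- log1p(tmm_normalize(study$ko$counts))
    blocks <- list(metabolites = log(m[ids, , drop = FALSE]),
                   taxa = taxa_b[ids, , drop = FALSE],
                   kos = ko_b[ids, , drop = FALSE])
    labels <- meta$generation
    model <- block_splsda(blocks, labels, ncomp = config$ncomp,
                          keepX = config$keepX)
    perf <- perf_cv(blocks, labels, ncomp = config$ncomp,
                    keepX = config$keepX, folds = config$cv_folds,
                    repeats = config$cv_repeats,
                    seed = config$seed + 7919L)
    list(model = model, perf = perf, auroc = model_auroc(model),
         similarity = similarity_matrix(model, blocks, cutoff = config$cutoff),
         cim = cim_cluster(model, blocks))
  })
  results$integration <- integ
  add("integrate", "auroc", integ$auroc)
  add("integrate", "similarity_edges", integ$similarity)
  add("integrate", "cim_matrix", integ$cim$matrix)
  # sample dendrogram in Newick for external viewers
  nwk <- ape::write.tree(ape::as.phylo(integ$cim$row_hclust))
  writeLines(nwk, file.path(outdir, "cim_sample_dendrogram.nwk"))
  files[[length(files) + 1L]] <- data.frame(
    stage = "integrate", file = "cim_sample_dendrogram.nwk",
    rows = 1L, cols = 1L)

  manifest <- do.call(rbind, files)
  manifest$md5 <- as.character(tools::md5sum(file.path(outdir, manifest$file)))
  structure(list(results = results, manifest = manifest, outdir = outdir,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable run report
#'
#' @param run a `pipeline_run`.
#' @return character vector of report lines (also usable with
#'   `writeLines`).
#' @export
pipeline_report <- function(run) {
  r <- run$results
  sig <- r$stats$significant
  div <- r$ecology$diversity
  lines <- c(
    sprintf("QA (pre-normalization): %s",
            paste(sprintf("%s=%d", r$qa$stages$stage, r$qa$stages$n_features),
                  collapse = " -> ")),
    sprintf("Final features after normalization + RSD gate: %d (all-batch RSD pass %d pre vs %d post)",
            ncol(r$normalized), r$rsd_pass_all$pre, r$rsd_pass_all$post),
    sprintf("QC dispersion ratio: %.3f (raw) -> %.3f (normalized)",
            r$chemometrics$dispersion_pre, r$chemometrics$dispersion_post),
    sprintf("Significant metabolites (FDR < %.2f): overall %d; %s",
            r$stats$alpha,
            sum(r$stats$results$q_overall < r$stats$alpha, na.rm = TRUE),
            paste(sprintf("%s=%d", names(sig), lengths(sig)), collapse = ", ")),
    sprintf("Mean Shannon: %s",
            paste(sprintf("%s=%.2f", levels(div$group),
                          tapply(div$shannon, div$group, mean)),
                  collapse = ", ")),
    sprintf("Enriched pathways (q < 0.05): %d",
            sum(r$associations$enrichment$q < 0.05, na.rm = TRUE)),
    sprintf("Integration: CV error %.3f; comp-1 score correlations %s",
            r$integration$perf$mean_error,
            paste(sprintf("%.2f",
                          r$integration$model$score_correlations[[1]][
                            upper.tri(r$integration$model$score_correlations[[1]])]),
                  collapse = "/")),
    sprintf("Similarity edges above |%.2f|: %d",
            run$config$cutoff, nrow(r$integration$similarity))
  )
  lines
}
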