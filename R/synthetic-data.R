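# Synthetic three-generation cohort generator with full ground truth.
#
# Emulates the data structure of a large-scale fecal multi-omics study:
# three single-generation GC-MS batches with pooled-QC and blank injections,
# multiplicative injection-order drift, per-batch offsets, family-correlated
# generation effects on the log scale, left-censored missingness,
# Dirichlet-multinomial taxa tables and taxa-driven KO tables.

GENERATIONS <- c("Infant", "Mother", "Grandmother")

#' Cohort configuration
#'
#' Describes a three-generation cohort: how many study samples per
#' generation, how many families link them, and the fraction of adult
#' samples whose family link is lost (unlinked samples get a singleton
#' family id so that mixed models remain estimable).
#'
#' Defaults mirror a cohort measured in three single-generation batches of
#' 67 Mothers, 63 Grandmothers and 67 Infants.
#'
#' @param n_per_generation named integer vector of study-sample counts for
#'   Infant, Mother and Grandmother.
#' @param n_families number of families; must be at least the largest
#'   generation count (each family contributes at most one member per
#'   generation).
#' @param missing_family_rate fraction of adult samples detached from their
#'   family (given a private family id).
#' @param seed integer seed; a fixed seed makes every generator downstream
#'   byte-identical.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_generation = c(Infant = 67, Mother = 67, Grandmother = 63),
                          n_families = 67,
                          missing_family_rate = 0.05,
                          seed = 1L) {
  n_per_generation <- as.integer(n_per_generation)
  if (length(n_per_generation) != 3L) {
    stop("n_per_generation must have one count per generation (Infant, Mother, Grandmother)")
  }
  names(n_per_generation) <- GENERATIONS
  if (any(n_per_generation < 1L)) stop("generation counts must be >= 1")
  if (n_families < max(n_per_generation)) {
    stop("n_families (", n_families, ") must be >= the largest generation count (",
         max(n_per_generation), ")")
  }
  if (missing_family_rate < 0 || missing_family_rate >= 1) {
    stop("missing_family_rate must be in [0, 1)")
  }
  structure(list(n_per_generation = n_per_generation,
                 n_families = as.integer(n_families),
                 missing_family_rate = missing_family_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat("  samples:", paste(sprintf("%s=%d", names(x$n_per_generation), x$n_per_generation),
                          collapse = ", "), "\n")
  cat("  families:", x$n_families,
      " missing-family rate:", x$missing_family_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate cohort metadata
#'
#' Builds one study-sample record per participant. Generations are assigned
#' to batches one generation per batch (Mothers in batch 1, Grandmothers in
#' batch 2, Infants in batch 3) and each infant is linked to a mother and
#' grandmother of the same family where those exist.
#'
#' @param config a [cohort_config()].
#' @return list with `metadata` (data frame: sample_id, subject_id, family,
#'   generation, batch, role) and `family_map` (family by generation
#'   membership table).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_generation
  # family f contributes at most one member of generation g;
  # infants take the first families so triads are mostly complete
  fam_of <- list(
    Infant      = sort(sample.int(config$n_families, n[["Infant"]])),
    Mother      = sort(sample.int(config$n_families, n[["Mother"]])),
    Grandmother = sort(sample.int(config$n_families, n[["Grandmother"]]))
  )
  batch_of <- c(Infant = 3L, Mother = 1L, Grandmother = 2L)
  recs <- lapply(GENERATIONS, function(g) {
    fam <- fam_of[[g]]
    data.frame(
      sample_id  = sprintf("%s_%03d", substr(g, 1, 3), seq_along(fam)),
      subject_id = sprintf("S%s%03d", substr(g, 1, 1), fam),
      family     = sprintf("F%03d", fam),
      generation = g,
      batch      = batch_of[[g]],
      role       = "study",
      stringsAsFactors = FALSE
    )
  })
  meta <- do.call(rbind, recs)
  # detach a fraction of adults from their family
  adult <- meta$generation != "Infant"
  lost <- adult & stats::runif(nrow(meta)) < config$missing_family_rate
  if (any(lost)) {
    meta$family[lost] <- sprintf("FX%03d", seq_len(sum(lost)))
  }
  meta$generation <- factor(meta$generation, levels = GENERATIONS)
  rownames(meta) <- NULL
  fam_map <- table(meta$family, meta$generation)
  list(metadata = meta, family_map = fam_map)
}

#' Worklist layout for one batch
#'
#' Orders the injections of a batch: 3 equilibrium QCs first, then study
#' samples with an interspersed QC after roughly every 9-10 samples (8 in
#' total, the last one closing the run), then blank injections. Injection
#' orders are unique and contiguous within the batch.
#'
#' @param n_study number of study samples in the batch.
#' @param n_equilibrium equilibrium QCs at the head of the worklist.
#' @param n_interspersed QCs distributed through the run.
#' @param n_blanks blank injections appended at the end of the run.
#' @return data frame with columns `injection_order` and `role`
#'   (`eqc`, `qc`, `study`, `blank`).
#' @export
worklist_layout <- function(n_study, n_equilibrium = 3L, n_interspersed = 8L,
                            n_blanks = 2L) {
  if (n_study < n_interspersed) stop("fewer study samples than interspersed QCs")
  seg <- diff(round(seq(0, n_study, length.out = n_interspersed + 1L)))
  roles <- c(rep("eqc", n_equilibrium))
  for (s in seg) roles <- c(roles, rep("study", s), "qc")
  roles <- c(roles, rep("blank", n_blanks))
  out <- data.frame(injection_order = seq_along(roles), role = roles,
                    stringsAsFactors = FALSE)
  stopifnot(sum(out$role == "qc") == n_interspersed,
            sum(out$role == "study") == n_study)
  out
}

#' Feature annotation panel
#'
#' Builds the feature table for the metabolome generator. The named panel
#' (SCFAs, BCFAs, the co-eluting linoleic/oleic feature, PUFAs, the two
#' internal standards) is always present; the remainder are generic
#' features assigned to metabolite classes and pathways.
#'
#' @param n_features total number of features (>= the named panel size).
#' @return data frame: feature_id, name, class, pathway, is_standard.
#' @keywords internal
feature_panel <- function(n_features = 150L) {
  named <- data.frame(
    name = c("Acetic acid", "Propionic acid", "Valeric acid", "Caproic acid",
             "Isotridecanoic acid", "Isomyristic acid", "Isopentadecanoic acid",
             "Anteisopentadecanoic acid", "Iso/Anteisopalmitic acid",
             "Isomargaric acid", "Anteisomargaric acid",
             "Linoleic Acid/Oleic Acid", "Arachidonic Acid",
             "Eicosatrienoic Acid", "Docosahexaenoic Acid",
             "Butyric/Isobutyric acid", "Isovaleric acid",
             "Putrescine", "Cadaverine", "Choline", "GABA", "Glucose",
             "Succinate", "Citrate", "Tryptophan", "Indole", "3-Methylindole",
             "Anthranilic acid", "Palmitic acid", "Stearic acid",
             "4-Methylvaleric acid", "Tricosane"),
    class = c(rep("SCFA", 4), rep("BCFA", 7), "MUFA", rep("PUFA", 3),
              "SCFA", "SCFA", "polyamine", "polyamine", "amine", "amino acid",
              "sugar", "organic acid", "organic acid", "amino acid", "indole",
              "indole", "organic acid", "fatty acid", "fatty acid",
              "internal standard", "internal standard"),
    pathway = c("Butanoate metabolism", "Propanoate metabolism",
                "Butanoate metabolism", "Butanoate metabolism",
                rep("Fatty acid biosynthesis", 7),
                rep("Biosynthesis of unsaturated fatty acids", 4),
                "Butanoate metabolism", "Butanoate metabolism",
                "Arginine and proline metabolism", "Lysine degradation",
                "Glycerophospholipid metabolism",
                "Alanine, aspartate and glutamate metabolism",
                "Glycolysis / Gluconeogenesis",
                "Citrate cycle", "Citrate cycle",
                "Tryptophan metabolism", "Tryptophan metabolism",
                "Tryptophan metabolism", "Tryptophan metabolism",
                "Fatty acid biosynthesis", "Fatty acid biosynthesis",
                NA, NA),
    stringsAsFactors = FALSE
  )
  if (n_features < nrow(named)) stop("n_features must be >= ", nrow(named))
  n_extra <- n_features - nrow(named)
  classes <- c("amino acid", "organic acid", "fatty acid", "sugar", "indole", "other")
  pathways <- c("Glycolysis / Gluconeogenesis", "Citrate cycle",
                "Alanine, aspartate and glutamate metabolism",
                "Tryptophan metabolism", "Propanoate metabolism",
                "Fatty acid biosynthesis", "Pentose phosphate pathway",
                "Starch and sucrose metabolism", NA)
  extra <- data.frame(
    name = sprintf("Feature_%03d", seq_len(n_extra)),
    class = sample(classes, n_extra, replace = TRUE),
    pathway = sample(pathways, n_extra, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ann <- rbind(named, extra)
  ann$feature_id <- sprintf("M%03d", seq_len(nrow(ann)))
  ann$is_standard <- ann$class == "internal standard"
  ann[, c("feature_id", "name", "class", "pathway", "is_standard")]
}

#' Ground-truth drift, batch and effect parameters
#'
#' Draws per-feature-by-batch multiplicative drift curves (a random mixture
#' of a linear ramp and a smooth sinusoidal component, strictly positive),
#' per-feature batch offset factors, log-scale generation effects with the
#' directions expected in an infant-vs-adult cohort (acetate and PUFAs up in
#' infants; longer-chain SCFAs, BCFAs and the linoleic/oleic feature up in
#' adults), family intercept and residual standard deviations, missingness
#' and blank-background levels.
#'
#' @param annotation feature table from [feature_panel()].
#' @param n_batches number of batches.
#' @param drift_amplitude range of the absolute drift amplitude across a
#'   batch (fraction of the reference level).
#' @param noise_cv analytical coefficient of variation of replicate
#'   injections (drives QC scatter).
#' @param informative_fraction fraction of the generic features given a
#'   non-zero generation effect.
#' @param effect_range range of |log-scale| generation effect sizes for
#'   informative features.
#' @param family_sd,resid_sd log-scale family-intercept and residual
#'   standard deviations.
#' @param n_contaminants generic features turned into blank-background
#'   contaminants (signal present in blanks at a level comparable to
#'   samples).
#' @param censor_fraction fraction of features subject to left-censoring.
#' @return object of class `drift_truth`: list of parameter tables.
#' @export
drift_truth <- function(annotation,
                        n_batches = 3L,
                        drift_amplitude = c(0.3, 0.8),
                        noise_cv = 0.02,
                        informative_fraction = 0.4,
                        effect_range = c(0.6, 1.5),
                        family_sd = 0.3,
                        resid_sd = 0.4,
                        n_contaminants = 8L,
                        censor_fraction = 0.25) {
  p <- nrow(annotation)
  fid <- annotation$feature_id
  base <- stats::setNames(exp(stats::rnorm(p, mean = 7, sd = 1)), fid)
  # acetate dominates the fecal SCFA pool by an order of magnitude
  base[annotation$name == "Acetic acid"] <- exp(9.5)

  # drift: d(x) = 1 + A * (w * x + (1 - w) * (1 - cos(pi * x)) / 2), x in [0,1]
  amp <- matrix(sample(c(-1, 1), p * n_batches, replace = TRUE) *
                  stats::runif(p * n_batches, drift_amplitude[1], drift_amplitude[2]),
                nrow = p, dimnames = list(fid, NULL))
  wmix <- matrix(stats::runif(p * n_batches), nrow = p, dimnames = list(fid, NULL))
  batch_factor <- matrix(exp(stats::rnorm(p * n_batches, 0, 0.25)),
                         nrow = p, dimnames = list(fid, NULL))
  # internal standards: no biology, gentle drift only
  is_std <- annotation$is_standard

  effects <- matrix(0, nrow = p, ncol = 3, dimnames = list(fid, GENERATIONS))
  set_eff <- function(names_like, infant, adult) {
    idx <- annotation$name %in% names_like
    effects[idx, "Infant"] <<- infant
    effects[idx, "Mother"] <<- adult
    effects[idx, "Grandmother"] <<- adult
  }
  set_eff("Acetic acid", infant = 0.8, adult = 0)
  set_eff(c("Propionic acid", "Valeric acid", "Caproic acid",
            "Butyric/Isobutyric acid", "Isovaleric acid"), infant = 0, adult = 0.9)
  set_eff(c("Isotridecanoic acid", "Isomyristic acid", "Isopentadecanoic acid",
            "Anteisopentadecanoic acid", "Iso/Anteisopalmitic acid",
            "Isomargaric acid", "Anteisomargaric acid"), infant = 0, adult = 1.0)
  set_eff("Linoleic Acid/Oleic Acid", infant = 0, adult = 0.9)
  set_eff(c("Arachidonic Acid", "Eicosatrienoic Acid", "Docosahexaenoic Acid"),
          infant = 0.8, adult = 0)
  set_eff(c("Palmitic acid", "Stearic acid"), infant = 0, adult = 0.6)
  set_eff(c("Putrescine", "Cadaverine", "Choline", "GABA", "Glucose",
            "Succinate", "Citrate"), infant = 0.9, adult = 0)
  set_eff(c("Indole", "3-Methylindole", "Anthranilic acid"), infant = 0, adult = 0.8)
  set_eff("Tryptophan", infant = 0.4, adult = 0)
  # grandmother-vs-mother gradient on the aging-related panel
  aging <- annotation$name %in% c("Isovaleric acid", "Indole", "3-Methylindole")
  effects[aging, "Grandmother"] <- effects[aging, "Grandmother"] + 0.3

  generic <- !annotation$is_standard & rowSums(abs(effects)) == 0
  n_inf <- round(informative_fraction * sum(generic))
  inf_idx <- sample(which(generic), n_inf)
  for (i in inf_idx) {
    sz <- stats::runif(1, effect_range[1], effect_range[2]) * sample(c(-1, 1), 1)
    # either an infant-vs-adults or a monotone-with-age pattern
    if (stats::runif(1) < 0.7) {
      effects[i, ] <- c(sz, 0, 0)
    } else {
      effects[i, ] <- c(0, sz / 2, sz)
    }
  }
  effects <- sweep(effects, 1, rowMeans(effects)) # center per feature

  contaminant <- rep(FALSE, p)
  cand <- which(!annotation$is_standard & rowSums(abs(effects)) < 1e-12)
  contaminant[sample(cand, min(n_contaminants, length(cand)))] <- TRUE
  blank_level <- ifelse(contaminant, base, 0)
  effects[contaminant, ] <- 0

  # only generic features are censored: the named panel (SCFAs, BCFAs,
  # unsaturated fatty acids, amines) sits well above the detection limit
  censored <- grepl("^Feature_", annotation$name) & !contaminant &
    stats::runif(p) < censor_fraction
  censor_q <- ifelse(censored, stats::runif(p, 0.02, 0.15), 0)

  amp[is_std, ] <- amp[is_std, ] * 0.2
  family_sd_v <- ifelse(is_std | contaminant, 0, family_sd)
  resid_sd_v <- ifelse(is_std | contaminant, 0, resid_sd)

  structure(list(
    feature_id = fid,
    base = base,
    drift_amp = amp,
    drift_mix = wmix,
    batch_factor = batch_factor,
    effects = effects,
    family_sd = stats::setNames(family_sd_v, fid),
    resid_sd = stats::setNames(resid_sd_v, fid),
    noise_cv = noise_cv,
    contaminant = stats::setNames(contaminant, fid),
    censor_q = stats::setNames(censor_q, fid),
    blank_level = stats::setNames(blank_level, fid),
    informative = stats::setNames(rowSums(abs(effects)) > 1e-12, fid),
    annotation = annotation
  ), class = "drift_truth")
}

#' Evaluate a truth drift curve
#'
#' @param truth a [drift_truth()] object.
#' @param batch batch index.
#' @param order injection orders.
#' @param order_range min/max injection order of the batch (drift is
#'   parameterized on the normalized position within the batch).
#' @return matrix features x orders of multiplicative drift factors.
#' @export
drift_curve <- function(truth, batch, order, order_range = range(order)) {
  x <- (order - order_range[1]) / max(order_range[2] - order_range[1], 1)
  a <- truth$drift_amp[, batch]
  w <- truth$drift_mix[, batch]
  shape <- outer(w, x) + outer(1 - w, (1 - cos(pi * x)) / 2)
  d <- 1 + a * shape
  stopifnot(all(d > 0))
  d
}

#' Generate a raw multi-batch metabolome matrix
#'
#' QC injections carry the pooled mean of the generation base levels times
#' drift, batch factor and analytical noise; study samples additionally
#' carry generation effects, family intercepts and biological residuals;
#' blanks carry only the blank background. Values below a feature's
#' detection limit are left-censored to `NA`.
#'
#' @param truth a [drift_truth()] object.
#' @param meta study-sample metadata from [generate_cohort()].
#' @param layouts optional list of per-batch worklists; defaults to
#'   [worklist_layout()] sized to each batch.
#' @return list with `intensities` (injections x features), `injections`
#'   (metadata for every injection including QCs and blanks), `annotation`,
#'   and the `truth` object augmented with the drawn family intercepts.
#' @export
generate_metabolome <- function(truth, meta, layouts = NULL) {
  stopifnot(inherits(truth, "drift_truth"))
  p <- length(truth$feature_id)
  batches <- sort(unique(meta$batch))
  if (is.null(layouts)) {
    layouts <- lapply(batches, function(b) {
      ns <- sum(meta$batch == b)
      worklist_layout(ns, n_interspersed = min(8L, ns))
    })
    names(layouts) <- as.character(batches)
  }
  for (b in batches) {
    if (sum(layouts[[as.character(b)]]$role == "study") != sum(meta$batch == b)) {
      stop("worklist layout for batch ", b, " does not match the metadata")
    }
  }
  # family random intercepts per feature
  fams <- unique(meta$family)
  fam_int <- matrix(stats::rnorm(length(fams) * p), nrow = length(fams),
                    dimnames = list(fams, truth$feature_id))
  fam_int <- sweep(fam_int, 2, truth$family_sd, `*`)

  qc_base <- truth$base * rowMeans(exp(truth$effects))
  noise_sd <- sqrt(log(1 + truth$noise_cv^2))

  inj_all <- list(); mat_all <- list()
  for (b in batches) {
    lay <- layouts[[as.character(b)]]
    idx_study <- which(meta$batch == b)
    n_inj <- nrow(lay)
    d <- drift_curve(truth, b, lay$injection_order,
                     order_range = range(lay$injection_order))
    bf <- truth$batch_factor[, b]
    m <- matrix(NA_real_, nrow = n_inj, ncol = p)
    s_ptr <- 0L
    inj <- data.frame(sample_id = character(n_inj), family = NA_character_,
                      generation = NA_character_, batch = b,
                      injection_order = lay$injection_order, role = lay$role,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n_inj)) {
      role <- lay$role[i]
      noise <- exp(stats::rnorm(p, 0, noise_sd))
      if (role %in% c("qc", "eqc")) {
        m[i, ] <- qc_base * d[, i] * bf * noise
        inj$sample_id[i] <- sprintf("B%d_%s_%02d", b, toupper(role), i)
        inj$generation[i] <- "QC"
      } else if (role == "blank") {
        m[i, ] <- truth$blank_level * noise *
          (truth$blank_level > 0) # non-contaminants exactly zero in blanks
        inj$sample_id[i] <- sprintf("B%d_BLANK_%02d", b, i)
        inj$generation[i] <- "Blank"
      } else {
        s_ptr <- s_ptr + 1L
        si <- idx_study[s_ptr]
        g <- as.character(meta$generation[si])
        bio <- exp(truth$effects[, g] + fam_int[meta$family[si], ] +
                     stats::rnorm(p, 0, truth$resid_sd))
        m[i, ] <- truth$base * bio * d[, i] * bf * noise
        inj$sample_id[i] <- meta$sample_id[si]
        inj$family[i] <- meta$family[si]
        inj$generation[i] <- g
      }
    }
    rownames(m) <- inj$sample_id
    colnames(m) <- truth$feature_id
    inj_all[[as.character(b)]] <- inj
    mat_all[[as.character(b)]] <- m
  }
  injections <- do.call(rbind, inj_all)
  rownames(injections) <- NULL
  intensities <- do.call(rbind, mat_all)

  # left-censoring below a per-feature detection limit, on study/QC rows
  for (j in seq_len(p)) {
    q <- truth$censor_q[j]
    if (q > 0) {
      lim <- stats::quantile(intensities[injections$role == "study", j],
                             probs = q, na.rm = TRUE)
      intensities[intensities[, j] < lim & injections$role != "blank", j] <- NA
    }
  }
  truth$family_intercepts <- fam_int
  list(intensities = intensities, injections = injections,
       annotation = truth$annotation, truth = truth)
}

# -- taxa ---------------------------------------------------------------

#' Default genus-level taxon set with lineage
#' @param n_taxa total number of genera (>= 24 named ones).
#' @keywords internal
default_taxa_table <- function(n_taxa = 80L) {
  named <- data.frame(
    genus = c("Bifidobacterium", "Escherichia/Shigella", "Veillonella",
              "Klebsiella", "Lactobacillus", "Enterococcus", "Bacteroides",
              "Faecalibacterium", "Blautia", "Roseburia", "Clostridium_III",
              "Clostridium_IV", "Clostridium_XIVb", "Akkermansia",
              "Prevotella", "Ruminococcus", "Dorea", "Coprococcus",
              "Alistipes", "Parabacteroides", "Desulfovibrio",
              "Streptococcus", "Collinsella", "Dialister"),
    phylum = c("Actinobacteria", "Proteobacteria", "Firmicutes",
               "Proteobacteria", "Firmicutes", "Firmicutes", "Bacteroidetes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Verrucomicrobia",
               "Bacteroidetes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Bacteroidetes", "Bacteroidetes", "Proteobacteria",
               "Firmicutes", "Actinobacteria", "Firmicutes"),
    stringsAsFactors = FALSE
  )
  if (n_taxa < nrow(named)) stop("n_taxa must be >= ", nrow(named))
  n_extra <- n_taxa - nrow(named)
  extra <- data.frame(
    genus = sprintf("Genus_%03d", seq_len(n_extra)),
    phylum = sample(c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                      "Proteobacteria", "Verrucomicrobia", "Fusobacteria"),
                    n_extra, replace = TRUE, prob = c(.5, .2, .1, .1, .05, .05)),
    stringsAsFactors = FALSE
  )
  tab <- rbind(named, extra)
  tab$taxon_id <- sprintf("T%03d", seq_len(nrow(tab)))
  tab$domain <- "Bacteria"
  tab[, c("taxon_id", "domain", "phylum", "genus")]
}

#' Base genus compositions per generation
#'
#' Infants are concentrated on Bifidobacterium, Escherichia/Shigella and
#' Veillonella (expected top-3 share above 50%); adults are flatter, led by
#' Bacteroides, Faecalibacterium, Blautia and Roseburia, with a slightly
#' higher expected Shannon diversity for Grandmothers than Mothers.
#'
#' @param lineage taxon table from [default_taxa_table()].
#' @return matrix taxa x generations of base proportions (columns sum to 1).
#' @export
base_compositions <- function(lineage) {
  n <- nrow(lineage)
  p_inf <- stats::setNames(rep(0, n), lineage$genus)
  p_adu <- p_inf
  p_inf[c("Bifidobacterium", "Escherichia/Shigella", "Veillonella")] <- c(0.32, 0.16, 0.12)
  p_inf[c("Klebsiella", "Lactobacillus", "Enterococcus", "Bacteroides",
          "Streptococcus")] <- c(0.06, 0.05, 0.03, 0.07, 0.02)
  p_adu[c("Bacteroides", "Faecalibacterium", "Blautia", "Roseburia",
          "Clostridium_III", "Clostridium_IV", "Clostridium_XIVb",
          "Akkermansia", "Prevotella", "Ruminococcus", "Dorea", "Coprococcus",
          "Alistipes", "Parabacteroides", "Desulfovibrio", "Collinsella",
          "Dialister")] <-
    c(0.10, 0.08, 0.07, 0.06, 0.03, 0.04, 0.03, 0.02, 0.05, 0.05, 0.03, 0.03,
      0.03, 0.02, 0.01, 0.02, 0.02)
  p_adu[c("Bifidobacterium", "Escherichia/Shigella", "Veillonella")] <- c(0.02, 0.01, 0.01)
  # spread the remaining mass over the filler genera with exponential decay
  fill <- !grepl("^(Bifido|Escher|Veillo)", lineage$genus) & p_inf == 0 & p_adu == 0
  wf <- exp(-0.10 * seq_len(sum(fill)))
  p_inf[fill] <- 0.17 * wf / sum(wf)
  p_adu[fill] <- (1 - sum(p_adu)) * wf^0.5 / sum(wf^0.5)
  p_inf <- p_inf / sum(p_inf)
  p_adu <- p_adu / sum(p_adu)
  # grandmothers: mild tilt toward Akkermansia/Desulfovibrio
  p_gm <- p_adu
  p_gm[c("Akkermansia", "Desulfovibrio")] <- p_gm[c("Akkermansia", "Desulfovibrio")] * 1.6
  p_gm <- p_gm / sum(p_gm)
  out <- cbind(Infant = p_inf, Mother = p_adu, Grandmother = p_gm)
  rownames(out) <- lineage$taxon_id
  out
}

#' Dirichlet draw
#' @keywords internal
r_dirichlet <- function(n, alpha) {
  if (any(alpha < 0)) stop("negative concentration parameters")
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  sweep(g, 1, rowSums(g), `/`)
}

#' Generate taxa count tables
#'
#' Dirichlet-multinomial counts per study sample around generation-specific
#' base compositions; infants are more overdispersed than adults.
#'
#' @param meta study-sample metadata.
#' @param n_taxa number of genera.
#' @param concentration named per-generation Dirichlet concentration
#'   (larger = less overdispersion).
#' @param mean_depth mean library size (log-normal across samples).
#' @return list with `counts` (samples x taxa), `lineage`, `base`
#'   (taxa x generations base proportions) and `library_size`.
#' @export
generate_taxa <- function(meta, n_taxa = 80L,
                          concentration = c(Infant = 35, Mother = 90, Grandmother = 90),
                          mean_depth = 2e4) {
  if (any(concentration <= 0)) stop("negative concentration parameters")
  lineage <- default_taxa_table(n_taxa)
  base <- base_compositions(lineage)
  n <- nrow(meta)
  depth <- pmax(500L, round(stats::rlnorm(n, log(mean_depth), 0.3)))
  counts <- matrix(0L, nrow = n, ncol = n_taxa,
                   dimnames = list(meta$sample_id, lineage$taxon_id))
  for (i in seq_len(n)) {
    g <- as.character(meta$generation[i])
    pr <- r_dirichlet(1, concentration[[g]] * base[, g])[1, ]
    counts[i, ] <- stats::rmultinom(1, depth[i], pr)[, 1]
  }
  list(counts = counts, lineage = lineage, base = base, library_size = depth)
}

# -- KOs ----------------------------------------------------------------

#' Per-taxon genome KO profiles and a BRITE map
#'
#' Each taxon expresses a sparse random subset of the KO universe plus a
#' shared housekeeping core; profile rows sum to one. The BRITE map assigns
#' each KO to one level-B hierarchy and one or (for a random 10%) two
#' level-C hierarchies.
#'
#' @param lineage taxon table.
#' @param n_ko size of the KO universe.
#' @return list with `profiles` (taxa x KO, rows sum to 1) and `brite_map`
#'   (data frame ko / level_b / level_c, one row per membership).
#' @export
genome_profiles <- function(lineage, n_ko = 300L) {
  kos <- sprintf("K%05d", seq_len(n_ko))
  n_taxa <- nrow(lineage)
  core <- seq_len(max(3L, round(0.08 * n_ko)))       # housekeeping core
  profiles <- matrix(0, n_taxa, n_ko, dimnames = list(lineage$taxon_id, kos))
  for (t in seq_len(n_taxa)) {
    own <- sample(setdiff(seq_len(n_ko), core), size = round(0.25 * n_ko))
    w <- stats::setNames(rep(0, n_ko), kos)
    w[core] <- stats::rexp(length(core)) * 2
    w[own] <- stats::rexp(length(own))
    profiles[t, ] <- w / sum(w)
  }
  level_b <- sprintf("B-%02d %s", 1:12,
                     c("Carbohydrate metabolism", "Energy metabolism",
                       "Lipid metabolism", "Amino acid metabolism",
                       "Nucleotide metabolism", "Metabolism of cofactors",
                       "Glycan metabolism", "Translation", "Replication and repair",
                       "Membrane transport", "Signal transduction",
                       "Cellular community"))
  level_c <- sprintf("C-%03d", seq_len(40))
  b_of <- sample(level_b, n_ko, replace = TRUE)
  c_of <- sample(level_c, n_ko, replace = TRUE)
  map <- data.frame(ko = kos, level_b = b_of, level_c = c_of,
                    stringsAsFactors = FALSE)
  dup <- sample(n_ko, round(0.1 * n_ko))
  extra <- data.frame(ko = kos[dup], level_b = b_of[dup],
                      level_c = sample(level_c, length(dup), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(profiles = profiles, brite_map = rbind(map, extra))
}

#' Generate KO count tables from taxa abundances
#'
#' KO counts per sample are multinomial draws from the taxa-abundance-
#' weighted mixture of the genome profiles, so taxa-function correlation is
#' built in.
#'
#' @param taxa output of [generate_taxa()].
#' @param genomes output of [genome_profiles()]; built on the fly if `NULL`.
#' @param mean_depth mean functional library size.
#' @return list with `counts` (samples x KO), `brite_map` and `profiles`.
#' @export
generate_ko <- function(taxa, genomes = NULL, mean_depth = 5e4) {
  if (is.null(genomes)) genomes <- genome_profiles(taxa$lineage)
  profiles <- genomes$profiles
  if (any(abs(rowSums(profiles) - 1) > 1e-6)) {
    stop("genome profile rows must sum to 1")
  }
  if (!all(colnames(taxa$counts) %in% rownames(profiles))) {
    stop("every taxon needs a genome KO profile")
  }
  profiles <- profiles[colnames(taxa$counts), , drop = FALSE]
  rel <- sweep(taxa$counts, 1, pmax(rowSums(taxa$counts), 1), `/`)
  mix <- rel %*% profiles                          # samples x KO expected proportions
  n <- nrow(mix)
  depth <- pmax(1000L, round(stats::rlnorm(n, log(mean_depth), 0.25)))
  counts <- matrix(0L, n, ncol(mix), dimnames = dimnames(mix))
  for (i in seq_len(n)) {
    counts[i, ] <- stats::rmultinom(1, depth[i], mix[i, ])[, 1]
  }
  list(counts = counts, brite_map = genomes$brite_map, profiles = profiles)
}

# -- whole-study wrapper ------------------------------------------------

#' Simulate a complete three-generation multi-omics study
#'
#' One call producing cohort metadata, the raw multi-batch metabolome with
#' QC/blank injections and ground-truth drift, a genus-level taxa table and
#' a KO table, all under a single seed.
#'
#' @param config a [cohort_config()].
#' @param n_features,n_taxa,n_ko block sizes.
#' @param ... further arguments passed to [drift_truth()].
#' @return object of class `triomics_study`.
#' @export
simulate_study <- function(config = cohort_config(), n_features = 150L,
                           n_taxa = 80L, n_ko = 300L, ...) {
  cohort <- generate_cohort(config)           # seeds the RNG from config$seed
  ann <- feature_panel(n_features)
  truth <- drift_truth(ann, ...)
  metab <- generate_metabolome(truth, cohort$metadata)
  taxa <- generate_taxa(cohort$metadata, n_taxa = n_taxa)
  genomes <- genome_profiles(taxa$lineage, n_ko = n_ko)
  ko <- generate_ko(taxa, genomes)
  structure(list(config = config, metadata = cohort$metadata,
                 family_map = cohort$family_map, metabolome = metab,
                 taxa = taxa, ko = ko),
            class = "triomics_study")
}

#' @export
print.triomics_study <- function(x, ...) {
  cat("Synthetic three-generation multi-omics study\n")
  cat(sprintf("  %d study samples, %d families, seed %d\n",
              nrow(x$metadata), length(unique(x$metadata$family)),
              x$config$seed))
  cat(sprintf("  metabolome: %d injections x %d features\n",
              nrow(x$metabolome$intensities), ncol(x$metabolome$intensities)))
  cat(sprintf("  taxa: %d genera   KOs: %d\n",
              ncol(x$taxa$counts), ncol(x$ko$counts)))
  invisible(x)
}

#' Write study tables to a directory
#'
#' Emits metadata, intensity, taxa, KO, lineage, BRITE and ground-truth
#' tables as TSV plus the configuration as a key: value text file.
#'
#' @param study a `triomics_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    path <- file.path(dir, f)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  wm <- function(m, f) {
    d <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    w(d, f)
  }
  truth <- study$metabolome$truth
  truth_tab <- data.frame(feature_id = truth$feature_id,
                          base = truth$base,
                          effect_infant = truth$effects[, "Infant"],
                          effect_mother = truth$effects[, "Mother"],
                          effect_grandmother = truth$effects[, "Grandmother"],
                          family_sd = truth$family_sd,
                          resid_sd = truth$resid_sd,
                          contaminant = truth$contaminant,
                          informative = truth$informative)
  cfg <- study$config
  cfg_lines <- c(sprintf("n_infant: %d", cfg$n_per_generation[["Infant"]]),
                 sprintf("n_mother: %d", cfg$n_per_generation[["Mother"]]),
                 sprintf("n_grandmother: %d", cfg$n_per_generation[["Grandmother"]]),
                 sprintf("n_families: %d", cfg$n_families),
                 sprintf("missing_family_rate: %g", cfg$missing_family_rate),
                 sprintf("seed: %d", cfg$seed))
  cfg_path <- file.path(dir, "config.txt")
  writeLines(cfg_lines, cfg_path)
  paths <- c(
    w(study$metadata, "metadata.tsv"),
    w(study$metabolome$injections, "injections.tsv"),
    wm(study$metabolome$intensities, "intensities.tsv"),
    w(study$metabolome$annotation, "feature_annotation.tsv"),
    wm(study$taxa$counts, "taxa_counts.tsv"),
    w(study$taxa$lineage, "taxa_lineage.tsv"),
    wm(study$ko$counts, "ko_counts.tsv"),
    w(study$ko$brite_map, "brite_map.tsv"),
    w(truth_tab, "ground_truth.tsv"),
    cfg_path
  )
  invisible(paths)
}
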