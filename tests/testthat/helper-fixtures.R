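# Small deterministic fixtures shared across test files.

# a minimal injection layout: 2 batches, 5 interspersed QCs each, blanks
toy_injections <- function(n_study = 10, n_qc = 5, batches = 1:2) {
  do.call(rbind, lapply(batches, function(b) {
    lay <- worklist_layout(n_study, n_equilibrium = 2, n_interspersed = n_qc,
                           n_blanks = 1)
    data.frame(sample_id = sprintf("B%d_I%02d", b, lay$injection_order),
               family = NA_character_, generation = NA_character_,
               batch = b, injection_order = lay$injection_order,
               role = lay$role, stringsAsFactors = FALSE)
  }))
}

# intensity matrix with chosen per-role values, one column per feature spec:
# feature spec = list(study=, qc=, blank=) scalar values
toy_matrix <- function(injections, features) {
  m <- sapply(features, function(f) {
    v <- numeric(nrow(injections))
    v[injections$role == "study"] <- f$study
    v[injections$role %in% c("qc", "eqc")] <- f$qc
    v[injections$role == "blank"] <- f$blank
    v
  })
  rownames(m) <- injections$sample_id
  m
}

# balanced three-generation design for mixed-model tests
lmm_design <- function(n_families = 30) {
  list(generation = factor(rep(c("Infant", "Mother", "Grandmother"),
                               each = n_families),
                           levels = c("Infant", "Mother", "Grandmother")),
       family = rep(sprintf("F%03d", seq_len(n_families)), 3))
}

# all permutations of seq_len(n) -- independent enumeration for oracles
enum_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- enum_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

# literal trimmed-mean-of-M-values oracle (canonical definition: 30% trim
# on M, 5% on A, precision weights, reference = upper-quartile sample
# closest to the mean, factors geometric-mean centered)
tmm_oracle <- function(counts) {
  y <- t(counts)
  lib <- colSums(y)
  f75 <- vapply(seq_len(ncol(y)), function(i) {
    quantile(y[, i], 0.75) / lib[i]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  nf <- vapply(seq_len(ncol(y)), function(i) {
    obs <- y[, i]; rv <- y[, ref]
    no <- lib[i]; nr <- lib[ref]
    keep <- obs > 0 & rv > 0
    logR <- log2((obs / no) / (rv / nr))[keep]
    absE <- ((log2(obs / no) + log2(rv / nr)) / 2)[keep]
    v <- ((no - obs) / (no * obs) + (nr - rv) / (nr * rv))[keep]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    k <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[k] / v[k]) / sum(1 / v[k]))
  }, numeric(1))
  unname(nf / exp(mean(log(nf))))
}

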