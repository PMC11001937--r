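# Headline metabolite-class ratios: SCFA/BCFA and MUFA/PUFA, computed per
# sample from relative abundances.

#' Ratio definitions
#'
#' Canonical metabolite lists for the two fatty-acid class ratios. The
#' SCFA/BCFA numerator is the 4-term short-chain sum, the denominator the
#' 7-term branched-chain sum. The MUFA/PUFA numerator is the single
#' co-eluting "Linoleic Acid/Oleic Acid" feature (one chromatographic
#' peak, not a quotient); the denominator is the 3-term PUFA sum.
#'
#' @format list of `name`, `numerator`, `denominator` character vectors.
#' @export
ratio_definitions <- list(
  scfa_bcfa = list(
    name = "SCFA/BCFA",
    numerator = c("Acetic acid", "Propionic acid", "Valeric acid", "Caproic acid"),
    denominator = c("Isotridecanoic acid", "Isomyristic acid",
                    "Isopentadecanoic acid", "Anteisopentadecanoic acid",
                    "Iso/Anteisopalmitic acid", "Isomargaric acid",
                    "Anteisomargaric acid")),
  mufa_pufa = list(
    name = "MUFA/PUFA",
    numerator = "Linoleic Acid/Oleic Acid",
    denominator = c("Arachidonic Acid", "Eicosatrienoic Acid",
                    "Docosahexaenoic Acid"))
)

# resolve metabolite names to matrix columns, honouring an alias map
resolve_columns <- function(matrix, names_wanted, annotation = NULL,
                            aliases = NULL) {
  cols <- colnames(matrix)
  lookup <- stats::setNames(cols, cols)
  if (!is.null(annotation)) {
    lookup <- c(lookup, stats::setNames(annotation$feature_id, annotation$name))
  }
  if (!is.null(aliases)) {
    lookup <- c(stats::setNames(lookup[aliases], names(aliases)), lookup)
  }
  hit <- lookup[names_wanted]
  missing <- names_wanted[is.na(hit) | !(hit %in% cols)]
  if (length(missing)) {
    stop("metabolite(s) not found in the matrix: ",
         paste(missing, collapse = ", "))
  }
  unname(hit)
}

ratio_from_definition <- function(matrix, def, annotation = NULL,
                                  aliases = NULL) {
  num_cols <- resolve_columns(matrix, def$numerator, annotation, aliases)
  den_cols <- resolve_columns(matrix, def$denominator, annotation, aliases)
  num <- rowSums(matrix[, num_cols, drop = FALSE], na.rm = TRUE)
  den <- rowSums(matrix[, den_cols, drop = FALSE], na.rm = TRUE)
  out <- ifelse(den > 0, num / den, NA_real_)
  if (any(den <= 0)) {
    attr(out, "undefined") <- rownames(matrix)[den <= 0]
  }
  stats::setNames(out, rownames(matrix))
}

#' SCFA/BCFA ratio per sample
#'
#' Sum of the four short-chain fatty-acid abundances divided by the sum of
#' the seven branched-chain fatty-acid abundances. Samples whose BCFA sum
#' is zero get `NA` and are listed in the `undefined` attribute.
#'
#' @param matrix samples x features abundance matrix; columns named either
#'   by metabolite name or by feature id (supply `annotation` to map
#'   feature ids to names).
#' @param annotation optional feature table with `feature_id` and `name`.
#' @param aliases optional named character vector mapping canonical
#'   metabolite names to the names used in this matrix.
#' @return named numeric vector, one ratio per sample.
#' @export
scfa_bcfa_ratio <- function(matrix, annotation = NULL, aliases = NULL) {
  ratio_from_definition(matrix, ratio_definitions$scfa_bcfa, annotation, aliases)
}

#' MUFA/PUFA ratio per sample
#'
#' Abundance of the co-eluting "Linoleic Acid/Oleic Acid" feature divided
#' by the sum of the three polyunsaturated fatty-acid abundances.
#'
#' @inheritParams scfa_bcfa_ratio
#' @return named numeric vector, one ratio per sample.
#' @export
mufa_pufa_ratio <- function(matrix, annotation = NULL, aliases = NULL) {
  ratio_from_definition(matrix, ratio_definitions$mufa_pufa, annotation, aliases)
}
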