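#' Feature-by-sample matrix with phenotype labels
#'
#' The basic container used throughout the package: a numeric matrix of
#' features (rows) by samples (columns) together with the molecular layer of
#' each feature (`"gene"` or `"metabolite"`) and a two-level phenotype label
#' per sample. Gene matrices hold raw counts on input; metabolite matrices
#' hold positive peak heights (or log-abundances after QC).
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   IDs) and colnames (sample IDs).
#' @param kind feature layer: either a single string recycled to all
#'   features, or a character vector of `"gene"`/`"metabolite"` per feature.
#' @param phenotype character or factor of length `ncol(values)` giving each
#'   sample's phenotype level, or a named vector matched to the column names.
#' @param reference the phenotype level to treat as the reference group
#'   (first factor level). Defaults to `"NP"` when present, otherwise the
#'   first level encountered.
#'
#' @return An object of class `omic_matrix`: the values matrix with
#'   attributes `kind` (per-feature) and `phenotype` (per-sample factor,
#'   reference level first).
#' @export
omic_matrix <- function(values, kind, phenotype, reference = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))

  kind <- as.character(kind)
  if (length(kind) == 1L) kind <- rep(kind, nrow(values))
  if (length(kind) != nrow(values))
    stop("'kind' must have length 1 or nrow(values)")
  if (!all(kind %in% c("gene", "metabolite")))
    stop("'kind' entries must be 'gene' or 'metabolite'")

  if (!is.null(names(phenotype))) {
    missing <- setdiff(colnames(values), names(phenotype))
    if (length(missing))
      stop("samples missing from phenotype map: ",
           paste(missing, collapse = ", "))
    phenotype <- phenotype[colnames(values)]
  }
  phenotype <- as.character(phenotype)
  if (length(phenotype) != ncol(values))
    stop("'phenotype' must label every sample")
  lev <- unique(phenotype)
  if (length(lev) != 2L)
    stop("phenotype must have exactly two levels, got: ",
         paste(lev, collapse = ", "))
  if (is.null(reference)) reference <- if ("NP" %in% lev) "NP" else lev[1L]
  if (!reference %in% lev)
    stop("reference level '", reference, "' not among phenotype levels")
  phenotype <- factor(phenotype, levels = c(reference, setdiff(lev, reference)))
  if (any(table(phenotype) < 2L))
    stop("each phenotype level needs at least 2 samples")

  structure(values,
            kind = kind,
            phenotype = phenotype,
            class = c("omic_matrix", "matrix", "array"))
}

#' @export
print.omic_matrix <- function(x, ...) {
  ph <- phenotype(x)
  kd <- table(feature_kind(x))
  cat(sprintf("omic_matrix: %d features (%s) x %d samples\n",
              nrow(x), paste(sprintf("%d %s", kd, names(kd)), collapse = ", "),
              ncol(x)))
  tb <- table(ph)
  cat(sprintf("phenotype: %s (reference = %s)\n",
              paste(sprintf("%s n=%d", names(tb), tb), collapse = ", "),
              levels(ph)[1L]))
  cat(sprintf("value range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
summary.omic_matrix <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Accessors for omic_matrix metadata
#'
#' @param x an [omic_matrix].
#' @return `phenotype()` the per-sample factor (reference level first);
#'   `feature_kind()` the per-feature layer vector; `reference_level()` /
#'   `other_level()` the two phenotype level names; `group_samples()` the
#'   sample IDs belonging to one level.
#' @export
phenotype <- function(x) attr(x, "phenotype")

#' @rdname phenotype
#' @export
feature_kind <- function(x) attr(x, "kind")

#' @rdname phenotype
#' @export
reference_level <- function(x) levels(phenotype(x))[1L]

#' @rdname phenotype
#' @export
other_level <- function(x) levels(phenotype(x))[2L]

#' @rdname phenotype
#' @param group a phenotype level name.
#' @export
group_samples <- function(x, group) {
  ph <- phenotype(x)
  if (!group %in% levels(ph))
    stop("unknown phenotype level '", group, "'")
  colnames(x)[ph == group]
}

# Subset rows/columns while carrying metadata along.
subset_features <- function(x, features) {
  keep <- if (is.character(features)) match(features, rownames(x)) else features
  if (anyNA(keep)) stop("unknown feature IDs in subset")
  omic_matrix(unclass(x)[keep, , drop = FALSE],
              kind = feature_kind(x)[keep],
              phenotype = as.character(phenotype(x)),
              reference = reference_level(x))
}

subset_samples <- function(x, samples) {
  keep <- if (is.character(samples)) match(samples, colnames(x)) else samples
  if (anyNA(keep)) stop("unknown sample IDs in subset")
  vals <- unclass(x)[, keep, drop = FALSE]
  ph <- as.character(phenotype(x))[keep]
  structure(vals,
            kind = feature_kind(x),
            phenotype = factor(ph, levels = levels(phenotype(x))),
            class = c("omic_matrix", "matrix", "array"))
}

# Stack a gene and a metabolite matrix over shared samples (combined layer).
stack_layers <- function(genes, metabs) {
  extra <- union(setdiff(colnames(genes), colnames(metabs)),
                 setdiff(colnames(metabs), colnames(genes)))
  if (length(extra))
    stop("sample mismatch between layers: ", paste(extra, collapse = ", "))
  m <- unclass(metabs)[, colnames(genes), drop = FALSE]
  overlap <- intersect(rownames(genes), rownames(m))
  if (length(overlap))
    stop("feature IDs shared across layers: ", paste(overlap, collapse = ", "))
  omic_matrix(rbind(unclass(genes), m),
              kind = c(feature_kind(genes), feature_kind(metabs)),
              phenotype = as.character(phenotype(genes)),
              reference = reference_level(genes))
}
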