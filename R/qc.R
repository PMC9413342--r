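#' Counts per million
#'
#' Scales each sample (column) of a raw count matrix to counts per million:
#' `cpm(i,j) = counts(i,j) / library_size(j) * 1e6`, where the library size
#' is the column sum of the *unfiltered* input. Apply before any feature
#' filtering so library sizes reflect total sequencing depth.
#'
#' @param counts an [omic_matrix] (or plain matrix) of non-negative counts.
#' @return matrix of the same shape on the CPM scale (an `omic_matrix` when
#'   the input was one).
#' @export
cpm <- function(counts) {
  v <- unclass(counts)
  if (any(v < 0)) stop("counts must be non-negative")
  lib <- colSums(v)
  zero <- colnames(v)[lib == 0]
  if (length(zero))
    stop("all-zero sample column(s): ", paste(zero, collapse = ", "))
  out <- sweep(v, 2L, lib, "/") * 1e6
  if (inherits(counts, "omic_matrix"))
    out <- omic_matrix(out, feature_kind(counts),
                       as.character(phenotype(counts)),
                       reference = reference_level(counts))
  out
}

#' log2(CPM + 1) normalization for count matrices
#'
#' The variance-stabilizing transform used as correlation and model input
#' for the gene layer throughout the pipeline.
#'
#' @inheritParams cpm
#' @return matrix of log2(CPM + 1) values.
#' @export
normalize_counts <- function(counts) {
  out <- cpm(counts)
  out[] <- log2(unclass(out) + 1)
  out
}

new_filter_report <- function(n_input, removed_by_rule, retained_ids) {
  stopifnot(n_input == length(retained_ids) + sum(lengths(removed_by_rule)))
  structure(list(n_input = n_input,
                 n_removed_by_rule = lengths(removed_by_rule),
                 removed_ids = removed_by_rule,
                 n_retained = length(retained_ids),
                 retained_ids = retained_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d retained\n", x$n_input, x$n_retained))
  for (rule in names(x$n_removed_by_rule))
    cat(sprintf("  removed by %-20s %d\n", paste0(rule, ":"),
                x$n_removed_by_rule[[rule]]))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(rule = c(names(x$n_removed_by_rule), "retained"),
             n = c(unname(x$n_removed_by_rule), x$n_retained),
             stringsAsFactors = FALSE)
}

#' Count-level quality filters for the gene layer
#'
#' Removes, in order, (i) features with zero counts in every sample
#' (unexpressed), (ii) features with mean CPM below `cpm_min` (very lowly
#' expressed), and (iii) features present — CPM at or above `present_cpm` —
#' in fewer than `present_frac` of the samples (rarely expressed). Each
#' removal is attributed to the first rule it fails; the retained set equals
#' the intersection of the three rules regardless of order. Filtering is
#' performed on the pooled samples of both groups; returned counts are raw.
#'
#' @param counts raw count [omic_matrix].
#' @param cpm_min mean-CPM threshold for rule (ii) (default 1).
#' @param present_frac minimum fraction of samples in which a feature must
#'   be present for rule (iii) (default 0.5, i.e. at least 50%).
#' @param present_cpm CPM at or above which a feature counts as present in a
#'   sample (default 1, the same unit as rule (ii)).
#' @return list with `matrix` (retained raw counts) and `report`
#'   (a `filter_report`).
#' @export
filter_counts <- function(counts, cpm_min = 1, present_frac = 0.5,
                          present_cpm = 1) {
  v <- unclass(counts)
  cp <- unclass(cpm(counts))
  fail_zero  <- rowSums(v) == 0
  fail_low   <- rowMeans(cp) < cpm_min
  fail_rare  <- rowMeans(cp >= present_cpm) < present_frac
  ids <- rownames(v)
  removed <- list(
    unexpressed     = ids[fail_zero],
    low_expressed   = ids[!fail_zero & fail_low],
    rarely_expressed = ids[!fail_zero & !fail_low & fail_rare])
  keep <- !(fail_zero | fail_low | fail_rare)
  if (!any(keep)) warning("no features survive the count filters")
  out <- subset_features(counts, which(keep))
  list(matrix = out, report = new_filter_report(nrow(v), removed, ids[keep]))
}

#' Per-group metabolite quality control and log normalization
#'
#' Within each phenotype group, computes the relative standard deviation
#' (RSD = sd / mean) of the raw peak heights of each metabolite and retains
#' the metabolite for that group's analyses when RSD <= `rsd_max`. The two
#' groups may retain different sets; the masks are returned alongside one
#' log-transformed matrix covering the union. Values are natural-log
#' transformed; inputs must be positive unless `pseudocount > 0`.
#'
#' @param metab [omic_matrix] of positive peak heights.
#' @param rsd_max RSD retention threshold (default 0.15); boundary value
#'   retained. `Inf` disables the filter (useful for data whose variation is
#'   biological rather than technical).
#' @param pseudocount added before the log (default 0; set 1 for tables
#'   containing zeros).
#' @return list with `matrix` (log-scale values for the union of retained
#'   metabolites), `masks` (named list per group of retained feature IDs)
#'   and `reports` (per-group `filter_report`s).
#' @export
metabolite_qc <- function(metab, rsd_max = 0.15, pseudocount = 0) {
  v <- unclass(metab)
  if (any(v + pseudocount <= 0)) {
    bad <- which(v + pseudocount <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive peak height for feature '", rownames(v)[bad[1L]],
         "' in sample '", colnames(v)[bad[2L]], "'")
  }
  ph <- phenotype(metab)
  masks <- list(); reports <- list()
  for (g in levels(ph)) {
    sub <- v[, ph == g, drop = FALSE]
    rsd <- apply(sub, 1L, stats::sd) / rowMeans(sub)
    keep <- rsd <= rsd_max
    masks[[g]] <- rownames(v)[keep]
    reports[[g]] <- new_filter_report(
      nrow(v), list(rsd_above_threshold = rownames(v)[!keep]),
      rownames(v)[keep])
  }
  union_ids <- union(masks[[1L]], masks[[2L]])
  logm <- log(v[union_ids, , drop = FALSE] + pseudocount)
  out <- omic_matrix(logm, feature_kind(metab)[match(union_ids, rownames(v))],
                     as.character(ph), reference = reference_level(metab))
  list(matrix = out, masks = masks, reports = reports)
}
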