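#' Two-group differential expression / abundance test
#'
#' A transparent stand-in caller used to anchor the network filters: a Welch
#' two-sample t-test per feature, run on log2(CPM + 1) for gene counts and
#' directly on log-normalized abundances for metabolites. The log2 fold
#' change is the difference of group means on the log2 scale with the
#' reference group (default NP) as the minuend, so positive values mean
#' higher expression in the reference group; `fc_direction = "other"` flips
#' the sign. Externally computed differential lists can be used instead via
#' [load_external_calls()].
#'
#' @param x an [omic_matrix]; raw counts when `values = "counts"`,
#'   already-normalized values when `values = "normalized"`.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 0.5).
#' @param values `"counts"` (apply log2(CPM+1) first) or `"normalized"`
#'   (use values as given; metabolite log-abundances are already on a log
#'   scale and their mean difference is rescaled to log2).
#' @param fc_direction `"reference"` (positive log2FC = higher in the
#'   reference group) or `"other"` (flipped).
#' @return a `differential_table` data frame with columns `feature_id`,
#'   `log2fc`, `p_value`, `direction` (`"up"`/`"down"` in the group the sign
#'   convention points to), `significant`, and a BH-adjusted `fdr` column
#'   provided for convenience (not used by the default calling rule).
#' @export
differential_test <- function(x, alpha = 0.05, lfc_min = 0.5,
                              values = c("counts", "normalized"),
                              fc_direction = c("reference", "other")) {
  values <- match.arg(values)
  fc_direction <- match.arg(fc_direction)
  ph <- phenotype(x)
  if (any(table(ph) < 2L)) stop("need >= 2 samples per group")
  v <- if (values == "counts") unclass(normalize_counts(x)) else unclass(x)
  # metabolite log-abundances are natural-log; report fold changes in log2
  scale_fc <- if (values == "normalized" &&
                  all(feature_kind(x) == "metabolite")) 1 / log(2) else 1

  ref <- v[, ph == levels(ph)[1L], drop = FALSE]
  oth <- v[, ph == levels(ph)[2L], drop = FALSE]
  n1 <- ncol(ref); n2 <- ncol(oth)
  m1 <- rowMeans(ref); m2 <- rowMeans(oth)
  s1 <- apply(ref, 1L, stats::var); s2 <- apply(oth, 1L, stats::var)
  se2 <- s1 / n1 + s2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: no evidence, p = 1 (fold change from means)
  p[se2 == 0] <- 1
  lfc <- (m1 - m2) * scale_fc
  if (fc_direction == "other") lfc <- -lfc

  out <- data.frame(feature_id = rownames(v),
                    log2fc = lfc,
                    p_value = p,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    significant = p <= alpha & abs(lfc) >= lfc_min,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "lfc_min") <- lfc_min
  class(out) <- c("differential_table", "data.frame")
  out
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("differential_table: %d features, %d significant (p <= %g, |log2FC| >= %g)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"), attr(x, "lfc_min")))
  print.data.frame(utils::head(x[order(x$p_value), ], 10L), row.names = FALSE)
  invisible(x)
}

#' Call significant features from a differential table
#'
#' Features with `p_value <= alpha` and `|log2fc| >= lfc_min`; both
#' boundaries are inclusive.
#'
#' @param table a `differential_table` (or any data frame with columns
#'   `feature_id`, `p_value`, `log2fc`).
#' @param alpha raw p-value cutoff (default 0.05).
#' @param lfc_min absolute log2 fold-change cutoff (default 0.5).
#' @return character vector of feature IDs.
#' @export
call_significant <- function(table, alpha = 0.05, lfc_min = 0.5) {
  table$feature_id[table$p_value <= alpha & abs(table$log2fc) >= lfc_min]
}

#' Load an externally computed differential feature list
#'
#' Accepts either a plain list of feature IDs (one per line) or a TSV shaped
#' like a `differential_table` (a `feature_id` column, in which case rows
#' flagged in a `significant` column are used when that column exists).
#' IDs absent from `feature_ids` are dropped with a warning naming them.
#'
#' @param path input file.
#' @param feature_ids valid feature IDs to validate against.
#' @return character vector of known feature IDs.
#' @export
load_external_calls <- function(path, feature_ids) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) stop("empty differential-feature file: ", path)
  if (grepl("\t", lines[1L]) || grepl(",", lines[1L])) {
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!"feature_id" %in% colnames(tab))
      stop("tabular differential file needs a 'feature_id' column")
    ids <- if ("significant" %in% colnames(tab))
      tab$feature_id[as.logical(tab$significant)] else tab$feature_id
  } else ids <- lines
  ids <- unique(ids)
  unknown <- setdiff(ids, feature_ids)
  if (length(unknown))
    warning("unknown feature IDs dropped: ", paste(unknown, collapse = ", "))
  intersect(ids, feature_ids)
}
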