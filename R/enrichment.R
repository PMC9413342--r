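#' Build an annotation collection against a background universe
#'
#' Trims every set to the universe and reports how many member IDs were
#' dropped. The universe defaults to all features appearing in any set, but
#' in practice should be the features surviving QC in the relevant layer.
#'
#' @param sets named list of feature-ID vectors (e.g. [read_gmt()] output).
#' @param universe background feature IDs.
#' @return an `annotation_collection`: list with `sets`, `universe`,
#'   `n_trimmed`.
#' @export
annotation_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("annotation sets must be named")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  trimmed <- lapply(sets, intersect, y = universe)
  structure(list(sets = trimmed, universe = universe,
                 n_trimmed = sum(lengths(sets)) - sum(lengths(trimmed))),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("annotation_collection: %d sets over a universe of %d features (%d member IDs trimmed)\n",
              length(x$sets), length(x$universe), x$n_trimmed))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the query features hit the set
#' more often than expected from random draws out of the universe: the raw
#' p-value is the exact upper tail `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` with universe size N, set size K, query
#' size n and k hits. Raw p-values are corrected across sets with the Holm
#' (Bonferroni step-down) procedure.
#'
#' @param query feature IDs of interest; IDs outside the universe are
#'   trimmed with a warning.
#' @param annot an [annotation_collection()].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return an `enrichment_table` data frame: `set_name`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_adjusted`, `significant`.
#' @export
hypergeometric_ora <- function(query, annot, alpha = 0.05) {
  stopifnot(inherits(annot, "annotation_collection"))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query set")
  outside <- setdiff(query, annot$universe)
  if (length(outside)) {
    warning(length(outside), " query feature(s) outside the universe trimmed")
    query <- setdiff(query, outside)
    if (!length(query)) stop("no query features inside the universe")
  }
  N <- length(annot$universe); n <- length(query)
  K <- lengths(annot$sets)
  k <- vapply(annot$sets, function(s) length(intersect(s, query)), 0L)
  # exact upper tail P[X >= k] = phyper(k - 1, K, N - K, n, lower = FALSE)
  p_raw <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- bonferroni_step_down(p_raw)
  out <- data.frame(set_name = names(annot$sets), k = k, K = K, n = n,
                    N = N, p_raw = p_raw, p_adjusted = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d sets tested, %d significant after step-down correction\n",
              nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  invisible(x)
}

#' Bonferroni step-down (Holm) p-value adjustment
#'
#' Sort the m p-values ascending; the i-th smallest is multiplied by
#' `m - i + 1`, capped at 1, and a running maximum enforces monotonicity;
#' adjusted values are returned in the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bonferroni_step_down <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  ord <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1L) * p[ord])
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Joint gene + metabolite pathway analysis
#'
#' Runs layer-wise hypergeometric over-representation for a gene query and
#' a metabolite query against their respective annotation collections, then
#' combines the two raw p-values per pathway with Fisher's method
#' (chi-squared with 4 degrees of freedom on `-2 (ln p_g + ln p_m)`).
#' Pathways named in both collections are combined; a layer missing a
#' pathway contributes p = 1, so combination across layers can only add
#' evidence, never remove it spuriously.
#'
#' @param gene_query,metab_query feature IDs per layer.
#' @param gene_annot,metab_annot [annotation_collection()]s per layer.
#' @param alpha significance level on the combined p (default 0.05).
#' @param fdr_max optional BH-FDR cutoff applied to the combined p-values
#'   (default 0.1); set `NULL` to disable.
#' @return data frame `set_name`, `p_gene`, `p_metab`, `fisher_stat`,
#'   `p_combined`, `fdr`, `significant`, ordered by combined p.
#' @export
joint_pathway <- function(gene_query, metab_query, gene_annot, metab_annot,
                          alpha = 0.05, fdr_max = 0.1) {
  og <- hypergeometric_ora(gene_query, gene_annot)
  om <- hypergeometric_ora(metab_query, metab_annot)
  nm <- union(og$set_name, om$set_name)
  if (!length(intersect(og$set_name, om$set_name)))
    warning("no pathway names shared between the two collections")
  pg <- og$p_raw[match(nm, og$set_name)]; pg[is.na(pg)] <- 1
  pm <- om$p_raw[match(nm, om$set_name)]; pm[is.na(pm)] <- 1
  stat <- -2 * (log(pg) + log(pm))
  p_comb <- stats::pchisq(stat, df = 4, lower.tail = FALSE)
  sig <- p_comb <= alpha
  fdr <- stats::p.adjust(p_comb, "BH")
  if (!is.null(fdr_max)) sig <- sig & fdr <= fdr_max
  out <- data.frame(set_name = nm, p_gene = pg, p_metab = pm,
                    fisher_stat = stat, p_combined = p_comb, fdr = fdr,
                    significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_combined), ]
}
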