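#' Per-group target sets and unique (exclusive) targets
#'
#' A group's targets are its hub features united with its significantly
#' differentially connected features. The unique targets are those
#' exclusive to one group; shared targets appear in both.
#'
#' @param hubs_a,hubs_b hub feature IDs per group (A is conventionally the
#'   reference group).
#' @param dc_a,dc_b differentially connected feature IDs per group.
#' @return list with `targets_a`, `targets_b` (data frames `id`,
#'   `provenance` in `hub` / `differentially_connected` / `both`),
#'   `exclusive_a`, `exclusive_b`, `shared` (character vectors).
#' @export
unique_targets <- function(hubs_a, hubs_b, dc_a, dc_b) {
  prov <- function(hubs, dc) {
    ids <- union(hubs, dc)
    data.frame(id = ids,
               provenance = ifelse(ids %in% hubs & ids %in% dc, "both",
                                   ifelse(ids %in% hubs, "hub",
                                          "differentially_connected")),
               stringsAsFactors = FALSE)
  }
  ta <- prov(hubs_a, dc_a); tb <- prov(hubs_b, dc_b)
  list(targets_a = ta, targets_b = tb,
       exclusive_a = setdiff(ta$id, tb$id),
       exclusive_b = setdiff(tb$id, ta$id),
       shared = intersect(ta$id, tb$id))
}

#' Cross-layer PCIT edges of the combined gene + metabolite network
#'
#' Stacks the normalized gene matrix and the log-scale metabolite matrix
#' over shared samples, runs the PCIT trio test on the combined correlation
#' matrix within one phenotype group, and returns only the gene-metabolite
#' (cross-layer) edges.
#'
#' @param genes normalized gene [omic_matrix] (e.g. [normalize_counts()]
#'   output).
#' @param metabs log-scale metabolite [omic_matrix].
#' @param group phenotype level to analyze.
#' @param keep_all return all cross-layer pairs with flags instead of only
#'   PCIT-significant ones.
#' @return a combined-layer `correlation_network` of cross-layer edges with
#'   `from` always the gene and `to` the metabolite.
#' @export
combined_pcit_pairs <- function(genes, metabs, group, keep_all = FALSE) {
  stacked <- stack_layers(genes, metabs)
  net <- pcit_network(stacked, group = group, keep_all = keep_all)
  nodes <- network_nodes(net)
  kind_of <- stats::setNames(nodes$kind, nodes$id)
  cross <- kind_of[net$from] != kind_of[net$to]
  edges <- as.data.frame(net)[cross, , drop = FALSE]
  flip <- kind_of[edges$from] == "metabolite"
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  new_network(edges, nodes, group = group, layer = "combined")
}

#' Select gene-metabolite pairs by correlation and target anchoring
#'
#' From the cross-layer edges, retains pairs that are PCIT-significant,
#' have `|r| >= r_min`, and have at least one endpoint among the supplied
#' targets (typically the group's *unique* targets). Pass `targets = NULL`
#' to skip the anchoring rule and keep every strong cross-layer pair.
#'
#' @param cross_edges output of [combined_pcit_pairs()].
#' @param targets anchor feature IDs (genes and/or metabolites); an empty
#'   set yields an empty result with a warning.
#' @param r_min absolute correlation floor (default 0.75).
#' @return data frame `gene_id`, `metabolite_id`, `r`, `group`,
#'   `evidence = "pcit"`.
#' @export
select_gm_pairs <- function(cross_edges, targets, r_min = 0.75) {
  keep <- cross_edges$significant & abs(cross_edges$r) >= r_min
  if (!is.null(targets)) {
    if (!length(targets)) {
      warning("empty target set: no gene-metabolite pairs selected")
      keep <- rep(FALSE, length(keep))
    } else {
      keep <- keep & (cross_edges$from %in% targets |
                        cross_edges$to %in% targets)
    }
  }
  sel <- cross_edges[keep, , drop = FALSE]
  data.frame(gene_id = sel$from, metabolite_id = sel$to, r = sel$r,
             group = rep_len(attr(cross_edges, "group"), nrow(sel)),
             evidence = rep_len("pcit", nrow(sel)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Drop the lowest-variance features
#'
#' Quality-control step before pairwise model fitting: removes the
#' `drop_fraction` quantile of features with the smallest variance across
#' all samples. Ties at the cut are retained.
#'
#' @param x an [omic_matrix].
#' @param drop_fraction fraction in \[0, 1) to drop (default 0.05).
#' @return the filtered [omic_matrix].
#' @export
variance_filter <- function(x, drop_fraction = 0.05) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  k <- floor(drop_fraction * nrow(x))
  if (k == 0L) return(x)
  vars <- apply(unclass(x), 1L, stats::var)
  cut <- sort(vars)[k + 1L]
  subset_features(x, which(vars >= cut))
}

#' Phenotype-interaction linear model for one gene-metabolite pair
#'
#' Ordinary least squares fit of
#' `m = b1 + b2 * g + b3 * p + b4 * (g * p) + e`,
#' where `m` is the log-scale metabolite abundance, `g` the normalized gene
#' expression and `p` the phenotype coded 0 for the reference level and 1
#' for the other. A significant interaction coefficient `b4` indicates a
#' phenotype-dependent gene-metabolite relationship. The two-sided p-value
#' for `b4` uses the t distribution with `n - 4` residual degrees of
#' freedom.
#'
#' @param gene numeric vector of normalized gene expression per sample.
#' @param metab numeric vector of log metabolite abundance per sample.
#' @param phenotype factor (reference level first) or 0/1 vector aligned
#'   with the samples.
#' @return one-row data frame `b1`, `b2`, `b3`, `b4`, `se_b4`,
#'   `p_interaction`, or `NULL` with a warning when the design is singular
#'   (e.g. a gene constant within a level).
#' @export
intlim_fit <- function(gene, metab, phenotype) {
  p <- if (is.factor(phenotype)) as.numeric(phenotype) - 1
       else as.numeric(phenotype)
  n <- length(metab)
  X <- cbind(1, gene, p, gene * p)
  fit <- stats::lm.fit(X, metab)
  if (fit$rank < 4L) {
    warning("singular design for pair; skipped")
    return(NULL)
  }
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - 4L
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * rss / df)
  tval <- b[4L] / se[4L]
  data.frame(b1 = b[1L], b2 = b[2L], b3 = b[3L], b4 = b[4L],
             se_b4 = se[4L],
             p_interaction = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
             row.names = NULL)
}

#' Within-group Spearman correlations and their difference
#'
#' Spearman rank correlation of the pair within each phenotype level and
#' the difference `r_other - r_ref` (the non-reference group minus the
#' reference group, e.g. pregnant minus nonpregnant).
#'
#' @inheritParams intlim_fit
#' @return list with `r_ref`, `r_other`, `diff`, `abs_diff`; correlations
#'   are `NA` when a level's values admit no ranking (all tied).
#' @export
spearman_group_difference <- function(gene, metab, phenotype) {
  p <- if (is.factor(phenotype)) as.numeric(phenotype) - 1
       else as.numeric(phenotype)
  grp_cor <- function(sel) {
    g <- gene[sel]; m <- metab[sel]
    if (length(g) < 3L || stats::var(g) == 0 || stats::var(m) == 0)
      return(NA_real_)
    stats::cor(g, m, method = "spearman")
  }
  r_ref <- grp_cor(p == 0); r_other <- grp_cor(p == 1)
  d <- r_other - r_ref
  list(r_ref = r_ref, r_other = r_other, diff = d, abs_diff = abs(d))
}

#' Fit the interaction model over many candidate pairs
#'
#' Applies [intlim_fit()] and [spearman_group_difference()] to every
#' (gene, metabolite) combination of the supplied ID lists.
#'
#' @param genes normalized gene [omic_matrix].
#' @param metabs log-scale metabolite [omic_matrix] over the same samples.
#' @param gene_ids,metab_ids candidate feature IDs (defaults: all rows).
#' @param alpha raw p-value cutoff on the interaction coefficient
#'   (default 0.05).
#' @return data frame with one row per fitted pair: IDs, coefficients,
#'   `p_interaction`, `fdr` (BH), group Spearman correlations,
#'   `spearman_diff`, `significant`, `evidence = "intlim"`.
#' @export
intlim_scan <- function(genes, metabs, gene_ids = rownames(genes),
                        metab_ids = rownames(metabs), alpha = 0.05) {
  samp <- colnames(genes)
  if (!setequal(samp, colnames(metabs)))
    stop("sample mismatch between layers")
  mv <- unclass(metabs)[, samp, drop = FALSE]
  gv <- unclass(genes)
  ph <- phenotype(genes)
  gene_ids <- intersect(gene_ids, rownames(gv))
  metab_ids <- intersect(metab_ids, rownames(mv))
  rows <- vector("list", length(gene_ids) * length(metab_ids))
  i <- 0L
  for (gid in gene_ids) {
    g <- gv[gid, ]
    for (mid in metab_ids) {
      m <- mv[mid, ]
      fit <- withCallingHandlers(
        intlim_fit(g, m, ph),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(fit)) next
      sp <- spearman_group_difference(g, m, ph)
      i <- i + 1L
      rows[[i]] <- cbind(data.frame(gene_id = gid, metabolite_id = mid,
                                    stringsAsFactors = FALSE),
                         fit,
                         data.frame(r_ref = sp$r_ref, r_other = sp$r_other,
                                    spearman_diff = sp$diff))
    }
  }
  out <- do.call(rbind, rows[seq_len(i)])
  if (is.null(out))
    return(data.frame(gene_id = character(), metabolite_id = character()))
  out$fdr <- stats::p.adjust(out$p_interaction, "BH")
  out$significant <- out$p_interaction <= alpha
  out$evidence <- "intlim"
  rownames(out) <- NULL
  out
}

#' Overlap of correlation-selected and model-selected pairs
#'
#' Pairs identified by both routes — the combined-network PCIT selection
#' and the interaction linear model — carry the strongest evidence for a
#' phenotype-dependent gene-metabolite relationship.
#'
#' @param pcit_pairs data frame from [select_gm_pairs()] (possibly several
#'   groups concatenated).
#' @param intlim_pairs data frame from [intlim_scan()]; only rows with
#'   `significant = TRUE` are considered when the column is present.
#' @return data frame of pairs present in both inputs, with the PCIT
#'   correlation, its `sign_call` (`positive`/`negative`), the model
#'   coefficients and `evidence = "both"`.
#' @export
overlap_pairs <- function(pcit_pairs, intlim_pairs) {
  if ("significant" %in% colnames(intlim_pairs))
    intlim_pairs <- intlim_pairs[intlim_pairs$significant, , drop = FALSE]
  key <- function(df) paste(df$gene_id, df$metabolite_id, sep = "\r")
  shared <- intersect(unique(key(pcit_pairs)), unique(key(intlim_pairs)))
  pc <- pcit_pairs[match(shared, key(pcit_pairs)), , drop = FALSE]
  il <- intlim_pairs[match(shared, key(intlim_pairs)), , drop = FALSE]
  if (!length(shared))
    return(data.frame(gene_id = character(), metabolite_id = character()))
  out <- data.frame(gene_id = pc$gene_id, metabolite_id = pc$metabolite_id,
                    r = pc$r, group = pc$group,
                    sign_call = ifelse(pc$r >= 0, "positive", "negative"),
                    b4 = il$b4, p_interaction = il$p_interaction,
                    spearman_diff = il$spearman_diff,
                    evidence = "both",
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
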