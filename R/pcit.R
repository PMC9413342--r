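#' Within-group correlation matrix
#'
#' Pearson (or Spearman) correlation across the samples of one phenotype
#' group. Zero-variance features are dropped with a warning before
#' computing, since their correlation is undefined.
#'
#' @param x an [omic_matrix] holding normalized values (use
#'   [normalize_counts()] on raw counts first).
#' @param group phenotype level to subset to; `NULL` uses all samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, group = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- unclass(x)
  if (!is.null(group)) v <- v[, group_samples(x, group), drop = FALSE]
  if (ncol(v) < 3L)
    stop("need >= 3 samples to estimate correlations (got ", ncol(v), ")")
  vars <- apply(v, 1L, stats::var)
  if (any(vars == 0)) {
    warning("dropping ", sum(vars == 0), " zero-variance feature(s): ",
            paste(utils::head(rownames(v)[vars == 0], 5L), collapse = ", "))
    v <- v[vars > 0, , drop = FALSE]
  }
  C <- stats::cor(t(v), method = method)
  diag(C) <- 1
  C
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of z:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`. Vectorized over
#' its arguments. Undefined (NaN) when a conditioning correlation is +/- 1;
#' the PCIT trio loop skips such trios.
#'
#' @param r_xy,r_xz,r_yz pairwise correlations in \[-1, 1\].
#' @return the partial correlation r_xy.z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

new_network <- function(edges, nodes, group = NA_character_,
                        layer = c("gene", "metabolite", "combined")) {
  layer <- match.arg(layer)
  rownames(edges) <- NULL
  structure(edges, nodes = nodes, group = group, layer = layer,
            class = c("correlation_network", "data.frame"))
}

#' Construct a correlation network from an edge list
#'
#' Builds the weighted undirected network container used by the topology
#' and integration stages, validating that there are no self-edges, no
#' duplicated unordered pairs, and that correlations lie in \[-1, 1\].
#'
#' @param edges data frame with columns `from`, `to` and optionally `r`
#'   (default 1) and `significant` (default `TRUE`).
#' @param nodes optional node table (`id`, `kind`); defaults to the nodes
#'   appearing in the edges, kind `"gene"`.
#' @param group phenotype level annotation.
#' @param layer `"gene"`, `"metabolite"` or `"combined"`.
#' @return a `correlation_network`.
#' @export
correlation_network <- function(edges, nodes = NULL, group = NA_character_,
                                layer = "gene") {
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges need 'from' and 'to' columns")
  if (is.null(edges$r)) edges$r <- 1
  if (is.null(edges$significant)) edges$significant <- TRUE
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicated unordered edge pairs")
  if (any(abs(edges$r) > 1)) stop("correlations must lie in [-1, 1]")
  if (is.null(nodes))
    nodes <- data.frame(id = union(edges$from, edges$to), kind = "gene",
                        stringsAsFactors = FALSE)
  new_network(edges[, c("from", "to", "r", "significant")], nodes,
              group = group, layer = layer)
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network [%s layer%s]: %d nodes, %d edges (%d flagged significant)\n",
              attr(x, "layer"),
              if (is.na(attr(x, "group"))) "" else paste0(", group ", attr(x, "group")),
              nrow(attr(x, "nodes")), nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  invisible(x)
}

#' @rdname network_nodes
#' @export
network_nodes <- function(net) attr(net, "nodes")

#' Node table of a correlation network
#'
#' @param net a `correlation_network`.
#' @return data frame with columns `id` and `kind`.
#' @name network_nodes
NULL

#' PCIT-significant edges of a correlation matrix
#'
#' Runs the partial correlation and information theory (PCIT) edge test:
#' every trio of features is examined, the three first-order partial
#' correlations yield an information-theoretic local tolerance, and an edge
#' whose correlation can be explained through a third feature (below the
#' tolerance-scaled correlations of both alternative paths, strictly) is
#' eliminated. Edges that survive every trio are flagged significant. The
#' trio scan is threshold-free; downstream analyses typically add an
#' absolute-correlation floor via [filter_network()].
#'
#' @param corr symmetric correlation matrix with feature IDs as dimnames.
#' @param kind per-feature layer vector (single string recycled); defaults
#'   to `"gene"`.
#' @param group phenotype level annotation carried on the result.
#' @param layer network layer annotation (`"gene"`, `"metabolite"`,
#'   `"combined"`); defaults to `"gene"` unless all features are
#'   metabolites.
#' @param keep_all if `TRUE`, return every feature pair with its flag; by
#'   default only surviving (significant) edges are returned.
#' @param guard magnitude below which a correlation is treated as zero in
#'   the tolerance denominators (default 1e-12).
#' @return a `correlation_network`: data frame of edges (`from`, `to`, `r`,
#'   `significant`) with the node table, group and layer as attributes.
#'   With fewer than 3 features the trio test is undefined; all non-zero
#'   pairs are returned flagged, with a warning.
#' @export
pcit_significant_edges <- function(corr, kind = "gene", group = NA_character_,
                                   layer = NULL, keep_all = FALSE,
                                   guard = 1e-12) {
  n <- nrow(corr)
  if (is.null(rownames(corr)))
    rownames(corr) <- colnames(corr) <- paste0("f", seq_len(n))
  ids <- rownames(corr)
  kind <- rep_len(as.character(kind), n)
  if (is.null(layer))
    layer <- if (all(kind == "metabolite")) "metabolite"
             else if (length(unique(kind)) > 1L) "combined" else "gene"
  if (n < 3L) {
    warning("fewer than 3 features: PCIT trio test skipped, ",
            "returning all non-zero-correlation pairs as significant")
    keep <- abs(corr) > guard
  } else {
    keep <- pcit_keep_cpp(unname(corr), guard)
  }
  ut <- upper.tri(keep)
  sel <- if (keep_all) ut else (ut & keep)
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]],
                      to = ids[idx[, 2L]],
                      r = corr[sel],
                      significant = keep[sel],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
  new_network(edges, nodes, group = group, layer = layer)
}

#' Apply correlation and differential-expression filters to a network
#'
#' Retains edges that are PCIT-significant, have `|r| >= r_min`, and — the
#' differential anchoring rule — have at least one endpoint in
#' `de_features`. Nodes left without any surviving edge are dropped from the
#' node table. The defaults mirror the layer conventions `r_min = 0.99`
#' (genes) and `0.9` (metabolites); pass the value explicitly.
#'
#' @param net a `correlation_network`.
#' @param de_features differential feature IDs anchoring the network;
#'   required unless `require_de = FALSE`.
#' @param r_min absolute correlation floor.
#' @param require_de set `FALSE` to skip the differential anchoring rule.
#' @return the filtered `correlation_network`.
#' @export
filter_network <- function(net, de_features = NULL, r_min,
                           require_de = TRUE) {
  keep <- net$significant & abs(net$r) >= r_min
  if (require_de) {
    if (is.null(de_features) || !length(de_features))
      stop("differential anchoring requires a non-empty 'de_features' ",
           "(use require_de = FALSE to disable)")
    keep <- keep & (net$from %in% de_features | net$to %in% de_features)
  }
  edges <- net[keep, , drop = FALSE]
  nodes <- network_nodes(net)
  nodes <- nodes[nodes$id %in% union(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- NULL
  new_network(as.data.frame(edges), nodes,
              group = attr(net, "group"), layer = attr(net, "layer"))
}

#' Per-group PCIT co-expression network from a feature matrix
#'
#' Convenience wrapper: subsets the group's samples, computes the
#' correlation matrix and runs [pcit_significant_edges()].
#'
#' @inheritParams correlation_matrix
#' @inheritParams pcit_significant_edges
#' @return a `correlation_network` for the group.
#' @export
pcit_network <- function(x, group = NULL, method = c("pearson", "spearman"),
                         keep_all = FALSE) {
  C <- correlation_matrix(x, group = group, method = method)
  kind <- feature_kind(x)[match(rownames(C), rownames(x))]
  pcit_significant_edges(C, kind = kind,
                         group = if (is.null(group)) NA_character_ else group,
                         keep_all = keep_all)
}

#' Write a network as a Cytoscape SIF file
#'
#' One line per edge: `source <relation> target`; isolated nodes are
#' written as bare node lines, as SIF allows.
#'
#' @param net a `correlation_network` (or any data frame with `from`/`to`).
#' @param path output path.
#' @param relation interaction label (default `"co"`).
#' @export
write_sif <- function(net, path, relation = "co") {
  lines <- sprintf("%s\t%s\t%s", net$from, relation, net$to)
  nodes <- network_nodes(net)
  if (!is.null(nodes)) {
    isolated <- setdiff(nodes$id, union(net$from, net$to))
    lines <- c(lines, isolated)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' Columns `source`, `target`, `r`, `significant`.
#'
#' @inheritParams write_sif
#' @export
write_edges <- function(net, path) {
  df <- data.frame(source = net$from, target = net$to, r = net$r,
                   significant = net$significant, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
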