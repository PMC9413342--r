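as_igraph <- function(net) {
  nodes <- network_nodes(net)
  ids <- if (!is.null(nodes)) nodes$id else union(net$from, net$to)
  igraph::graph_from_data_frame(
    data.frame(from = net$from, to = net$to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ids))
}

#' Node degree and betweenness centrality
#'
#' Degree is the number of incident edges; betweenness is the exact
#' (Brandes) shortest-path betweenness of the undirected, unweighted graph,
#' unnormalized by default. Pairs in different components contribute
#' nothing.
#'
#' @param net a `correlation_network`.
#' @param normalized divide betweenness by `(N-1)(N-2)/2` (the Cytoscape
#'   Network Analyzer convention) when `TRUE`; default `FALSE`.
#' @return a `topology_table` data frame: `node_id`, `degree`,
#'   `betweenness`.
#' @export
network_topology <- function(net, normalized = FALSE) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  out <- data.frame(node_id = igraph::V(g)$name,
                    degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("topology_table", "data.frame")
  out
}

#' @rdname network_topology
#' @export
node_degrees <- function(net) network_topology(net)[, c("node_id", "degree")]

#' @rdname network_topology
#' @export
node_betweenness <- function(net, normalized = FALSE)
  network_topology(net, normalized)[, c("node_id", "betweenness")]

#' Call hub nodes from a topology table
#'
#' Hubs are nodes passing both a degree and a betweenness threshold. With
#' the lenient boundary (`betweenness_strict = FALSE`) the rule
#' `degree >= 1, betweenness >= 0` admits every non-isolated node; the
#' default practical rule requires strictly positive betweenness, i.e.
#' nodes actually lying on shortest paths between others. `top_k` instead
#' selects the k highest-degree nodes (ties broken by betweenness).
#'
#' @param topo a `topology_table`.
#' @param min_degree minimum degree (default 1).
#' @param min_betweenness betweenness threshold (default 0).
#' @param betweenness_strict `TRUE` (default) requires
#'   `betweenness > min_betweenness`; `FALSE` uses `>=`.
#' @param top_k optional: return the k most-connected nodes instead of
#'   thresholding.
#' @return character vector of hub node IDs.
#' @export
call_hubs <- function(topo, min_degree = 1, min_betweenness = 0,
                      betweenness_strict = TRUE, top_k = NULL) {
  if (!is.null(top_k)) {
    ord <- order(-topo$degree, -topo$betweenness)
    return(topo$node_id[utils::head(ord, top_k)])
  }
  ok_b <- if (betweenness_strict) topo$betweenness > min_betweenness
          else topo$betweenness >= min_betweenness
  topo$node_id[topo$degree >= min_degree & ok_b]
}

#' Central reference (union) network of two group networks
#'
#' Builds the union of two networks from the same layer and annotates every
#' node and edge with its membership: present only in the first network,
#' only in the second, or shared. This is the "central reference network"
#' used to display rewiring between phenotype groups; export it with
#' [write_sif()] plus the node-attribute table for rendering elsewhere.
#'
#' @param netA,netB `correlation_network`s of the same layer (A is
#'   conventionally the reference group's network).
#' @return a `union_network`: list with `edges` (`from`, `to`, `membership`,
#'   `r_A`, `r_B`), `nodes` (`id`, `kind`, `membership`) and `counts`.
#' @export
union_reference_network <- function(netA, netB) {
  if (!identical(attr(netA, "layer"), attr(netB, "layer")))
    stop("layer mismatch: ", attr(netA, "layer"), " vs ", attr(netB, "layer"))
  key <- function(net) {
    a <- pmin(net$from, net$to); b <- pmax(net$from, net$to)
    paste(a, b, sep = "\r")
  }
  kA <- key(netA); kB <- key(netB)
  all_keys <- union(kA, kB)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  membership <- ifelse(all_keys %in% kA & all_keys %in% kB, "shared",
                       ifelse(all_keys %in% kA, "A-only", "B-only"))
  edges <- data.frame(from = parts[, 1L], to = parts[, 2L],
                      membership = membership,
                      r_A = netA$r[match(all_keys, kA)],
                      r_B = netB$r[match(all_keys, kB)],
                      stringsAsFactors = FALSE)
  nA <- network_nodes(netA); nB <- network_nodes(netB)
  ids <- union(nA$id, nB$id)
  nodes <- data.frame(
    id = ids,
    kind = ifelse(ids %in% nA$id, nA$kind[match(ids, nA$id)],
                  nB$kind[match(ids, nB$id)]),
    membership = ifelse(ids %in% nA$id & ids %in% nB$id, "shared",
                        ifelse(ids %in% nA$id, "A-only", "B-only")),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes,
                 counts = list(nodes = table(nodes$membership),
                               edges = table(edges$membership)),
                 layer = attr(netA, "layer")),
            class = "union_network")
}

#' @export
print.union_network <- function(x, ...) {
  cat(sprintf("union_network [%s layer]: %d nodes, %d edges\n",
              x$layer, nrow(x$nodes), nrow(x$edges)))
  cat("node membership: ")
  print(x$counts$nodes)
  cat("edge membership: ")
  print(x$counts$edges)
  invisible(x)
}

#' Differential connectivity between two group networks
#'
#' For every node of the union node set, the differential-connectivity
#' index is the degree difference `DK = K_ref - K_other` (nodes absent from
#' a network count degree 0 there). DK is standardized across nodes to
#' `z = (DK - mean(DK)) / sd(DK)`; nodes with `|z| >= z_crit` are
#' significantly differentially connected. A `gain` call means
#' significantly more connections in the reference network, `loss` the
#' opposite — swapping the two inputs negates every DK and z and swaps the
#' calls.
#'
#' @param net_ref the reference group's `correlation_network`.
#' @param net_other the other group's network.
#' @param z_crit significance cutoff on |z| (default 1.96, the two-sided 5%
#'   standard-normal critical point).
#' @param nodes node universe over which DK is standardized; defaults to
#'   the union of the two networks' node tables. Pass the full feature set
#'   to standardize against all analyzed features.
#' @return a `diffconn_table` data frame: `node_id`, `k_ref`, `k_other`,
#'   `dk`, `z`, `significant`, `call`; attributes `mu` and `sigma`.
#' @export
differential_connectivity <- function(net_ref, net_other, z_crit = 1.96,
                                      nodes = NULL) {
  dr <- node_degrees(net_ref); do <- node_degrees(net_other)
  ids <- if (is.null(nodes)) union(dr$node_id, do$node_id)
         else unique(as.character(nodes))
  k_ref <- dr$degree[match(ids, dr$node_id)]; k_ref[is.na(k_ref)] <- 0L
  k_other <- do$degree[match(ids, do$node_id)]; k_other[is.na(k_other)] <- 0L
  dk <- k_ref - k_other
  mu <- mean(dk); sigma <- stats::sd(dk)
  if (length(dk) < 2L || is.na(sigma) || sigma == 0) {
    warning("sd(DK) is zero; z-scores undefined, no significant calls")
    z <- rep(NA_real_, length(dk))
  } else z <- (dk - mu) / sigma
  sig <- !is.na(z) & abs(z) >= z_crit
  out <- data.frame(node_id = ids, k_ref = k_ref, k_other = k_other,
                    dk = dk, z = z,
                    significant = sig,
                    call = ifelse(sig & z > 0, "gain",
                                  ifelse(sig & z < 0, "loss", "none")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "z_crit") <- z_crit
  class(out) <- c("diffconn_table", "data.frame")
  out
}

#' @export
print.diffconn_table <- function(x, ...) {
  cat(sprintf("diffconn_table: %d nodes, %d significant at |z| >= %g (%d gain, %d loss)\n",
              nrow(x), sum(x$significant), attr(x, "z_crit"),
              sum(x$call == "gain"), sum(x$call == "loss")))
  print.data.frame(utils::head(x[order(-abs(x$z)), ], 10L), row.names = FALSE)
  invisible(x)
}
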