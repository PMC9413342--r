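#' Pipeline configuration
#'
#' Collects every threshold of the workflow with the study's defaults:
#' differential calls at raw `p <= 0.05` and `|log2FC| >= 0.5`; per-group
#' PCIT networks kept at `|r| >= 0.99` (genes) and `>= 0.90` (metabolites)
#' with differential-feature anchoring; metabolite QC at RSD `<= 0.15`;
#' differential connectivity at `|z| >= 1.96`; gene-metabolite pairs at
#' `|r| >= 0.75` anchored on unique targets; lowest 5% variance genes
#' excluded before the interaction model.
#'
#' @param alpha raw p-value level for differential calls and the
#'   interaction model.
#' @param lfc_min minimum absolute log2 fold change.
#' @param r_gene,r_metab,r_gm absolute-correlation floors for the gene,
#'   metabolite and cross-layer networks.
#' @param rsd_max metabolite RSD retention threshold; `Inf` disables the
#'   filter (appropriate when metabolite variation is biological rather
#'   than technical replication noise).
#' @param z_crit differential-connectivity cutoff on |z|.
#' @param var_drop fraction of lowest-variance genes excluded before the
#'   interaction model.
#' @param hub_betweenness_strict hub rule: `TRUE` (default) requires
#'   betweenness strictly above the threshold, `FALSE` uses the lenient
#'   `>= 0` boundary that admits every non-isolated node.
#' @param candidate_rule candidate universe for the interaction model:
#'   `"targets"` (differential features plus targets, the study design) or
#'   `"all"` (every variance-filtered gene against every metabolite).
#' @param metab_integration which metabolites enter the combined network:
#'   `"qc_union"` (union of the per-group QC-retained sets) or `"all"`
#'   (the full pre-QC table, log-transformed).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, lfc_min = 0.5, r_gene = 0.99,
                            r_metab = 0.90, r_gm = 0.75, rsd_max = 0.15,
                            z_crit = 1.96, var_drop = 0.05,
                            hub_betweenness_strict = TRUE,
                            candidate_rule = c("targets", "all"),
                            metab_integration = c("qc_union", "all")) {
  candidate_rule <- match.arg(candidate_rule)
  metab_integration <- match.arg(metab_integration)
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stop("'", nm, "' must be a number in [", lo, ", ", hi, "]")
  }
  chk01(alpha, "alpha"); chk01(lfc_min, "lfc_min", 0, Inf)
  chk01(r_gene, "r_gene"); chk01(r_metab, "r_metab"); chk01(r_gm, "r_gm")
  if (!(is.numeric(rsd_max) && (is.infinite(rsd_max) || rsd_max >= 0)))
    stop("'rsd_max' must be non-negative or Inf")
  chk01(z_crit, "z_crit", 0, Inf); chk01(var_drop, "var_drop", 0, 1 - 1e-9)
  structure(list(alpha = alpha, lfc_min = lfc_min, r_gene = r_gene,
                 r_metab = r_metab, r_gm = r_gm, rsd_max = rsd_max,
                 z_crit = z_crit, var_drop = var_drop,
                 hub_betweenness_strict = hub_betweenness_strict,
                 candidate_rule = candidate_rule,
                 metab_integration = metab_integration),
            class = "pipeline_config")
}

#' Run the full co-expression and integration workflow
#'
#' Executes, in order: count and metabolite QC, differential testing (or
#' externally supplied differential lists), per-group PCIT networks with
#' correlation and differential-anchoring filters, topology and hub calls,
#' union reference networks, differential connectivity, unique-target
#' derivation, per-group combined-layer PCIT and gene-metabolite pair
#' selection, gene variance filtering, the phenotype-interaction linear
#' model with group Spearman differences, the PCIT/model overlap, and —
#' when annotation collections are supplied — pathway over-representation.
#' The run is deterministic: no step draws random numbers.
#'
#' @param genes raw count [omic_matrix] (kind `"gene"`).
#' @param metabolites peak-height [omic_matrix] (kind `"metabolite"`).
#' @param config a [pipeline_config()].
#' @param de_genes,de_metabolites optional externally computed differential
#'   feature IDs; when `NULL` the built-in Welch test is used.
#' @param gene_annotation,metab_annotation optional [annotation_collection()]s
#'   for the enrichment stage.
#' @return a `gm_pipeline` object: a list of every stage artifact plus a
#'   `manifest` of stage counts.
#' @export
run_pipeline <- function(genes, metabolites, config = pipeline_config(),
                         de_genes = NULL, de_metabolites = NULL,
                         gene_annotation = NULL, metab_annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- reference_level(genes); oth <- other_level(genes)

  ## --- QC -----------------------------------------------------------------
  gqc <- filter_counts(genes)
  g_norm <- subset_features(normalize_counts(genes),
                            gqc$report$retained_ids)
  mqc <- metabolite_qc(metabolites, rsd_max = config$rsd_max)
  m_log <- if (config$metab_integration == "all") {
    tmp <- unclass(metabolites)
    omic_matrix(log(tmp), "metabolite", as.character(phenotype(metabolites)),
                reference = ref)
  } else mqc$matrix

  ## --- differential features ---------------------------------------------
  de_tab_g <- differential_test(g_norm, alpha = config$alpha,
                                lfc_min = config$lfc_min,
                                values = "normalized")
  de_tab_m <- differential_test(m_log, alpha = config$alpha,
                                lfc_min = config$lfc_min,
                                values = "normalized")
  if (is.null(de_genes))
    de_genes <- call_significant(de_tab_g, config$alpha, config$lfc_min)
  if (is.null(de_metabolites))
    de_metabolites <- call_significant(de_tab_m, config$alpha,
                                       config$lfc_min)

  ## --- per-group networks -------------------------------------------------
  nets <- list(); topo <- list(); hubs <- list()
  for (g in c(ref, oth)) {
    gn <- filter_network(pcit_network(g_norm, group = g),
                         de_genes, config$r_gene,
                         require_de = length(de_genes) > 0)
    mm <- subset_features(m_log, intersect(mqc$masks[[g]], rownames(m_log)))
    mn <- filter_network(pcit_network(mm, group = g),
                         de_metabolites, config$r_metab,
                         require_de = length(de_metabolites) > 0)
    nets[[g]] <- list(gene = gn, metabolite = mn)
    topo[[g]] <- list(gene = network_topology(gn),
                      metabolite = network_topology(mn))
    hubs[[g]] <- list(
      gene = call_hubs(topo[[g]]$gene,
                       betweenness_strict = config$hub_betweenness_strict),
      metabolite = call_hubs(topo[[g]]$metabolite,
                             betweenness_strict = config$hub_betweenness_strict))
  }

  ## --- network comparison -------------------------------------------------
  union_nets <- list(gene = union_reference_network(nets[[ref]]$gene,
                                                    nets[[oth]]$gene),
                     metabolite = union_reference_network(
                       nets[[ref]]$metabolite, nets[[oth]]$metabolite))
  dc <- list(gene = differential_connectivity(nets[[ref]]$gene,
                                              nets[[oth]]$gene,
                                              z_crit = config$z_crit),
             metabolite = differential_connectivity(nets[[ref]]$metabolite,
                                                    nets[[oth]]$metabolite,
                                                    z_crit = config$z_crit))
  dc_ref <- unlist(lapply(dc, function(d) d$node_id[d$call == "gain"]),
                   use.names = FALSE)
  dc_oth <- unlist(lapply(dc, function(d) d$node_id[d$call == "loss"]),
                   use.names = FALSE)
  targets <- unique_targets(c(hubs[[ref]]$gene, hubs[[ref]]$metabolite),
                            c(hubs[[oth]]$gene, hubs[[oth]]$metabolite),
                            dc_ref, dc_oth)

  ## --- integration ---------------------------------------------------------
  excl <- list(); excl[[ref]] <- targets$exclusive_a
  excl[[oth]] <- targets$exclusive_b
  gm_pairs <- list()
  for (g in c(ref, oth)) {
    cross <- combined_pcit_pairs(g_norm, m_log, group = g)
    gm_pairs[[g]] <- select_gm_pairs(
      cross,
      targets = if (length(excl[[g]])) excl[[g]] else character(),
      r_min = config$r_gm)
  }
  pcit_pairs <- do.call(rbind, gm_pairs)

  g_var <- variance_filter(g_norm, config$var_drop)
  if (config$candidate_rule == "targets") {
    cand_genes <- intersect(
      union(de_genes, c(targets$targets_a$id, targets$targets_b$id)),
      rownames(g_var))
    cand_metabs <- intersect(
      union(de_metabolites, c(targets$targets_a$id, targets$targets_b$id)),
      rownames(m_log))
  } else {
    cand_genes <- rownames(g_var)
    cand_metabs <- rownames(m_log)
  }
  intlim <- intlim_scan(g_var, m_log, cand_genes, cand_metabs,
                        alpha = config$alpha)
  overlap <- overlap_pairs(pcit_pairs, intlim)

  ## --- enrichment ----------------------------------------------------------
  enrich <- NULL
  if (!is.null(gene_annotation)) {
    query <- unique(c(de_genes, targets$targets_a$id, targets$targets_b$id))
    query <- intersect(query, gene_annotation$universe)
    enrich <- list(gene = hypergeometric_ora(query, gene_annotation,
                                             alpha = config$alpha))
    if (!is.null(metab_annotation) && nrow(overlap)) {
      enrich$joint <- joint_pathway(
        intersect(overlap$gene_id, gene_annotation$universe),
        intersect(overlap$metabolite_id, metab_annotation$universe),
        gene_annotation, metab_annotation, alpha = config$alpha)
    }
  }

  manifest <- list(
    n_genes_input = nrow(genes),
    n_genes_retained = gqc$report$n_retained,
    n_metabolites_input = nrow(metabolites),
    n_metabolites_retained = stats::setNames(
      lengths(mqc$masks), names(mqc$masks)),
    n_de_genes = length(de_genes),
    n_de_metabolites = length(de_metabolites),
    gene_network_edges = vapply(nets, function(x) nrow(x$gene), 0L),
    metab_network_edges = vapply(nets, function(x) nrow(x$metabolite), 0L),
    n_hubs = vapply(hubs, function(h) length(h$gene) + length(h$metabolite), 0L),
    n_diffconn = c(gain = length(dc_ref), loss = length(dc_oth)),
    n_targets = c(length(targets$targets_a$id), length(targets$targets_b$id)),
    n_shared_targets = length(targets$shared),
    n_exclusive = c(length(targets$exclusive_a), length(targets$exclusive_b)),
    n_pcit_pairs = vapply(gm_pairs, nrow, 0L),
    n_intlim_pairs_tested = nrow(intlim),
    n_intlim_significant = sum(intlim$significant %in% TRUE),
    n_overlap_pairs = nrow(overlap),
    config = unclass(config))

  structure(list(config = config, qc = list(genes = gqc, metabolites = mqc),
                 normalized = list(genes = g_norm, metabolites = m_log),
                 de = list(gene_table = de_tab_g, metab_table = de_tab_m,
                           de_genes = de_genes,
                           de_metabolites = de_metabolites),
                 networks = nets, topology = topo, hubs = hubs,
                 union_networks = union_nets,
                 differential_connectivity = dc,
                 targets = targets, pcit_pairs = pcit_pairs,
                 intlim = intlim, overlap = overlap,
                 enrichment = enrich, manifest = manifest),
            class = "gm_pipeline")
}

#' @export
print.gm_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("gm_pipeline run\n")
  cat(sprintf("  genes: %d -> %d after count QC; %d differential\n",
              m$n_genes_input, m$n_genes_retained, m$n_de_genes))
  cat(sprintf("  metabolites: %d input; retained per group: %s; %d differential\n",
              m$n_metabolites_input,
              paste(sprintf("%s=%d", names(m$n_metabolites_retained),
                            m$n_metabolites_retained), collapse = ", "),
              m$n_de_metabolites))
  cat(sprintf("  gene network edges: %s | metabolite: %s\n",
              paste(sprintf("%s=%d", names(m$gene_network_edges),
                            m$gene_network_edges), collapse = ", "),
              paste(sprintf("%s=%d", names(m$metab_network_edges),
                            m$metab_network_edges), collapse = ", ")))
  cat(sprintf("  hubs: %s | differentially connected: gain=%d loss=%d\n",
              paste(sprintf("%s=%d", names(m$n_hubs), m$n_hubs),
                    collapse = ", "),
              m$n_diffconn[["gain"]], m$n_diffconn[["loss"]]))
  cat(sprintf("  targets: %d / %d (shared %d; exclusive %d / %d)\n",
              m$n_targets[1L], m$n_targets[2L], m$n_shared_targets,
              m$n_exclusive[1L], m$n_exclusive[2L]))
  cat(sprintf("  gene-metabolite pairs: PCIT %s; model-tested %d, significant %d; overlap %d\n",
              paste(sprintf("%s=%d", names(m$n_pcit_pairs), m$n_pcit_pairs),
                    collapse = ", "),
              m$n_intlim_pairs_tested, m$n_intlim_significant,
              m$n_overlap_pairs))
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' Deterministic TSV/SIF export of all tables and networks of a
#' [run_pipeline()] result; rerunning the same configuration on the same
#' data rewrites byte-identical files.
#'
#' @param run a `gm_pipeline` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_pipeline <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c()
  w <- function(df, path) { write_tsv(as.data.frame(df), path); path }
  paths <- c(paths,
             w(run$de$gene_table, p("de_genes.tsv")),
             w(run$de$metab_table, p("de_metabolites.tsv")))
  for (g in names(run$networks)) {
    for (layer in c("gene", "metabolite")) {
      net <- run$networks[[g]][[layer]]
      paths <- c(paths,
                 write_edges(net, p("network_", layer, "_", g, ".tsv")),
                 write_sif(net, p("network_", layer, "_", g, ".sif")),
                 w(run$topology[[g]][[layer]], p("topology_", layer, "_", g, ".tsv")))
    }
  }
  for (layer in c("gene", "metabolite")) {
    un <- run$union_networks[[layer]]
    paths <- c(paths,
               w(un$edges, p("union_", layer, "_edges.tsv")),
               w(un$nodes, p("union_", layer, "_nodes.tsv")),
               w(run$differential_connectivity[[layer]],
                 p("diffconn_", layer, ".tsv")))
  }
  paths <- c(paths,
             w(run$targets$targets_a, p("targets_reference.tsv")),
             w(run$targets$targets_b, p("targets_other.tsv")),
             w(run$pcit_pairs, p("gm_pairs_pcit.tsv")),
             w(run$intlim, p("gm_pairs_intlim.tsv")),
             w(run$overlap, p("gm_pairs_overlap.tsv")))
  if (!is.null(run$enrichment$gene))
    paths <- c(paths, w(run$enrichment$gene, p("enrichment_genes.tsv")))
  if (!is.null(run$enrichment$joint))
    paths <- c(paths, w(run$enrichment$joint, p("enrichment_joint.tsv")))
  invisible(paths)
}

#' Score a pipeline run against planted simulation truth
#'
#' @param run a `gm_pipeline` object from [run_pipeline()].
#' @param truth the `truth` element of [simulate_omics()] output.
#' @return list of [score_calls()] results for the differential stage, the
#'   rewired-node stage and the overlap pair stage.
#' @export
score_pipeline <- function(run, truth) {
  dc <- run$differential_connectivity
  dc_called <- unlist(lapply(dc, function(d) d$node_id[d$significant]),
                      use.names = FALSE)
  planted_pairs <- if (is.null(truth$gm_pairs)) character()
                   else pair_keys(truth$gm_pairs)
  list(
    de = score_calls(c(run$de$de_genes, run$de$de_metabolites),
                     c(truth$de_genes, truth$de_metabolites)),
    rewired = score_calls(dc_called, truth$rewired),
    overlap = score_calls(pair_keys(run$overlap), planted_pairs))
}
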