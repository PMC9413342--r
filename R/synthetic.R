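#' Specification of a synthetic paired omics study
#'
#' Describes a two-group study with paired transcriptome (negative-binomial
#' counts) and metabolome (log-normal peak heights), with three kinds of
#' planted structure: latent-factor co-expression modules that may be
#' active in only one group (rewiring), differentially expressed features,
#' and gene-metabolite pairs whose slope differs by phenotype.
#'
#' @param n_genes number of genes (default 300).
#' @param n_metabolites number of metabolites (default 30).
#' @param n_per_group samples per phenotype group (default 6, the scale of
#'   a small paired omics cohort).
#' @param groups two phenotype level names, reference first (default
#'   `c("NP", "AIP")`).
#' @param nb_size negative-binomial size (inverse dispersion) of gene
#'   counts (default 10).
#' @param gene_mean_log_mean,gene_mean_log_sd log-normal distribution of
#'   baseline gene mean counts (defaults log(200) and 1).
#' @param metab_log_mean baseline mean of metabolite log-abundance
#'   (default 10).
#' @param metab_log_sd within-group biological sd of metabolite
#'   log-abundance (default 0.5).
#' @param modules list of module definitions, each a list with `features`
#'   (IDs; genes like `"g0001"`, metabolites like `"m001"`), `loading` in
#'   (0, 1), and `groups` (levels in which the module's shared factor is
#'   active; a module active in one group only creates genuine rewiring).
#' @param de data frame with columns `feature`, `lfc`: planted log2 (genes)
#'   or log2-scale (metabolites) fold changes applied to the non-reference
#'   group.
#' @param gm_pairs data frame with columns `gene`, `metabolite`, `b1`,
#'   `b2`, `b4`, `noise_sd`: metabolite log-abundance generated as
#'   `m = b1 + b2 g + b4 g p + e`, with `g` the gene's log2(CPM + 1) and
#'   `p` the 0/1 phenotype.
#' @param seed RNG seed; every stage draws from its own stream derived from
#'   this seed so the output is bit-reproducible.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 300, n_metabolites = 30,
                            n_per_group = 6, groups = c("NP", "AIP"),
                            nb_size = 10,
                            gene_mean_log_mean = log(200),
                            gene_mean_log_sd = 1,
                            metab_log_mean = 10, metab_log_sd = 0.5,
                            modules = list(), de = NULL, gm_pairs = NULL,
                            seed = 1) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  metab_ids <- sprintf("m%03d", seq_len(n_metabolites))
  all_ids <- c(gene_ids, metab_ids)
  for (mod in modules) {
    bad <- setdiff(mod$features, all_ids)
    if (length(bad)) stop("module references unknown features: ",
                          paste(bad, collapse = ", "))
    if (mod$loading <= 0 || mod$loading >= 1)
      stop("module loading must be in (0, 1)")
    if (!all(mod$groups %in% groups)) stop("unknown module group")
  }
  if (!is.null(de)) {
    bad <- setdiff(de$feature, all_ids)
    if (length(bad)) stop("DE definition references unknown features: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(gm_pairs)) {
    bad <- c(setdiff(gm_pairs$gene, gene_ids),
             setdiff(gm_pairs$metabolite, metab_ids))
    if (length(bad)) stop("gm pair references unknown features: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_genes = n_genes, n_metabolites = n_metabolites,
                 n_per_group = n_per_group, groups = groups,
                 nb_size = nb_size,
                 gene_mean_log_mean = gene_mean_log_mean,
                 gene_mean_log_sd = gene_mean_log_sd,
                 metab_log_mean = metab_log_mean,
                 metab_log_sd = metab_log_sd,
                 modules = modules, de = de, gm_pairs = gm_pairs,
                 gene_ids = gene_ids, metab_ids = metab_ids,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Fixed per-stage seed streams: stage k of global seed s gets its own seed,
# so adding later stages never shifts the draws of earlier ones.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% (2^31 - 1))
}

#' Generate a synthetic paired transcriptome + metabolome dataset
#'
#' Gene counts are negative-binomial with a Gaussian-copula latent layer:
#' each gene's latent value is `lambda * f + sqrt(1 - lambda^2) * e` when
#' it belongs to a module with shared factor `f` (per sample; only in the
#' groups where the module is active) and pure noise otherwise, mapped
#' through the NB quantile function so marginal count distributions are
#' exactly NB. Planted fold changes multiply the NB mean in the
#' non-reference group. Metabolites are log-normal with the same module
#' mechanism on the log scale; planted gene-metabolite pairs overwrite the
#' metabolite with the interaction model `m = b1 + b2 g + b4 g p + e`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genes` (count [omic_matrix]), `metabolites` (peak
#'   height [omic_matrix], i.e. `exp()` of the log-abundances) and `truth`
#'   (list: `de_genes`, `de_metabolites`, `rewired` — members of modules
#'   active in only one group — and `gm_pairs` with the true
#'   coefficients).
#' @export
simulate_omics <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_per_group
  samples <- c(sprintf("%s_%02d", spec$groups[1L], seq_len(n)),
               sprintf("%s_%02d", spec$groups[2L], seq_len(n)))
  ph <- rep(spec$groups, each = n)
  is_other <- ph == spec$groups[2L]
  ns <- 2L * n

  # stage 1: baseline gene means
  set.seed(stream_seed(spec$seed, 1L))
  mu <- exp(stats::rnorm(spec$n_genes, spec$gene_mean_log_mean,
                         spec$gene_mean_log_sd))
  names(mu) <- spec$gene_ids

  # stage 2: module factors (one per module, per sample)
  set.seed(stream_seed(spec$seed, 2L))
  factors <- lapply(spec$modules, function(mod) stats::rnorm(ns))

  # stage 3: latent gene layer
  set.seed(stream_seed(spec$seed, 3L))
  z <- matrix(stats::rnorm(spec$n_genes * ns), spec$n_genes, ns,
              dimnames = list(spec$gene_ids, samples))
  z <- apply_modules(z, spec, factors, ph, spec$gene_ids)

  lfc_gene <- rep(0, spec$n_genes); names(lfc_gene) <- spec$gene_ids
  de_genes <- character(); de_metabs <- character()
  if (!is.null(spec$de)) {
    de_g <- spec$de[spec$de$feature %in% spec$gene_ids, , drop = FALSE]
    lfc_gene[de_g$feature] <- de_g$lfc
    de_genes <- de_g$feature
    de_metabs <- setdiff(spec$de$feature, spec$gene_ids)
  }
  mu_mat <- outer(mu, rep(1, ns))
  mu_mat[, is_other] <- mu_mat[, is_other] * 2^lfc_gene
  counts <- matrix(stats::qnbinom(stats::pnorm(z), size = spec$nb_size,
                                  mu = mu_mat),
                   spec$n_genes, ns, dimnames = list(spec$gene_ids, samples))
  genes <- omic_matrix(counts, "gene", stats::setNames(ph, samples),
                       reference = spec$groups[1L])

  # stage 4: metabolite log-abundances
  set.seed(stream_seed(spec$seed, 4L))
  w <- matrix(stats::rnorm(spec$n_metabolites * ns), spec$n_metabolites, ns,
              dimnames = list(spec$metab_ids, samples))
  w <- apply_modules(w, spec, factors, ph, spec$metab_ids)
  logm <- spec$metab_log_mean + spec$metab_log_sd * w
  if (length(de_metabs)) {
    shift <- spec$de$lfc[match(de_metabs, spec$de$feature)] * log(2)
    logm[de_metabs, is_other] <- logm[de_metabs, is_other] + shift
  }

  # stage 5: planted gene-metabolite interaction pairs
  set.seed(stream_seed(spec$seed, 5L))
  if (!is.null(spec$gm_pairs) && nrow(spec$gm_pairs)) {
    g_norm <- unclass(normalize_counts(genes))
    for (i in seq_len(nrow(spec$gm_pairs))) {
      pr <- spec$gm_pairs[i, ]
      g <- g_norm[pr$gene, ]
      logm[pr$metabolite, ] <- pr$b1 + pr$b2 * g +
        pr$b4 * g * as.numeric(is_other) +
        stats::rnorm(ns, 0, pr$noise_sd)
    }
  }
  metabs <- omic_matrix(exp(logm), "metabolite",
                        stats::setNames(ph, samples),
                        reference = spec$groups[1L])

  rewired <- unique(unlist(lapply(spec$modules, function(mod)
    if (length(mod$groups) < length(spec$groups)) mod$features else NULL)))
  truth <- list(de_genes = de_genes, de_metabolites = de_metabs,
                rewired = if (is.null(rewired)) character() else rewired,
                gm_pairs = spec$gm_pairs)
  list(genes = genes, metabolites = metabs, truth = truth)
}

apply_modules <- function(z, spec, factors, ph, layer_ids) {
  for (j in seq_along(spec$modules)) {
    mod <- spec$modules[[j]]
    members <- intersect(mod$features, layer_ids)
    if (!length(members)) next
    active <- ph %in% mod$groups
    lam <- mod$loading
    f <- factors[[j]]
    z[members, active] <- lam * matrix(f[active], length(members),
                                       sum(active), byrow = TRUE) +
      sqrt(1 - lam^2) * z[members, active]
  }
  z
}

#' Canonical planted benchmark design
#'
#' The standard synthetic study used throughout the package's tests and
#' the reproducibility script: 300 genes and 30 metabolites with the three
#' kinds of planted structure arranged the way a coherent two-group study
#' presents them. Gene module A (15 genes, loading 0.9) is active in both
#' groups; module B (15 genes, loading 0.9) is active only in the
#' reference group and module C (10 genes, loading 0.9) only in the other
#' group — both create genuine rewiring. Differential expression
#' (|log2FC| = 1.5) is planted on ten genes, five of them inside module B
#' so that differential features anchor co-expression edges, plus three
#' differential metabolites (one inside the metabolite module). The three
#' planted gene-metabolite interaction pairs (`b2 = 0.5`, `b4 = 1.5`,
#' noise sd 0.5) use module C genes, so the pair genes also rewire and can
#' become exclusive targets of the non-reference group.
#'
#' @param n_per_group samples per group (default 50, the power scale; use
#'   6 for a cohort-scale smoke test).
#' @param seed RNG seed.
#' @return a [simulation_spec()].
#' @export
planted_study_spec <- function(n_per_group = 50, seed = 1) {
  genes <- sprintf("g%04d", 1:300)
  metabs <- sprintf("m%03d", 1:30)
  simulation_spec(
    n_genes = 300, n_metabolites = 30, n_per_group = n_per_group,
    modules = list(
      list(features = genes[1:15], loading = 0.9, groups = c("NP", "AIP")),
      list(features = genes[16:30], loading = 0.9, groups = "NP"),
      list(features = genes[41:50], loading = 0.9, groups = "AIP"),
      list(features = metabs[10:15], loading = 0.8,
           groups = c("NP", "AIP"))),
    de = data.frame(feature = c(genes[26:40], metabs[c(1, 10, 11)]),
                    lfc = c(rep(1.5, 15), rep(1, 3)),
                    stringsAsFactors = FALSE),
    gm_pairs = data.frame(gene = genes[41:43],
                          metabolite = metabs[4:6],
                          b1 = 10, b2 = 0.5, b4 = 1.5, noise_sd = 0.5,
                          stringsAsFactors = FALSE),
    seed = seed)
}

#' Score a set of calls against planted truth
#'
#' @param called IDs (or pair keys) called by a pipeline stage.
#' @param truth the planted IDs.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall` (`NA`
#'   precision when nothing was called, `NA` recall when nothing was
#'   planted).
#' @export
score_calls <- function(called, truth) {
  called <- unique(called); truth <- unique(truth)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' @rdname score_calls
#' @param df data frame with `gene_id`/`metabolite_id` (or
#'   `gene`/`metabolite`) columns.
#' @return `pair_keys()`: canonical `"gene|metabolite"` keys for scoring
#'   pair lists.
#' @export
pair_keys <- function(df) {
  g <- if ("gene_id" %in% names(df)) df$gene_id else df$gene
  m <- if ("metabolite_id" %in% names(df)) df$metabolite_id else df$metabolite
  paste(g, m, sep = "|")
}
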