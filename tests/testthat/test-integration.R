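test_that("unique targets follow set algebra and the counting identity", {
  res <- unique_targets(hubs_a = c("x", "y"), hubs_b = c("y", "w"),
                        dc_a = "z", dc_b = "z")
  expect_setequal(res$exclusive_a, "x")
  expect_setequal(res$exclusive_b, "w")
  expect_setequal(res$shared, c("y", "z"))
  expect_identical(
    res$targets_a$provenance[res$targets_a$id == "x"], "hub")
  expect_identical(
    res$targets_a$provenance[res$targets_a$id == "z"],
    "differentially_connected")

  same <- unique_targets(c("a", "b"), c("a", "b"), "c", "c")
  expect_length(same$exclusive_a, 0)
  expect_length(same$exclusive_b, 0)

  set.seed(3)
  for (i in 1:10) {
    A <- sample(letters, sample(5:15, 1))
    B <- sample(letters, sample(5:15, 1))
    r <- unique_targets(A, B, character(), character())
    expect_identical(length(A) + length(B),
                     length(r$exclusive_a) + length(r$exclusive_b) +
                       2L * length(r$shared))
  }
})

# Shared scaffolding: a small two-layer dataset with one exact cross-layer
# dependence.
make_two_layer <- function(n_per_group = 10, n_genes = 15, n_metab = 5,
                           seed = 1) {
  set.seed(seed)
  samples <- sprintf("s%03d", 1:(2 * n_per_group))
  ph <- setNames(rep(c("NP", "AIP"), each = n_per_group), samples)
  g <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes), samples))
  m <- matrix(rnorm(n_metab * 2 * n_per_group), n_metab,
              dimnames = list(sprintf("m%02d", 1:n_metab), samples))
  m[1, ] <- 3 * g[1, ] + 1  # metabolite m01 is a linear readout of g01
  list(genes = omic_matrix(g, "gene", ph),
       metabs = omic_matrix(m, "metabolite", ph), ph = ph)
}

test_that("combined PCIT returns cross-layer edges, gene first", {
  d <- make_two_layer()
  cross <- combined_pcit_pairs(d$genes, d$metabs, group = "NP")
  expect_true(all(startsWith(cross$from, "g")))
  expect_true(all(startsWith(cross$to, "m")))
  expect_true(any(cross$from == "g01" & cross$to == "m01" &
                    cross$significant))

  # oracle equivalence on the stacked instance, restricted to cross edges
  vals <- rbind(unclass(d$genes), unclass(d$metabs))
  C <- cor(t(vals[, d$ph == "NP"]))
  oracle <- pcit_oracle_edges(C)
  oracle_cross <- oracle[grepl("^g.* m|^m.* g", oracle)]
  canon <- sort(paste(pmin(cross$from, cross$to),
                      pmax(cross$from, cross$to)))
  expect_identical(canon, sort(oracle_cross))

  # sample mismatch is a hard error
  short <- omic_matrix(unclass(d$metabs)[, 1:19, drop = FALSE],
                       "metabolite", d$ph[1:19])
  expect_error(combined_pcit_pairs(d$genes, short, "NP"), "mismatch")
})

test_that("independent layers yield no strong cross edges at n = 500", {
  set.seed(9)
  n <- 500
  samples <- sprintf("s%03d", 1:n)
  ph <- setNames(rep(c("NP", "AIP"), each = n / 2), samples)
  g <- matrix(rnorm(20 * n), 20,
              dimnames = list(sprintf("g%02d", 1:20), samples))
  m <- matrix(rnorm(5 * n), 5,
              dimnames = list(sprintf("m%02d", 1:5), samples))
  cross <- combined_pcit_pairs(omic_matrix(g, "gene", ph),
                               omic_matrix(m, "metabolite", ph),
                               group = "NP")
  expect_identical(nrow(cross[abs(cross$r) >= 0.75, ]), 0L)
})

# helper: wrap a cross-edge data frame as a combined-layer network
new_cross_net <- function(edges, group) {
  ids <- unique(c(edges$from, edges$to))
  correlation_network(edges,
                      nodes = data.frame(id = ids,
                                         kind = ifelse(startsWith(ids, "g"),
                                                       "gene", "metabolite"),
                                         stringsAsFactors = FALSE),
                      group = group, layer = "combined")
}

test_that("pair selection applies the correlation floor and target anchoring", {
  edges <- data.frame(from = c("g1", "g2", "g3"),
                      to = c("m1", "m2", "m3"),
                      r = c(0.8, 0.74, 0.9),
                      significant = TRUE)
  net <- new_cross_net(edges, group = "AIP")
  sel <- select_gm_pairs(net, targets = c("g1", "m3"))
  expect_setequal(paste(sel$gene_id, sel$metabolite_id), c("g1 m1", "g3 m3"))
  expect_true(all(sel$evidence == "pcit"))
  expect_true(all(sel$group == "AIP"))

  # r = 0.74 is below the floor even when anchored
  sel2 <- select_gm_pairs(net, targets = "g2")
  expect_identical(nrow(sel2), 0L)

  # no anchoring
  sel3 <- select_gm_pairs(net, targets = NULL)
  expect_identical(nrow(sel3), 2L)

  expect_warning(sel4 <- select_gm_pairs(net, targets = character()),
                 "empty target")
  expect_identical(nrow(sel4), 0L)

  # monotone in r_min
  for (r in c(0.5, 0.75, 0.85)) {
    lo <- select_gm_pairs(net, NULL, r_min = r)
    hi <- select_gm_pairs(net, NULL, r_min = r + 0.1)
    expect_true(all(paste(hi$gene_id, hi$metabolite_id) %in%
                      paste(lo$gene_id, lo$metabolite_id)))
  }
})

test_that("variance filtering drops the stated fraction, keeping ties", {
  d <- make_two_layer(n_genes = 100)
  expect_identical(nrow(variance_filter(d$genes, 0)), 100L)
  expect_identical(nrow(variance_filter(d$genes, 0.05)), 95L)

  v <- unclass(d$genes)
  v[1:3, ] <- 7  # constants always land in the dropped set
  x <- omic_matrix(v, "gene", d$ph)
  kept <- rownames(variance_filter(x, 0.05))
  expect_false(any(c("g01", "g02", "g03") %in% kept))
})

test_that("the interaction model recovers planted coefficients", {
  set.seed(12)
  n <- 50
  ph <- two_group_phenotype(n)
  p <- as.numeric(ph) - 1
  b4_hat <- replicate(60, {
    g <- rnorm(2 * n)
    m <- 1 + 0.5 * g + 0 * p + 1.5 * g * p + rnorm(2 * n, 0, 0.5)
    intlim_fit(g, m, ph)$b4
  })
  expect_lt(abs(mean(b4_hat) - 1.5), 0.1)

  g <- rnorm(2 * n)
  m <- 1 + 0.5 * g + 1.5 * g * p + rnorm(2 * n, 0, 0.5)
  fit <- intlim_fit(g, m, ph)
  expect_lt(fit$p_interaction, 0.05)

  # swapping the phenotype coding negates b4 and leaves its p unchanged
  swapped <- intlim_fit(g, m, factor(ph, levels = rev(levels(ph))))
  expect_equal(swapped$b4, -fit$b4, tolerance = 1e-9)
  expect_equal(swapped$p_interaction, fit$p_interaction, tolerance = 1e-9)

  # singular design: gene constant within a level
  g2 <- c(rep(1, n), rnorm(n))
  expect_warning(bad <- intlim_fit(g2 * 0 + rep(c(1, 2), each = n),
                                   m, ph), "singular")
  expect_null(bad)
})

test_that("Spearman group differences behave on canonical cases", {
  ph <- two_group_phenotype(6)
  x <- rep(1:6, 2)
  # same monotone relation in both groups
  same <- spearman_group_difference(x, x^3, ph)
  expect_equal(same$diff, 0)
  # perfectly increasing in the non-reference group, decreasing in reference
  y <- c(6:1, 1:6)
  opp <- spearman_group_difference(x, y, ph)
  expect_equal(opp$r_ref, -1)
  expect_equal(opp$r_other, 1)
  expect_equal(opp$abs_diff, 2)
  # invariance under strictly monotone transforms
  tr <- spearman_group_difference(exp(x), y, ph)
  expect_equal(tr$diff, opp$diff)
  # a level with no ranking is flagged NA
  flat <- spearman_group_difference(c(rep(1, 6), 1:6), y, ph)
  expect_true(is.na(flat$r_ref))
})

test_that("overlap requires membership in both evidence lists", {
  pc <- data.frame(gene_id = c("g1", "g2"), metabolite_id = c("m1", "m2"),
                   r = c(0.8, -0.9), group = "AIP", evidence = "pcit")
  il <- data.frame(gene_id = c("g2", "g3"), metabolite_id = c("m2", "m3"),
                   b4 = c(1.2, 0.4), p_interaction = c(0.001, 0.2),
                   spearman_diff = c(1.1, 0.2),
                   significant = c(TRUE, TRUE))
  ov <- overlap_pairs(pc, il)
  expect_identical(nrow(ov), 1L)
  expect_identical(ov$gene_id, "g2")
  expect_identical(ov$evidence, "both")
  expect_identical(ov$sign_call, "negative")

  expect_identical(nrow(overlap_pairs(pc, il[2, ])), 0L)
  full <- overlap_pairs(pc, data.frame(gene_id = pc$gene_id,
                                       metabolite_id = pc$metabolite_id,
                                       b4 = 1, p_interaction = 0.01,
                                       spearman_diff = 0.5,
                                       significant = TRUE))
  expect_identical(nrow(full), 2L)
  # insignificant model rows never contribute
  none <- overlap_pairs(pc, transform(il, significant = FALSE))
  expect_identical(nrow(none), 0L)
})
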