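# two samples only, to exercise the group-size guard
two_sample_matrix <- function(x) {
  v <- unclass(x)[, 1:2]
  structure(v, kind = attr(x, "kind"),
            phenotype = factor(c("NP", "AIP"), levels = c("NP", "AIP")),
            class = class(x))
}

test_that("correlation_matrix matches the textbook formula", {
  set.seed(5)
  samples <- sprintf("s%d", 1:6)
  ph <- setNames(rep(c("NP", "AIP"), each = 3), samples)
  v <- matrix(rnorm(60), 10, dimnames = list(paste0("f", 1:10), samples))
  x <- omic_matrix(v, "gene", ph)
  C <- correlation_matrix(x)
  # independent computation from the covariance/sd definition
  manual <- outer(1:10, 1:10, Vectorize(function(i, j) {
    a <- v[i, ]; b <- v[j, ]
    mean((a - mean(a)) * (b - mean(b))) /
      sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  }))
  expect_equal(unname(C), manual, tolerance = 1e-12)
  expect_equal(diag(C), setNames(rep(1, 10), rownames(v)))

  # exact linear dependence
  v2 <- rbind(x1 = rnorm(6), stretch = 0, neg = 0)
  v2["stretch", ] <- 2 * v2["x1", ] + 3
  v2["neg", ] <- -v2["x1", ]
  colnames(v2) <- samples
  C2 <- correlation_matrix(omic_matrix(v2, "gene", ph))
  expect_equal(C2["x1", "stretch"], 1)
  expect_equal(C2["x1", "neg"], -1)

  expect_error(correlation_matrix(x, group = "NP"), NA)
  expect_error(correlation_matrix(two_sample_matrix(x)), "3 samples")
})

test_that("partial_correlation follows its closed form", {
  expect_equal(partial_correlation(0.7, 0, 0), 0.7)
  expect_equal(partial_correlation(0.5, 0.5, 0.5), 1 / 3)
  expect_equal(partial_correlation(0.4 * 0.6, 0.4, 0.6), 0)
  expect_true(is.nan(partial_correlation(0.5, 1, 0.5)))
})

test_that("PCIT keeps direct edges and eliminates the explained-away edge", {
  # no associations at all
  C0 <- diag(3)
  dimnames(C0) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_identical(nrow(pcit_significant_edges(C0)), 0L)

  # chain x - y - z at moderate strength: r_xz = r_xy * r_yz is explained
  # through y. By hand: partials are (0.447, 0, 0.447), tolerance
  # eps = mean(0.894, 0, 0.894) = 0.596, and 0.25 < 0.596 * 0.5 eliminates
  # (x, z) while 0.5 > 0.596 * 0.25 retains the direct edges.
  C <- matrix(c(1, 0.5, 0.25,
                0.5, 1, 0.5,
                0.25, 0.5, 1), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  net <- pcit_significant_edges(C)
  kept <- paste(net$from, net$to)
  expect_setequal(kept, c("x y", "y z"))
  expect_identical(sort(kept), pcit_oracle_edges(C))

  # a strong chain (0.9, 0.9, 0.81) leaves the indirect edge above the
  # tolerance-scaled alternatives (0.81 > 0.496 * 0.9), so it survives:
  # the trio test prunes explained edges only when they are weak relative
  # to the tolerance, not merely consistent with a product of paths.
  Cs <- matrix(c(1, 0.9, 0.81,
                 0.9, 1, 0.9,
                 0.81, 0.9, 1), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nets <- pcit_significant_edges(Cs)
  expect_identical(sort(paste(nets$from, nets$to)), pcit_oracle_edges(Cs))
  expect_identical(nrow(nets), 3L)
})

test_that("the edge caller agrees with the naive triple-loop on random instances", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(3:25, 1)
    C <- random_corr(n, m = sample(c(5, 8, 20), 1))
    net <- pcit_significant_edges(C)
    expect_identical(sort(paste(net$from, net$to)), pcit_oracle_edges(C))
  }
})

test_that("the edge set is equivariant under feature permutation", {
  set.seed(44)
  C <- random_corr(12)
  perm <- sample(12)
  Cp <- C[perm, perm]
  e1 <- pcit_significant_edges(C)
  e2 <- pcit_significant_edges(Cp)
  canon <- function(net)
    sort(paste(pmin(net$from, net$to), pmax(net$from, net$to)))
  expect_identical(canon(e1), canon(e2))
})

test_that("degenerate inputs are handled: tiny n and unit correlations", {
  C2 <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(net <- pcit_significant_edges(C2), "fewer than 3")
  expect_identical(nrow(net), 1L)

  # a perfectly correlated pair: its trios are skipped, edges survive
  samples <- sprintf("s%d", 1:6)
  ph <- setNames(rep(c("NP", "AIP"), each = 3), samples)
  v <- matrix(rnorm(4 * 6), 4, dimnames = list(paste0("f", 1:4), samples))
  v[2, ] <- 2 * v[1, ]
  C <- correlation_matrix(omic_matrix(v, "gene", ph))
  expect_silent(net <- pcit_significant_edges(C))
  expect_true("f2" %in% c(net$from, net$to))
})

test_that("network filtering applies significance, correlation and DE anchoring", {
  net <- net_from_edges(from = c("g1", "g2", "g3", "g4"),
                        to   = c("g2", "g3", "g4", "g5"),
                        r    = c(0.995, 0.95, 0.999, 0.97))
  de <- c("g1", "g3", "g4")

  gene_rule <- filter_network(net, de, r_min = 0.99)
  expect_setequal(paste(gene_rule$from, gene_rule$to), c("g1 g2", "g3 g4"))

  metab_rule <- filter_network(net, de, r_min = 0.9)
  expect_setequal(paste(metab_rule$from, metab_rule$to),
                  c("g1 g2", "g2 g3", "g3 g4", "g4 g5"))

  # an edge with no DE endpoint is dropped however strong
  no_anchor <- filter_network(net, "g5", r_min = 0.9)
  expect_identical(paste(no_anchor$from, no_anchor$to), "g4 g5")

  expect_error(filter_network(net, character(), r_min = 0.9), "de_features")
  expect_identical(nrow(filter_network(net, de, r_min = 0.9,
                                       require_de = FALSE)), 4L)

  # monotone in r_min
  for (r in c(0.9, 0.95, 0.99, 0.999)) {
    lo <- filter_network(net, de, r_min = r, require_de = FALSE)
    hi <- filter_network(net, de, r_min = min(r + 0.05, 1),
                         require_de = FALSE)
    expect_true(all(paste(hi$from, hi$to) %in% paste(lo$from, lo$to)))
  }

  # nodes without surviving edges are dropped from the node table
  expect_setequal(network_nodes(gene_rule)$id, c("g1", "g2", "g3", "g4"))
})

test_that("PCIT separates direct from indirect edges in sparse graphical models", {
  # Data simulated from chain-structured Gaussian graphical models: the
  # trio test should retain the direct (conditional-dependence) edges and
  # eliminate most of the two-hop marginal correlations they induce, which
  # plain correlation thresholding cannot distinguish at the same |r|.
  set.seed(77)
  n <- 30; m <- 200; n_rep <- 20
  rates <- matrix(NA_real_, n_rep, 2)
  for (rep in 1:n_rep) {
    A <- matrix(0, n, n)
    direct <- NULL; indirect <- NULL
    for (s in seq(1, n - 2, by = 3)) {
      A[s, s + 1] <- A[s + 1, s] <- -0.45
      A[s + 1, s + 2] <- A[s + 2, s + 1] <- -0.45
      direct <- rbind(direct, c(s, s + 1), c(s + 1, s + 2))
      indirect <- rbind(indirect, c(s, s + 2))
    }
    P <- A + diag(rep(1, n))
    S <- solve(P)
    Dg <- diag(1 / sqrt(diag(S)))
    S <- Dg %*% S %*% Dg
    X <- matrix(rnorm(m * n), m, n) %*% chol(S)
    C <- cor(X)
    dimnames(C) <- list(paste0("f", 1:n), paste0("f", 1:n))
    net <- pcit_significant_edges(C)
    kept <- paste(net$from, net$to)
    rates[rep, ] <- c(
      mean(paste0("f", direct[, 1], " f", direct[, 2]) %in% kept),
      mean(paste0("f", indirect[, 1], " f", indirect[, 2]) %in% kept))
  }
  expect_gte(mean(rates[, 1]), 0.95)  # direct edges survive
  expect_lte(mean(rates[, 2]), 0.5)   # most explained-away edges pruned
  expect_gt(mean(rates[, 1]) - mean(rates[, 2]), 0.3)
})

test_that("edge lists export to SIF and TSV", {
  net <- net_from_edges(c("a", "b"), c("b", "c"), r = c(0.9, -0.8))
  sif <- withr::local_tempfile(fileext = ".sif")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sif(net, sif)
  expect_identical(readLines(sif), c("a\tco\tb", "b\tco\tc"))
  write_edges(net, tsv)
  back <- read.delim(tsv)
  expect_identical(back$source, c("a", "b"))
  expect_equal(back$r, c(0.9, -0.8))
})
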