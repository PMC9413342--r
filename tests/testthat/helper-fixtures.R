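# Small in-code fixtures shared across test files.

# A tiny valid count matrix: 3 features x 4 samples, two per group.
tiny_counts <- function() {
  m <- matrix(c(10, 0, 5,
                20, 1, 4,
                30, 2, 6,
                40, 3, 8), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  omic_matrix(m, "gene", c(s1 = "NP", s2 = "NP", s3 = "AIP", s4 = "AIP"))
}

tiny_phenotype <- function() c(s1 = "NP", s2 = "NP", s3 = "AIP", s4 = "AIP")

# Build a correlation_network directly from an edge list (r defaults 1).
net_from_edges <- function(from, to, r = 1, group = NA_character_,
                           layer = "gene", nodes = NULL) {
  correlation_network(data.frame(from = from, to = to,
                                 r = rep_len(r, length(from)),
                                 stringsAsFactors = FALSE),
                      nodes = nodes, group = group, layer = layer)
}

# Two-group samples helper for model-level tests.
two_group_phenotype <- function(n_per_group) {
  factor(rep(c("NP", "AIP"), each = n_per_group), levels = c("NP", "AIP"))
}
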