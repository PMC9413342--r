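# Independent reference implementations used to cross-check the package.
# Each is written directly from the defining formula or an exhaustive
# enumeration, deliberately sharing no code with the implementation.

# Naive scalar triple-loop PCIT: for every trio, the three first-order
# partial correlations, the mean tolerance over non-degenerate ratios, and
# strict elimination of any edge dominated through the third node.
pcit_oracle_edges <- function(C, guard = 1e-12) {
  n <- nrow(C)
  elim <- matrix(FALSE, n, n)
  pc <- function(rab, rac, rbc)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  if (n >= 3) {
    for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
      rxy <- C[x, y]; rxz <- C[x, z]; ryz <- C[y, z]
      if (abs(rxy) >= 1 || abs(rxz) >= 1 || abs(ryz) >= 1) next
      parts <- c(pc(rxy, rxz, ryz), pc(rxz, rxy, ryz), pc(ryz, rxy, rxz))
      direct <- c(rxy, rxz, ryz)
      ok <- abs(direct) > guard
      if (!any(ok)) next
      eps <- mean(parts[ok] / direct[ok])
      if (abs(rxy) < abs(eps * rxz) && abs(rxy) < abs(eps * ryz))
        elim[x, y] <- TRUE
      if (abs(rxz) < abs(eps * rxy) && abs(rxz) < abs(eps * ryz))
        elim[x, z] <- TRUE
      if (abs(ryz) < abs(eps * rxy) && abs(ryz) < abs(eps * rxz))
        elim[y, z] <- TRUE
    }
  }
  keep <- which(upper.tri(C) & !elim & abs(C) > guard, arr.ind = TRUE)
  ids <- rownames(C)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  sort(paste(ids[keep[, 1L]], ids[keep[, 2L]]))
}

# Correlation matrix from random data; n features over m samples.
random_corr <- function(n, m = 8) {
  X <- matrix(rnorm(n * m), n, m)
  C <- cor(t(X))
  dimnames(C) <- list(paste0("f", 1:n), paste0("f", 1:n))
  C
}

# Betweenness by Floyd-Warshall distances plus shortest-path counting --
# a different algorithm from the Brandes accumulation it checks.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # sigma[s, t]: number of shortest s-t paths, by increasing distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(D[is.finite(D)])
  if (maxd >= 1) for (d in 1:maxd) {
    for (s in 1:n) for (t in 1:n) {
      if (D[s, t] != d) next
      pred <- which(adj[, t] > 0 & D[s, ] == d - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- acc
  }
  btw
}

# Erdos-Renyi edge list over n named nodes (may leave isolated nodes).
random_graph_edges <- function(n, p = 0.3) {
  ids <- paste0("n", seq_len(n))
  pairs <- t(combn(ids, 2))
  sel <- runif(nrow(pairs)) < p
  data.frame(from = pairs[sel, 1L], to = pairs[sel, 2L],
             stringsAsFactors = FALSE)
}

# Upper-tail hypergeometric probability by enumerating every possible draw
# of n items out of a universe of N in which the first K are "annotated".
hyper_tail_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}
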