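# Independent brute-force oracles. These deliberately avoid the package's own
# computational paths: triple loops, exhaustive enumeration, closed forms.

# Topological overlap by naive triple loop over shared neighbours.
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l_ij <- 0
    for (u in seq_len(n)) l_ij <- l_ij + a[i, u] * a[u, j]
    tom[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Betweenness by exhaustive enumeration of all simple paths per pair.
oracle_bc <- function(len, tol = 1e-9) {
  n <- nrow(len)
  bc <- numeric(n)
  paths_between <- function(i, j) {
    out <- list()
    rec <- function(path, d) {
      u <- path[length(path)]
      if (u == j) {
        out[[length(out) + 1L]] <<- list(path = path, d = d)
        return(invisible())
      }
      for (v in seq_len(n)) {
        if (!v %in% path && is.finite(len[u, v])) rec(c(path, v), d + len[u, v])
      }
    }
    rec(i, 0)
    out
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- paths_between(i, j)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dmin <- min(ds)
    sel <- ps[ds <= dmin * (1 + tol)]
    thru <- table(unlist(lapply(sel, function(p) setdiff(p$path, c(i, j)))))
    for (v in names(thru)) {
      bc[as.integer(v)] <- bc[as.integer(v)] + thru[[v]] / length(sel)
    }
  }
  setNames(bc, rownames(len))
}

# Hypergeometric upper tail P(X >= k) by explicit summation of the mass
# function with exact binomial coefficients.
oracle_hyper_upper <- function(k, set_size, universe_size, query_size) {
  ks <- k:min(set_size, query_size)
  if (k <= 0) return(1)
  sum(vapply(ks, function(x) {
    choose(set_size, x) * choose(universe_size - set_size, query_size - x)
  }, numeric(1))) / choose(universe_size, query_size)
}

# Random symmetric TOM-like matrix with some absent edges.
random_tom <- function(n, density = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  np <- n * (n - 1) / 2
  vals <- ifelse(runif(np) < density, runif(np, 0.05, 1), 0)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  dimnames(m) <- rep(list(sprintf("g%02d", seq_len(n))), 2)
  m
}

# Adjusted Rand index between a detected assignment and planted labels,
# excluding genes the detection left unassigned.
ari_vs_truth <- function(assignment, truth) {
  labels <- assignment$labels
  planted <- truth$module[match(names(labels), truth$gene_id)]
  idx <- labels != "unassigned"
  mclust::adjustedRandIndex(labels[idx], planted[idx])
}

# Euclidean edge-length matrix from a TOM matrix (1/TOM convention).
tom_lengths <- function(tom) {
  len <- 1 / tom
  diag(len) <- Inf
  len[tom == 0] <- Inf
  len
}
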