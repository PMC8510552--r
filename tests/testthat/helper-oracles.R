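# Independent oracles and small fixture builders used across the suite.
# All fixtures are built in code; nothing is read from disk.

# Brute-force betaMNTD: explicit loops over taxa pairs, straight from the
# definition; the implementation under test uses vectorized min-matrices.
brute_beta_mntd <- function(m, D) {
  rel <- sweep(m, 1L, rowSums(m), "/")
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) for (l in (k + 1L):n) {
    jk <- which(m[k, ] > 0)
    jl <- which(m[l, ] > 0)
    a <- sum(vapply(jk, function(j) rel[k, j] * min(D[j, jl]), 1.0))
    b <- sum(vapply(jl, function(j) rel[l, j] * min(D[j, jk]), 1.0))
    out[k, l] <- out[l, k] <- 0.5 * (a + b)
  }
  out
}

# Patristic distances by explicit shortest paths over the tree's edges
# (independent of ape::cophenetic).
brute_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2L, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  d <- igraph::distances(g, v = as.character(seq_len(n)),
                         to = as.character(seq_len(n)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Random count table over a tree's tips.
random_table <- function(tree, n_samp, depth = 500, seed = 1) {
  withr_seed <- function(s, f) { set.seed(s); f() }
  withr_seed(seed, function() {
    pool <- rexp(length(tree$tip.label))
    m <- t(stats::rmultinom(n_samp, depth, pool / sum(pool)))
    rownames(m) <- paste0("S", seq_len(n_samp))
    colnames(m) <- tree$tip.label
    m
  })
}

# Communities generated by the Raup-Crick null procedure itself, from a
# reference table's marginals (richness, reads, occurrence, abundance).
generate_rc_null_table <- function(ref, seed) {
  set.seed(seed)
  rich <- rowSums(ref > 0)
  reads <- rowSums(ref)
  occ <- colSums(ref > 0)
  ab <- colSums(ref)
  out <- ref * 0
  for (s in seq_len(nrow(ref))) {
    ch <- sample.int(ncol(ref), rich[s], prob = occ / sum(occ))
    x <- rep(1, rich[s])
    extra <- reads[s] - rich[s]
    if (extra > 0)
      x <- x + stats::rmultinom(1, extra, ab[ch] / sum(ab[ch]))[, 1L]
    out[s, ch] <- x
  }
  out
}

# Graph with a fixed number of nodes and edges (Erdos-Renyi G(n, m)),
# with a 'sign' edge attribute so topology_summary can report PPE/PNE.
random_gnm <- function(n, e, seed = 1, p_positive = 0.8) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, e)
  igraph::V(g)$name <- paste0("OTU", seq_len(n))
  igraph::E(g)$sign <- ifelse(stats::runif(e) < p_positive, 1L, -1L)
  g
}

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# All permutations of 1..n (n! small) for exhaustive Mantel oracles.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

two_triangles <- function() {
  g <- igraph::graph_from_edgelist(cbind(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    c("a2", "a3", "a1", "b2", "b3", "b1")), directed = FALSE)
  g
}
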