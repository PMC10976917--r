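# Fixtures and independent oracles shared across the test files.
# All fixtures are built in code; nothing is read from disk.

# Small two-type graph with enough edge density that every attention
# neighborhood is non-trivial. 8 nodes: v1..v4 type "a", v5..v8 type "b".
tiny_graph <- function(feature_dim = 3, seed = 42) {
  set.seed(seed)
  nodes <- data.frame(node_id = paste0("v", 1:8),
                      node_type = rep(c("a", "b"), each = 4),
                      label = c("c0", "c1", "c0", "c1", "c1", "c0", NA, NA),
                      stringsAsFactors = FALSE)
  s <- c(1, 1, 2, 2, 3, 3, 4, 5, 5, 6, 7, 7, 8, 1, 2, 3, 5, 6, 7)
  d <- c(2, 3, 3, 4, 1, 4, 2, 6, 7, 5, 8, 5, 6, 5, 6, 7, 1, 2, 3)
  edges <- data.frame(src = paste0("v", s), dst = paste0("v", d),
                      src_type = ifelse(s <= 4, "a", "b"),
                      dst_type = ifelse(d <= 4, "a", "b"),
                      relation = "r", stringsAsFactors = FALSE)
  hetero_digraph(nodes, edges, X = matrix(rnorm(8 * feature_dim), 8, feature_dim))
}

tiny_metapaths <- function() {
  list(meta_path("aa", c("a", "a")),
       meta_path("aba", c("a", "b", "a")),
       meta_path("bb", c("b", "b")))
}

# Random strongly connected digraph: Bernoulli(p) off-diagonal edges plus a
# Hamiltonian cycle guaranteeing strong connectivity.
rand_strong_digraph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  A[cbind(1:n, c(2:n, 1))] <- 1
  A
}

rand_symmetric_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A <- ((A + t(A)) > 0) * 1
  diag(A) <- 0
  A
}

# Oracle: dominant left eigenvector of a row-stochastic matrix from a dense
# eigensolver, normalized to sum 1.
dense_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) v <- -v
  v
}

# Oracle: does a type-respecting directed path of the given type sequence
# run from node i to node j? Exhaustive enumeration.
path_exists_oracle <- function(A, node_type, types, i, j) {
  walk <- function(v, hop) {
    if (hop == length(types)) return(v == j)
    nxt <- which(A[v, ] > 0 & node_type == types[hop + 1])
    any(vapply(nxt, walk, logical(1), hop = hop + 1))
  }
  node_type[i] == types[1] && walk(i, 1)
}

# Oracle: k = 2 proximity by direct dense arithmetic on P1 = D̃⁻¹Ã.
proximity2_oracle <- function(A) {
  At <- A + diag(nrow(A))
  P1 <- At / rowSums(At)
  X <- P1 %*% t(P1)
  Y <- t(P1) %*% P1
  out <- matrix(0, nrow(A), ncol(A))
  m <- X > 0 & Y > 0
  out[m] <- (X[m] + Y[m]) / 2
  out
}

# Shared small trained-model fixture pieces
tiny_model <- function(k_max = 2, dropout = 0, heads = 2, hidden_dim = 3,
                       seed = 7) {
  g <- tiny_graph()
  dhgnn(g, tiny_metapaths(),
        config = dhgnn_config(hidden_dim = hidden_dim, heads = heads,
                              semantic_dim = 5, k_max = k_max,
                              dropout = dropout),
        seed = seed)
}
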