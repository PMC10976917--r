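test_that("feature projection is the type-specific linear map", {
  node_type <- c("a", "a", "b")
  # identity projections return the input
  X <- matrix(rnorm(9), 3, 3)
  proj_id <- list(a = diag(3), b = diag(3))
  expect_equal(project_features(X, node_type, proj_id), X)

  # per-type input dims 5 and 9 both project to the common width 4
  Xl <- list(a = matrix(rnorm(10), 2, 5), b = matrix(rnorm(9), 1, 9))
  proj <- list(a = matrix(rnorm(20), 4, 5), b = matrix(rnorm(36), 4, 9))
  H <- project_features(Xl, node_type, proj)
  expect_equal(dim(H), c(3, 4))
  expect_equal(H[3, ], as.vector(proj$b %*% Xl$b[1, ]))

  # linearity: zero features map to zero
  expect_equal(project_features(matrix(0, 3, 3), node_type, proj_id),
               matrix(0, 3, 3))
  expect_error(project_features(X, node_type, proj_id["a"]), "no projection")
})

test_that("node attention weights are masked row-stochastic and asymmetric", {
  set.seed(1)
  H <- matrix(rnorm(12), 4, 3)
  # single neighbor: weight 1
  mask <- diag(4) > 0
  mask[1, 2] <- TRUE
  mask[1, 1] <- FALSE
  al <- node_attention_weights(H, mask, rnorm(6))[[1]]
  expect_equal(al[1, 2], 1)

  # equal scores over 4 neighbors: each 0.25
  Hc <- matrix(1, 4, 3)  # identical features -> identical scores
  full <- matrix(TRUE, 4, 4)
  alc <- node_attention_weights(Hc, full, rnorm(6))[[1]]
  expect_equal(as.vector(alc), rep(0.25, 16))

  # asymmetry on a 2-node example with distinct features
  H2 <- rbind(c(1, 0), c(0, 2))
  a <- c(1, -1, 2, 0.5)
  al2 <- node_attention_weights(H2, matrix(TRUE, 2, 2), a)[[1]]
  expect_false(isTRUE(all.equal(al2[1, 2], al2[2, 1])))

  # rows always sum to 1
  expect_equal(rowSums(al2), c(1, 1))
  # empty neighborhood without self-loop errors
  bad <- mask
  bad[1, ] <- FALSE
  expect_error(node_attention_weights(H, bad, rnorm(6)), "self-loop")
})

test_that("node-level aggregation concatenates heads and respects the residual", {
  H <- matrix(rnorm(12), 4, 3)
  # single neighbor, identity activation, no residual: z_i = h'_j
  al <- matrix(0, 4, 4)
  al[1, 2] <- 1
  al[2, 2] <- al[3, 3] <- al[4, 4] <- 1
  Z <- aggregate_node_level(H, list(al), activation = identity)
  expect_equal(Z[1, ], H[2, ])

  # K = 8 heads of width 16 concatenate to 128 columns
  H16 <- matrix(rnorm(5 * 16), 5, 16)
  alist <- replicate(8, diag(5), simplify = FALSE)
  expect_equal(ncol(aggregate_node_level(H16, alist)), 128)

  # identical neighbor features: any convex weights give the same output
  Hc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  w1 <- matrix(0.25, 4, 4)
  w2 <- diag(4)
  expect_equal(aggregate_node_level(Hc, list(w1)), aggregate_node_level(Hc, list(w2)))
})

test_that("semantic attention weights form a simplex and fuse linearly", {
  set.seed(2)
  Zs <- replicate(3, matrix(rnorm(20), 5, 4), simplify = FALSE)
  q <- rnorm(6)
  W <- matrix(rnorm(24), 6, 4)
  b <- rnorm(6)
  sa <- semantic_attention(Zs, q, W, b)
  expect_true(all(sa$beta >= 0))
  expect_equal(sum(sa$beta), 1)

  one <- semantic_attention(Zs[1], q, W, b)
  expect_equal(one$beta, 1)
  expect_equal(one$Z, Zs[[1]])

  same <- semantic_attention(list(Zs[[1]], Zs[[1]], Zs[[1]], Zs[[1]]), q, W, b)
  expect_equal(same$beta, rep(0.25, 4))
})

test_that("multi-scale propagation and inception fusion follow their contracts", {
  A <- rand_strong_digraph(6, seed = 4)
  st <- normalize_proximity(korder_proximity(A, 2), A)
  X <- matrix(rnorm(6 * 3), 6, 3)

  # k = 0 with identity weights returns X
  Z <- multiscale_propagation(X, st, list(diag(3), diag(3), diag(3)))
  expect_equal(Z[[1]], X)
  # identity input exposes the propagator itself
  Z2 <- multiscale_propagation(diag(6), st, list(diag(6), diag(6), diag(6)))
  expect_equal(Z2[[2]], st$propagators[[2]])
  # shape contract
  th <- replicate(3, matrix(rnorm(12), 3, 4), simplify = FALSE)
  expect_true(all(vapply(multiscale_propagation(X, st, th), function(m)
    all(dim(m) == c(6, 4)), logical(1))))
  expect_error(multiscale_propagation(X, st, th[1:2]), "Theta per scale")

  expect_equal(inception_fusion(list(X), activation = identity), X)
  expect_equal(inception_fusion(list(X, -X), activation = identity),
               matrix(0, 6, 3))
  expect_equal(dim(inception_fusion(list(X, X), fusion = "concat")), c(6, 6))
  expect_error(inception_fusion(list(X, X[, 1:2]), fusion = "sum"), "equal dim")
})

test_that("forward produces row-normalized probabilities and is pure in eval mode", {
  m <- tiny_model()
  fw1 <- dhgnn_forward(m)
  expect_lt(max(abs(rowSums(fw1$probs) - 1)), 1e-8)
  fw2 <- dhgnn_forward(m)
  expect_identical(fw1$probs, fw2$probs)  # bit-identical repeat call
  expect_equal(sum(fw1$beta), 1)

  # two-class softmax head: P(c0) + P(c1) = 1 row-wise (binary reduction)
  expect_equal(unname(fw1$probs[, 1] + fw1$probs[, 2]), rep(1, 8))
})

test_that("analytic gradients match central finite differences", {
  m <- tiny_model(k_max = 2, dropout = 0)
  labels <- m$graph$labels
  mask <- !is.na(labels)
  lossfn <- function(params) {
    semi_supervised_loss(dhgnn_forward(m, params)$probs, labels, mask)
  }
  fw <- dhgnn_forward(m, keep_cache = TRUE)
  gr <- dhgnn_backward(m, m$params, fw$cache,
                       metadhgnn:::loss_grad_logits(fw$probs, labels, mask))
  get_leaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_leaf <- function(p, path, val) {
    if (length(path) == 1) { p[[path[[1]]]] <- val; return(p) }
    p[[path[[1]]]] <- set_leaf(p[[path[[1]]]], path[-1], val)
    p
  }
  eps <- 1e-6
  for (path in list(list("proj", "a"), list("proj", "b"), list("attn", 1L),
                    list("attn", 3L), list("w_res"), list("sem_W"),
                    list("sem_b"), list("sem_q"), list("theta", 1L),
                    list("theta", 3L), list("clf_W"), list("clf_b"))) {
    leaf <- get_leaf(m$params, path)
    gan <- get_leaf(gr, path)
    gnum <- leaf * 0
    for (i in seq_along(leaf)) {
      up <- leaf; up[i] <- leaf[i] + eps
      dn <- leaf; dn[i] <- leaf[i] - eps
      gnum[i] <- (lossfn(set_leaf(m$params, path, up)) -
                    lossfn(set_leaf(m$params, path, dn))) / (2 * eps)
    }
    expect_lt(max(abs(gnum - gan)), 1e-6)
  }
})

test_that("relabeling nodes permutes the output probabilities identically", {
  g <- tiny_graph()
  mps <- tiny_metapaths()
  cfg <- dhgnn_config(hidden_dim = 3, heads = 2, semantic_dim = 5,
                      k_max = 2, dropout = 0)
  m1 <- dhgnn(g, mps, config = cfg, seed = 7)
  p1 <- dhgnn_predict(m1)

  set.seed(11)
  perm <- sample(8)
  nodes2 <- data.frame(node_id = g$node_ids[perm],
                       node_type = unname(g$node_type[perm]),
                       label = ifelse(is.na(g$labels[perm]), NA,
                                      g$label_levels[g$labels[perm] + 1]),
                       stringsAsFactors = FALSE)
  g2 <- hetero_digraph(nodes2, g$edges, X = g$X[perm, ])
  m2 <- dhgnn(g2, mps, config = cfg, seed = 99)
  m2$params <- m1$params  # same parameters, permuted graph
  p2 <- dhgnn_predict(m2)
  expect_equal(p2, p1[perm, ], tolerance = 1e-10)
})

test_that("a single-meta-path single-scale model reduces to a plain attention layer", {
  g <- tiny_graph()
  mp <- list(meta_path("aa", c("a", "a")))
  cfg <- dhgnn_config(hidden_dim = 3, heads = 2, semantic_dim = 5,
                      k_max = 0, dropout = 0)
  m <- dhgnn(g, mp, config = cfg, seed = 3)
  m$params$theta[[1]][] <- 0  # silence the multi-scale branch (elu(0) = 0)
  probs <- dhgnn_predict(m)

  # direct construction from the standalone ops
  Hp <- project_features(g$X, g$node_type, m$params$proj)
  mask <- metapath_masks(g, mp)[[1]]
  alphas <- node_attention_weights(Hp, mask, m$params$attn[[1]])
  Zp <- aggregate_node_level(Hp, alphas, w_res = m$params$w_res)
  logits <- Zp %*% m$params$clf_W + rep(m$params$clf_b, each = 8)
  manual <- exp(logits) / rowSums(exp(logits))
  expect_equal(probs, manual, tolerance = 1e-12)
})

test_that("attention normalizations hold over randomized configurations", {
  for (rep_i in 1:25) {
    set.seed(rep_i)
    n <- sample(4:9, 1)
    d <- sample(2:4, 1)
    K <- sample(1:3, 1)
    H <- matrix(rnorm(n * d), n, d)
    mask <- matrix(runif(n * n) < 0.5, n, n)
    diag(mask) <- TRUE
    als <- node_attention_weights(H, mask, matrix(rnorm(2 * d * K), 2 * d, K))
    for (al in als) expect_lt(max(abs(rowSums(al) - 1)), 1e-8)
    P <- sample(2:4, 1)
    Zs <- replicate(P, matrix(rnorm(n * 3), n, 3), simplify = FALSE)
    sa <- semantic_attention(Zs, rnorm(4), matrix(rnorm(12), 4, 3), rnorm(4))
    expect_lt(abs(sum(sa$beta) - 1), 1e-8)
    expect_true(all(sa$beta >= 0))
  }
})
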