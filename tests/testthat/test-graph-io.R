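test_that("loader builds a validated graph from edge/node tables", {
  g <- generate_toy_cytokine_network(57, 33, 395, seed = 3)
  ed <- withr::local_tempfile(fileext = ".tsv")
  nd <- withr::local_tempfile(fileext = ".tsv")
  write_hetero_graph(g, ed, nd)
  g2 <- load_hetero_graph(ed, nd)
  expect_equal(n_nodes(g2), 90)
  expect_equal(sum(g2$A > 0), 395)
  expect_identical(g2$node_ids, g$node_ids)
  expect_identical(g2$node_type, g$node_type)
  expect_equal(g2$A, g$A)
  expect_identical(g2$labels, g$labels)
})

test_that("edgeless and duplicate edge lists follow the adjacency contract", {
  nodes <- data.frame(node_id = c("a", "b", "c"), node_type = "t")
  g <- hetero_digraph(nodes, NULL)
  expect_equal(g$A, matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))

  edges <- data.frame(src = c("a", "a"), dst = c("b", "b"),
                      src_type = "t", dst_type = "t", relation = "r")
  g2 <- hetero_digraph(nodes, edges)
  expect_equal(g2$A["a", "b"], 1)  # duplicates collapse
  expect_equal(sum(g2$A), 1)
})

test_that("dangling endpoints error when strict and drop with warning otherwise", {
  nd <- withr::local_tempfile(fileext = ".tsv")
  ed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tnode_type\tlabel", "a\tt\tunlabeled", "b\tt\tunlabeled"), nd)
  writeLines(c("src\tdst\tsrc_type\tdst_type\trelation",
               "a\tb\tt\tt\tr", "a\tzzz\tt\tt\tr"), ed)
  expect_error(load_hetero_graph(ed, nd, strict = TRUE), "dangling endpoint")
  expect_warning(g <- load_hetero_graph(ed, nd, strict = FALSE), "dropped")
  expect_equal(sum(g$A), 1)
})

test_that("features load from dense TSV and Matrix Market with node order", {
  nodes <- data.frame(node_id = c("a", "b"), node_type = "t", label = NA)
  edges <- data.frame(src = "a", dst = "b", src_type = "t", dst_type = "t",
                      relation = "r")
  nd <- withr::local_tempfile(fileext = ".tsv")
  ed <- withr::local_tempfile(fileext = ".tsv")
  g0 <- hetero_digraph(nodes, edges)
  write_hetero_graph(g0, ed, nd)

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tf1\tf2", "b\t3\t4", "a\t1\t2"), ft)
  g <- load_hetero_graph(ed, nd, feature_path = ft)
  expect_equal(unname(g$X["a", ]), c(1, 2))  # reordered to node order

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_matrix_market(matrix(c(3, 1, 4, 2), 2, 2), mtx)
  writeLines(c("b", "a"), sub("\\.mtx$", ".nodes", mtx))
  g2 <- load_hetero_graph(ed, nd, feature_path = mtx)
  expect_equal(unname(g2$X["a", ]), c(1, 2))
})

test_that("unlabeled and named labels map to contiguous indices", {
  nodes <- data.frame(node_id = c("a", "b", "c", "d"), node_type = "t",
                      label = c("neg", "pos", "unlabeled", NA))
  g <- hetero_digraph(nodes, NULL)
  expect_identical(unname(g$labels), c(0L, 1L, NA_integer_, NA_integer_))
  expect_identical(g$label_levels, c("neg", "pos"))
})

test_that("meta-path adjacency composes type-restricted blocks", {
  # two cells releasing the same cytokine become two-hop neighbors
  nodes <- data.frame(node_id = c("c1", "c2", "k"),
                      node_type = c("cell", "cell", "cytokine"))
  edges <- data.frame(src = c("c1", "c2", "k"), dst = c("k", "k", "c1"),
                      src_type = c("cell", "cell", "cytokine"),
                      dst_type = c("cytokine", "cytokine", "cell"),
                      relation = c("release", "release", "influence"))
  g <- hetero_digraph(nodes, edges)
  mpa <- derive_metapath_adjacency(g, meta_path("ckc", c("cell", "cytokine", "cell")),
                                   directed = FALSE)
  expect_gt(mpa$M["c1", "c2"], 0)
  expect_gt(mpa$M["c2", "c1"], 0)

  # a length-2 meta-path returns exactly the relation's adjacency block
  g2 <- tiny_graph()
  mpa2 <- derive_metapath_adjacency(g2, meta_path("aa", c("a", "a")))
  blk <- (g2$A[g2$node_type == "a", g2$node_type == "a"] > 0) * 1
  expect_equal(unname(mpa2$M), unname(blk))

  expect_error(derive_metapath_adjacency(g2, meta_path("ab", c("a", "b"))),
               "same type")
  expect_error(derive_metapath_adjacency(g2, meta_path("ax", c("a", "nope", "a"))),
               "unknown node type")
})

test_that("meta-path support equals the brute-force path-enumeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 8
    types <- sample(c("a", "b"), n, replace = TRUE)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    diag(A) <- 0
    nodes <- data.frame(node_id = paste0("v", 1:n), node_type = types)
    idx <- which(A > 0, arr.ind = TRUE)
    edges <- data.frame(src = paste0("v", idx[, 1]), dst = paste0("v", idx[, 2]),
                        src_type = types[idx[, 1]], dst_type = types[idx[, 2]],
                        relation = "r")
    g <- hetero_digraph(nodes, edges)
    for (tseq in list(c("a", "a"), c("a", "b", "a"), c("b", "a", "b"),
                      c("a", "a", "a"))) {
      if (!all(tseq %in% types)) next
      mpa <- derive_metapath_adjacency(g, meta_path("mp", tseq))
      anchor <- which(types == tseq[1])
      for (ii in seq_along(anchor)) for (jj in seq_along(anchor)) {
        expect_equal(mpa$M[ii, jj] > 0,
                     path_exists_oracle(A, types, tseq, anchor[ii], anchor[jj]),
                     info = sprintf("seed %d seq %s i %d j %d", seed,
                                    paste(tseq, collapse = "-"), ii, jj))
      }
    }
  }
})

test_that("prediction tables sort by probability and round-trip", {
  df <- data.frame(node_id = c("x", "y", "z"), type = "cytokine",
                   median_probability = c(0.9, 0.1, 0.5),
                   selected = c(TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(df, path)
  back <- read_predictions(path)
  expect_equal(back$median_probability, c(0.9, 0.5, 0.1))
  expect_equal(back$node_id, c("x", "z", "y"))
  # round-trip preserves values exactly
  expect_identical(back[order(back$node_id), ]$selected, c(TRUE, FALSE, FALSE))

  empty <- df[0, ]
  write_predictions(empty, path)
  expect_equal(length(readLines(path)), 1)  # header only
})

test_that("meta-path configs read from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: aa", "  types: [a, a]",
               "- name: aba", "  types: [a, b, a]"), y)
  mps <- read_metapaths(y)
  expect_length(mps, 2)
  expect_identical(mps[[2]]$types, c("a", "b", "a"))

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"name":"bb","types":["b","b"]}]', j)
  expect_identical(read_metapaths(j)[[1]]$types, c("b", "b"))
})
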