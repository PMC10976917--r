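#' Synthetic directed heterogeneous graphs
#'
#' Seeded generators producing the two test-bed graphs every other module
#' is exercised on: a directed heterogeneous stochastic-block graph with
#' planted classes and Gaussian class-conditional features, and a toy
#' cytokine/cell network with the field's direction semantics (cells
#' release cytokines, cytokines influence cells).
#'
#' @name synthetic_data
NULL

#' Stochastic-block specification
#'
#' The default is the strong-signal two-type, two-class benchmark used as
#' the end-to-end recovery fixture: 200 nodes per type, directed edge
#' probability 0.15 between same-class nodes and 0.01 across classes
#' (regardless of type pair), 8 Gaussian features per type with class mean
#' separation 2.0 and unit noise, and half of the labels observed.
#'
#' @param type_counts named integer vector: nodes per type
#' @param n_classes number of planted classes
#' @param p_within directed edge probability between same-class nodes
#' @param p_between directed edge probability between different-class nodes
#' @param block_prob optional full probability array
#'   `[src_type, dst_type, src_class, dst_class]` overriding the two rates
#' @param feature_dim features per node
#' @param mean_sep Euclidean distance between any two class mean vectors
#' @param noise_sd feature noise standard deviation
#' @param label_fraction fraction of nodes whose labels are observed
#' @param one_hot use one-hot identity features instead of Gaussian ones
#' @param seed RNG seed
#' @export
sbm_spec <- function(type_counts = c(typeA = 200, typeB = 200),
                     n_classes = 2, p_within = 0.15, p_between = 0.01,
                     block_prob = NULL, feature_dim = 8, mean_sep = 2.0,
                     noise_sd = 1.0, label_fraction = 0.5, one_hot = FALSE,
                     seed = 1) {
  type_counts <- unlist(type_counts)  # tolerate YAML-parsed lists
  stopifnot(all(type_counts >= 1), n_classes >= 2,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            noise_sd >= 0, label_fraction >= 0, label_fraction <= 1,
            feature_dim >= n_classes)
  structure(list(type_counts = type_counts, n_classes = n_classes,
                 p_within = p_within, p_between = p_between,
                 block_prob = block_prob, feature_dim = feature_dim,
                 mean_sep = mean_sep, noise_sd = noise_sd,
                 label_fraction = label_fraction, one_hot = one_hot,
                 seed = seed),
            class = "sbm_spec")
}

#' Generate a directed heterogeneous stochastic-block graph
#'
#' Every ordered node pair (i, j), i != j, receives a directed edge
#' independently with its block probability. Features are drawn from the
#' class-conditional Gaussian model (class means are scaled standard basis
#' vectors a `mean_sep` apart); labels are hidden except for the configured
#' fraction, sampled uniformly. The full ground truth is kept in
#' `attr(graph, "true_labels")`. Fully seeded and reproducible.
#'
#' @param spec an [sbm_spec()]
#' @return a [hetero_digraph()] with observed labels, plus attributes
#'   `true_labels` (0-based vector over all nodes) and `spec`
#' @export
generate_sbm <- function(spec = sbm_spec()) {
  stopifnot(inherits(spec, "sbm_spec"))
  if (sum(spec$type_counts) == 0) stop("degenerate spec: zero nodes")
  set.seed(spec$seed)
  types <- rep(names(spec$type_counts), spec$type_counts)
  n <- length(types)
  node_ids <- sprintf("n%04d", seq_len(n))
  # planted classes: balanced within each type, assigned round-robin then
  # shuffled so class and node index are independent
  cls <- unlist(lapply(spec$type_counts, function(ct) {
    sample(rep_len(0:(spec$n_classes - 1), ct))
  }), use.names = FALSE)

  prob_of <- function(i, j) {
    if (!is.null(spec$block_prob)) {
      spec$block_prob[types[i], types[j], cls[i] + 1, cls[j] + 1]
    } else if (cls[i] == cls[j]) spec$p_within else spec$p_between
  }
  Pm <- matrix(spec$p_between, n, n)
  same <- outer(cls, cls, `==`)
  Pm[same] <- spec$p_within
  if (!is.null(spec$block_prob)) {
    for (i in seq_len(n)) for (j in seq_len(n)) Pm[i, j] <- prob_of(i, j)
  }
  diag(Pm) <- 0
  Amask <- matrix(stats::runif(n * n), n, n) < Pm
  ij <- which(Amask, arr.ind = TRUE)
  edges <- data.frame(src = node_ids[ij[, 1]], dst = node_ids[ij[, 2]],
                      src_type = types[ij[, 1]], dst_type = types[ij[, 2]],
                      relation = paste(types[ij[, 1]], types[ij[, 2]], sep = "_"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$src, node_ids), match(edges$dst, node_ids)), ]
  rownames(edges) <- NULL

  if (spec$one_hot) {
    X <- NULL
  } else {
    means <- diag(spec$n_classes) * spec$mean_sep / sqrt(2)
    X <- matrix(stats::rnorm(n * spec$feature_dim, sd = spec$noise_sd),
                n, spec$feature_dim)
    X[, seq_len(spec$n_classes)] <- X[, seq_len(spec$n_classes)] +
      means[cls + 1, , drop = FALSE]
  }

  observed <- sample(n, round(spec$label_fraction * n))
  lab <- rep(NA_character_, n)
  lab[observed] <- paste0("class", cls[observed])
  nodes <- data.frame(node_id = node_ids, node_type = types, label = lab,
                      stringsAsFactors = FALSE)
  g <- hetero_digraph(nodes, edges, X = X,
                      label_levels = paste0("class", 0:(spec$n_classes - 1)))
  attr(g, "true_labels") <- cls
  attr(g, "spec") <- spec
  g
}

#' Default meta-paths for a two-type SBM graph
#'
#' One direct and one two-hop meta-path per type, so every node has
#' neighborhoods in at least one meta-path.
#'
#' @param type_names the two type names
#' @return list of [meta_path()] objects
#' @export
sbm_default_metapaths <- function(type_names = c("typeA", "typeB")) {
  a <- type_names[1]
  b <- type_names[2]
  list(meta_path(paste0(a, "-", a), c(a, a)),
       meta_path(paste0(a, "-", b, "-", a), c(a, b, a)),
       meta_path(paste0(b, "-", b), c(b, b)),
       meta_path(paste0(b, "-", a, "-", b), c(b, a, b)))
}

#' Generate a toy cytokine/cell interaction network
#'
#' Emulates the shape of a curated cytokine-cell topology: `n_cytokines`
#' cytokine nodes, `n_cells` cell nodes, and exactly `n_edges` distinct
#' directed edges sampled uniformly among the four permitted relations —
#' cell -> cytokine (`release`), cytokine -> cell (`influence`),
#' cell -> cell (`cell_cell`) and cytokine -> cytokine
#' (`cytokine_cytokine`). The defaults (57, 33, 395) match the size of the
#' curated core network the method was built for. No labels are attached;
#' the discovery pipeline assigns them from seed lists.
#'
#' @param n_cytokines,n_cells node counts per type
#' @param n_edges exact number of directed edges
#' @param seed RNG seed
#' @return a [hetero_digraph()] (one-hot features)
#' @export
generate_toy_cytokine_network <- function(n_cytokines = 57, n_cells = 33,
                                          n_edges = 395, seed = 1) {
  n <- n_cytokines + n_cells
  max_edges <- n * (n - 1)
  if (n_edges > max_edges) stop("infeasible edge count: ", n_edges, " > ", max_edges)
  set.seed(seed)
  ids <- c(sprintf("CK%02d", seq_len(n_cytokines)),
           sprintf("CELL%02d", seq_len(n_cells)))
  types <- c(rep("cytokine", n_cytokines), rep("cell", n_cells))
  # sample ordered pairs without replacement, excluding self-pairs
  off_diag <- which(row(diag(n)) != col(diag(n)))
  pick <- sample(off_diag, n_edges)
  src <- ((pick - 1) %% n) + 1
  dst <- ((pick - 1) %/% n) + 1
  rel <- ifelse(types[src] == "cell" & types[dst] == "cytokine", "release",
         ifelse(types[src] == "cytokine" & types[dst] == "cell", "influence",
         ifelse(types[src] == "cell", "cell_cell", "cytokine_cytokine")))
  edges <- data.frame(src = ids[src], dst = ids[dst],
                      src_type = types[src], dst_type = types[dst],
                      relation = rel, stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$src, ids), match(edges$dst, ids)), ]
  rownames(edges) <- NULL
  nodes <- data.frame(node_id = ids, node_type = types,
                      label = NA_character_, stringsAsFactors = FALSE)
  hetero_digraph(nodes, edges)
}

#' Default meta-paths for cytokine/cell graphs
#'
#' The direct cytokine-cytokine relation and the cytokine-cell-cytokine
#' composite (two cytokines coupled through a shared cell), plus their cell
#' counterparts so cell nodes also carry attention neighborhoods.
#'
#' @return list of [meta_path()] objects
#' @export
cytokine_default_metapaths <- function() {
  list(meta_path("cytokine-cytokine", c("cytokine", "cytokine")),
       meta_path("cytokine-cell-cytokine", c("cytokine", "cell", "cytokine")),
       meta_path("cell-cell", c("cell", "cell")),
       meta_path("cell-cytokine-cell", c("cell", "cytokine", "cell")))
}
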