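#' Typed directed heterogeneous graphs
#'
#' A `hetero_digraph` is the single container every stage of the package
#' reads: an ordered node set with one type per node, a square non-negative
#' adjacency matrix `A` with `A[i, j] > 0` iff there is a directed edge
#' i -> j, the typed edge list it was built from, an optional node-feature
#' matrix `X` (rows aligned with the node order), and partial class labels.
#'
#' Node order is the stable order of first appearance in the node table;
#' all matrices are indexed accordingly. Labels are stored as 0-based
#' contiguous class indices with `NA` for unlabeled nodes; the original
#' class names are kept in `label_levels`.
#'
#' @param nodes data.frame with columns `node_id`, `node_type` and
#'   (optionally) `label`; `label` may be a class name, `"unlabeled"` or `NA`.
#' @param edges data.frame with columns `src`, `dst`, `src_type`, `dst_type`,
#'   `relation` and optionally `sign`. Duplicate edges collapse to weight 1.
#' @param X optional numeric feature matrix, one row per node in node order.
#'   When `NULL`, one-hot identity features are used.
#' @param label_levels optional character vector naming the classes in index
#'   order; inferred from the label column when missing.
#' @return An object of class `hetero_digraph` with elements `node_ids`,
#'   `node_type`, `A`, `edges`, `X`, `labels`, `label_levels`.
#' @export
hetero_digraph <- function(nodes, edges, X = NULL, label_levels = NULL) {
  stopifnot(is.data.frame(nodes), all(c("node_id", "node_type") %in% names(nodes)))
  node_ids <- as.character(nodes$node_id)
  if (anyDuplicated(node_ids)) {
    stop("duplicate node ids: ", paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  n <- length(node_ids)
  node_type <- stats::setNames(as.character(nodes$node_type), node_ids)

  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(src = character(), dst = character(),
                        src_type = character(), dst_type = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  bad <- !(edges$src %in% node_ids) | !(edges$dst %in% node_ids)
  if (any(bad)) stop("dangling endpoint in edge table")

  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(edges) > 0) {
    A[cbind(match(edges$src, node_ids), match(edges$dst, node_ids))] <- 1
  }

  labels <- rep(NA_integer_, n)
  if ("label" %in% names(nodes)) {
    raw <- as.character(nodes$label)
    raw[is.na(raw) | raw == "unlabeled" | raw == ""] <- NA
    if (is.null(label_levels)) label_levels <- sort(unique(raw[!is.na(raw)]))
    labels <- match(raw, label_levels) - 1L
  }
  names(labels) <- node_ids

  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("feature matrix row count (", nrow(X),
                           ") does not match node count (", n, ")")
    rownames(X) <- node_ids
  } else {
    X <- diag(n)
    dimnames(X) <- list(node_ids, node_ids)
  }

  structure(list(node_ids = node_ids, node_type = node_type, A = A,
                 edges = edges, X = X, labels = labels,
                 label_levels = label_levels %||% character()),
            class = "hetero_digraph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hetero_digraph <- function(x, ...) {
  tt <- table(x$node_type)
  cat("hetero_digraph:", length(x$node_ids), "nodes (",
      paste(names(tt), tt, sep = "=", collapse = ", "), "),",
      sum(x$A > 0), "directed edges,",
      sum(!is.na(x$labels)), "labeled\n")
  invisible(x)
}

#' Number of nodes in a hetero_digraph
#' @param graph a `hetero_digraph`
#' @export
n_nodes <- function(graph) length(graph$node_ids)

#' Load a typed directed graph from edge/node tables
#'
#' Reads the canonical on-disk representation: a tab-separated edge table
#' with header `src dst src_type dst_type relation [sign]` and a node table
#' with header `node_id node_type label` (`label` a class name or
#' `"unlabeled"`). Features are optional: either a dense TSV whose first
#' column is `node_id`, or a Matrix Market file plus a sidecar text file
#' giving the node order (one id per line, same basename with suffix
#' `.nodes`).
#'
#' Edges whose endpoints are missing from the node table raise a "dangling
#' endpoint" error when `strict = TRUE` and are dropped with a warning
#' otherwise. Duplicate edges collapse to weight 1. An edge `sign` column
#' (promote/inhibit) is parsed and retained but not used by the model.
#'
#' @param edge_table_path path to the edge TSV
#' @param node_table_path path to the node TSV
#' @param feature_path optional path to a dense feature TSV or `.mtx` file
#' @param strict error (rather than warn and drop) on dangling endpoints
#' @return a validated [hetero_digraph()]
#' @export
load_hetero_graph <- function(edge_table_path, node_table_path,
                              feature_path = NULL, strict = TRUE) {
  nodes <- utils::read.delim(node_table_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!all(c("node_id", "node_type") %in% names(nodes))) {
    stop("node table must have columns node_id, node_type [, label]")
  }
  edges <- utils::read.delim(edge_table_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (nrow(edges) > 0 && !all(c("src", "dst") %in% names(edges))) {
    stop("edge table must have columns src, dst, src_type, dst_type, relation")
  }
  if (nrow(edges) > 0) {
    bad <- !(edges$src %in% nodes$node_id) | !(edges$dst %in% nodes$node_id)
    if (any(bad)) {
      if (strict) stop("dangling endpoint in edge table: ",
                       paste(utils::head(unique(c(edges$src[bad], edges$dst[bad])), 5),
                             collapse = ", "))
      warning(sum(bad), " edge(s) with dangling endpoints dropped")
      edges <- edges[!bad, , drop = FALSE]
    }
  }

  X <- NULL
  if (!is.null(feature_path)) {
    if (grepl("\\.mtx$", feature_path)) {
      M <- as.matrix(Matrix::readMM(feature_path))
      order_path <- sub("\\.mtx$", ".nodes", feature_path)
      ord <- readLines(order_path)
      rownames(M) <- ord
      X <- M[nodes$node_id, , drop = FALSE]
    } else {
      ft <- utils::read.delim(feature_path, stringsAsFactors = FALSE)
      rn <- as.character(ft[[1]])
      M <- as.matrix(ft[, -1, drop = FALSE])
      rownames(M) <- rn
      X <- M[nodes$node_id, , drop = FALSE]
    }
  }
  hetero_digraph(nodes, edges, X = X)
}

#' Write a hetero_digraph back to edge/node tables
#'
#' Inverse of [load_hetero_graph()]: node set, typed edge set and labels
#' round-trip exactly. Features are not written (pass them separately).
#'
#' @param graph a `hetero_digraph`
#' @param edge_path,node_path output TSV paths
#' @export
write_hetero_graph <- function(graph, edge_path, node_path) {
  lab <- ifelse(is.na(graph$labels), "unlabeled",
                graph$label_levels[graph$labels + 1L])
  nodes <- data.frame(node_id = graph$node_ids,
                      node_type = unname(graph$node_type[graph$node_ids]),
                      label = lab, stringsAsFactors = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Meta-path definition
#'
#' A meta-path is an ordered sequence of node types of length >= 2 defining
#' a composite relation in a heterogeneous graph (e.g. cytokine-cell-cytokine:
#' two cytokines influencing / released by a shared cell). For node
#' classification the first and last types must coincide (the anchor type).
#'
#' @param name short identifier
#' @param types character vector of node-type names, length >= 2
#' @export
meta_path <- function(name, types) {
  stopifnot(is.character(types), length(types) >= 2)
  structure(list(name = name, types = types), class = "meta_path")
}

#' Read meta-path definitions from a YAML or JSON config
#'
#' The file holds a list of `{name, types: [...]}` entries.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`)
#' @return list of [meta_path()] objects
#' @export
read_metapaths <- function(path) {
  spec <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(spec, function(s) meta_path(s$name, unlist(s$types)))
}

#' Meta-path adjacency over the anchor type
#'
#' Composes the per-hop type-restricted adjacency blocks along a meta-path's
#' type sequence: `M = B[t1,t2] %*% B[t2,t3] %*% ...`, where `B[s,t]` is the
#' binarized block of `A` from nodes of type `s` to nodes of type `t`. With
#' `directed = FALSE` each block is taken from the symmetrized support
#' `(A + t(A)) > 0` first. `M[i, j] > 0` iff a type-respecting path of that
#' shape runs from anchor node i to anchor node j; the boolean support of
#' `M` defines the meta-path neighborhoods used by node-level attention.
#'
#' @param graph a `hetero_digraph`
#' @param metapath a [meta_path()]; its first and last types must coincide
#'   when `require_closed = TRUE` (the classification setting)
#' @param directed compose directed blocks (default) or symmetrized ones
#' @param require_closed demand first type == last type
#' @return object of class `metapath_adjacency` with the anchor-type matrix
#'   `M`, `anchor_type`, `anchor_ids` and the meta-path itself
#' @export
derive_metapath_adjacency <- function(graph, metapath, directed = TRUE,
                                      require_closed = TRUE) {
  types <- metapath$types
  known <- unique(graph$node_type)
  if (!all(types %in% known)) {
    stop("meta-path uses unknown node type(s): ",
         paste(setdiff(types, known), collapse = ", "))
  }
  if (require_closed && types[1] != types[length(types)]) {
    stop("meta-path for classification must start and end on the same type")
  }
  base <- (graph$A > 0) * 1
  if (!directed) base <- ((graph$A + t(graph$A)) > 0) * 1
  idx <- lapply(types, function(t) which(graph$node_type == t))
  if (length(idx[[1]]) == 0) stop("anchor type has no nodes")
  M <- NULL
  for (h in seq_len(length(types) - 1)) {
    B <- base[idx[[h]], idx[[h + 1]], drop = FALSE]
    M <- if (is.null(M)) B else M %*% B
  }
  structure(list(metapath = metapath, anchor_type = types[1],
                 anchor_ids = graph$node_ids[idx[[1]]], M = M),
            class = "metapath_adjacency")
}

#' Meta-path neighborhoods
#'
#' @param mpa a `metapath_adjacency`
#' @return named list: for each anchor node, the anchor ids j with M(i,j) > 0
#' @export
metapath_neighborhoods <- function(mpa) {
  stats::setNames(lapply(seq_along(mpa$anchor_ids),
                         function(i) mpa$anchor_ids[mpa$M[i, ] > 0]),
                  mpa$anchor_ids)
}

#' Write a prediction table
#'
#' Serializes the ranked output of the discovery pipeline: a tab-separated
#' file with columns `node_id`, `type`, `median_probability`, `selected`,
#' sorted by median probability descending. Ties keep the input (node id)
#' order so the file is deterministic. Round-trips losslessly through
#' [read_predictions()].
#'
#' @param table a `prediction_table` (see [repeated_prediction()]) or a
#'   data.frame with the four columns above
#' @param path output path
#' @export
write_predictions <- function(table, path) {
  df <- if (inherits(table, "prediction_table")) as.data.frame(table) else table
  need <- c("node_id", "type", "median_probability", "selected")
  if (!all(need %in% names(df))) stop("prediction table missing columns")
  df <- df[, need, drop = FALSE]
  df <- df[order(-df$median_probability, df$node_id), , drop = FALSE]
  df$median_probability <- sprintf("%.17g", df$median_probability)
  df$selected <- ifelse(df$selected, "TRUE", "FALSE")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a prediction table written by [write_predictions()]
#' @param path file path
#' @return data.frame with columns node_id, type, median_probability, selected
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(node_id = "character", type = "character",
                                         median_probability = "numeric",
                                         selected = "logical"))
  df
}

#' @export
as.data.frame.prediction_table <- function(x, ...) {
  data.frame(node_id = x$node_id, type = x$type,
             median_probability = x$median_probability,
             selected = x$selected, stringsAsFactors = FALSE)
}
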