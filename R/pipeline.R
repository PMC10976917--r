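#' Seed-based discovery pipeline
#'
#' The biological-discovery procedure: start from a curated list of
#' positive nodes (e.g. cytokines known to associate with cytokine release
#' syndrome), pick the graph-farthest nodes as negatives, run the full
#' meta-train + train + predict stack many times with different seeds,
#' aggregate per-node positive-class probabilities by their median, and
#' select the far-right mode of the resulting bimodal distribution as the
#' predicted set.
#'
#' @name cytokine_pipeline
NULL

#' Select negative seed nodes by graph distance
#'
#' Distance of a node is the minimum shortest-path length to any positive
#' node on the undirected view of the graph; unreachable nodes count as
#' infinitely far and are selected first. Returns the `n` farthest
#' non-positive nodes, ties broken by lower degree then lexicographic node
#' id — fully deterministic and invariant to the order of the positive
#' list.
#'
#' @param graph a `hetero_digraph`
#' @param positives character vector of positive node ids
#' @param n number of negatives to select
#' @return character vector of `n` node ids
#' @export
select_negative_nodes <- function(graph, positives, n) {
  if (length(positives) == 0) stop("positives must be non-empty")
  missing_ids <- setdiff(positives, graph$node_ids)
  if (length(missing_ids)) stop("unknown positive node(s): ",
                                paste(missing_ids, collapse = ", "))
  candidates <- setdiff(graph$node_ids, positives)
  if (n > length(candidates)) stop("cannot select ", n, " negatives from ",
                                   length(candidates), " non-positive nodes")
  if (n == 0) return(character())
  ig <- igraph::graph_from_adjacency_matrix((graph$A > 0) * 1, mode = "plus",
                                            diag = FALSE)
  D <- igraph::distances(ig, v = match(positives, graph$node_ids))
  dist_min <- apply(D, 2, min)
  names(dist_min) <- graph$node_ids
  deg <- igraph::degree(ig)
  names(deg) <- graph$node_ids
  ord <- candidates[order(-dist_min[candidates], deg[candidates], candidates)]
  ord[seq_len(n)]
}

#' Repeated seeded prediction runs
#'
#' Labels the graph from the seed set (positives = class 1, negatives =
#' class 0, everything else unlabeled) and runs the full stack `n_runs`
#' times with seeds `base_seed .. base_seed + n_runs - 1`: optional
#' meta-pretraining on the training split, base training with early
#' stopping, then eval-mode prediction of the positive-class probability
#' for every node. Per-node medians over the runs are computed exactly;
#' `n_runs` is odd by default so the median is an observed value.
#'
#' @param graph a `hetero_digraph`
#' @param seed_set list with character vectors `positives` and `negatives`
#' @param config a [train_config()]
#' @param meta a [meta_config()] or NULL to skip meta-pretraining
#' @param n_runs number of repeats (>= 1)
#' @param base_seed first run seed
#' @param metapaths meta-paths for the model (default:
#'   [cytokine_default_metapaths()] when the graph has cytokine/cell types,
#'   else one closed meta-path per type pair)
#' @param predict_fn optional override mapping
#'   `(labeled_graph, run_seed)` to a length-n vector of positive-class
#'   probabilities; used to test the aggregation independently of training
#' @return object of class `prediction_table`: `node_id`, `type`, `runs`
#'   (n x n_runs matrix), `median_probability`, `selected` (all FALSE until
#'   [select_far_right()]), `threshold` (NA), `run_seeds`
#' @export
repeated_prediction <- function(graph, seed_set, config = train_config(),
                                meta = NULL, n_runs = 11, base_seed = 0,
                                metapaths = NULL, predict_fn = NULL) {
  stopifnot(n_runs >= 1)
  pos <- seed_set$positives
  neg <- seed_set$negatives
  if (length(intersect(pos, neg))) stop("positive and negative seeds overlap")
  bad <- setdiff(c(pos, neg), graph$node_ids)
  if (length(bad)) stop("unknown seed node(s): ", paste(bad, collapse = ", "))

  lab <- rep(NA_character_, n_nodes(graph))
  lab[match(pos, graph$node_ids)] <- "positive"
  lab[match(neg, graph$node_ids)] <- "negative"
  nodes <- data.frame(node_id = graph$node_ids,
                      node_type = unname(graph$node_type),
                      label = lab, stringsAsFactors = FALSE)
  lg <- hetero_digraph(nodes, graph$edges,
                       X = if (is.null(graph$X)) NULL else graph$X,
                       label_levels = c("negative", "positive"))

  if (is.null(metapaths)) {
    metapaths <- if (all(sort(unique(unname(graph$node_type))) ==
                         c("cell", "cytokine"))) {
      cytokine_default_metapaths()
    } else {
      lapply(unique(unname(graph$node_type)),
             function(t) meta_path(paste0(t, "-", t), c(t, t)))
    }
  }

  run_seeds <- base_seed + seq_len(n_runs) - 1
  runs <- matrix(NA_real_, n_nodes(lg), n_runs)
  for (r in seq_len(n_runs)) {
    p <- tryCatch({
      if (!is.null(predict_fn)) {
        predict_fn(lg, run_seeds[r])
      } else {
        cfg_r <- config
        cfg_r$seed <- run_seeds[r]
        mcfg <- dhgnn_config(hidden_dim = cfg_r$hidden_dim, heads = cfg_r$heads,
                             semantic_dim = cfg_r$semantic_dim,
                             k_max = cfg_r$k_max, alpha = cfg_r$alpha,
                             dropout = cfg_r$dropout)
        model <- dhgnn(lg, metapaths, n_classes = 2, config = mcfg,
                       seed = run_seeds[r])
        splits <- split_labeled_nodes(lg$labels, cfg_r$split, run_seeds[r])
        init <- NULL
        if (!is.null(meta)) {
          meta_r <- meta
          meta_r$seed <- run_seeds[r]
          init <- meta_train(model, meta_r, pool = splits$train)$params
        }
        tr <- train_dhgnn(model, cfg_r, init_params = init, splits = splits)
        dhgnn_predict(tr$model)[, 2]
      }
    }, error = function(e) stop("run ", r, " (seed ", run_seeds[r],
                                ") failed: ", conditionMessage(e)))
    runs[, r] <- p
  }
  structure(list(node_id = lg$node_ids, type = unname(lg$node_type),
                 runs = runs,
                 median_probability = apply(runs, 1, stats::median),
                 selected = rep(FALSE, n_nodes(lg)),
                 threshold = NA_real_, run_seeds = run_seeds),
            class = "prediction_table")
}

#' Select the far-right mode of the median distribution
#'
#' Builds a histogram of the per-node median probabilities (default 50
#' bins). Valley detection locates the two outermost modes (leftmost and
#' rightmost local maxima of the counts) and places the threshold at the
#' left edge of the shallowest bin strictly between them; when several
#' bins tie for shallowest (e.g. an empty gap), the middle one of the tied
#' run is used so the threshold sits centrally in the gap. Nodes with
#' `median >= threshold` are selected (ties at the boundary included).
#' Falls back to the fixed threshold when the distribution has no interior
#' valley, and errors when all medians are identical.
#'
#' @param table a `prediction_table`
#' @param method `"valley"` (default) or `"fixed"`
#' @param bins histogram bin count
#' @param fixed_threshold fallback / fixed threshold
#' @return the table updated with `selected`, `threshold`, `histogram`
#'   (data.frame bin_left, bin_right, count) and `n_selected`
#' @export
select_far_right <- function(table, method = c("valley", "fixed"), bins = 50,
                             fixed_threshold = 0.95) {
  method <- match.arg(method)
  med <- table$median_probability
  if (length(unique(med)) < 2) {
    stop("degenerate median distribution (all values identical); ",
         "use method = \"fixed\" on richer output")
  }
  breaks <- seq(min(med), max(med), length.out = bins + 1)
  h <- graphics::hist(med, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  counts <- h$counts
  threshold <- fixed_threshold
  if (method == "valley") {
    left_pad <- c(-1, counts[-length(counts)])
    right_pad <- c(counts[-1], -1)
    modes <- which(counts > 0 & counts >= left_pad & counts >= right_pad &
                     (counts > left_pad | counts > right_pad))
    if (length(modes) >= 2) {
      i1 <- modes[1]
      i2 <- modes[length(modes)]
      cand <- if (i2 - i1 > 1) (i1 + 1):(i2 - 1) else integer()
      if (length(cand)) {
        mn <- min(counts[cand])
        tied <- cand[counts[cand] == mn]
        pick <- tied[ceiling(length(tied) / 2)]
        threshold <- breaks[pick]
      }
    }
  }
  table$threshold <- threshold
  table$selected <- med >= threshold
  table$histogram <- data.frame(bin_left = utils::head(breaks, -1),
                                bin_right = breaks[-1], count = counts)
  table$n_selected <- sum(table$selected)
  table
}

#' Run the discovery pipeline end to end
#'
#' Orchestrates negative selection, repeated prediction, far-right
#' selection and serialization. Outputs in `out_dir`: `ranked.tsv` (the
#' prediction table), `histogram.csv`, `manifest.json` (all seeds,
#' threshold, configuration and input digests — enough to re-execute the
#' run bit-identically) and `run.log`.
#'
#' @param edge_path,node_path graph TSV paths (see [load_hetero_graph()])
#' @param seeds_path YAML file with `positives: [...]` and optionally
#'   `negatives: [...]` (when absent, `n_negatives` farthest nodes are
#'   chosen) and `n_negatives:`
#' @param config_path optional training-config YAML ([read_train_config()])
#' @param out_dir output directory (created if needed)
#' @param n_runs repeated runs (odd recommended)
#' @param base_seed first run seed
#' @param metapaths optional list of [meta_path()]s
#' @param feature_path optional feature file
#' @return the final `prediction_table`, invisibly
#' @export
run_pipeline <- function(edge_path, node_path, seeds_path, config_path = NULL,
                         out_dir, n_runs = 11, base_seed = 0,
                         metapaths = NULL, feature_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  cat("", file = logf)

  log_line("stage=load graph=", edge_path)
  graph <- load_hetero_graph(edge_path, node_path, feature_path = feature_path)

  seeds <- yaml::read_yaml(seeds_path)
  positives <- as.character(unlist(seeds$positives))
  if (!is.null(seeds$negatives)) {
    negatives <- as.character(unlist(seeds$negatives))
  } else {
    n_neg <- seeds$n_negatives %||% 30
    log_line("stage=select_negatives n=", n_neg)
    negatives <- select_negative_nodes(graph, positives, n_neg)
  }

  if (!is.null(config_path)) {
    cfgs <- read_train_config(config_path)
    config <- cfgs$train
    meta <- cfgs$meta
  } else {
    config <- train_config()
    meta <- meta_config(k_shot = 5)
  }

  log_line("stage=repeated_prediction n_runs=", n_runs, " base_seed=", base_seed)
  table <- repeated_prediction(graph, list(positives = positives,
                                           negatives = negatives),
                               config = config, meta = meta, n_runs = n_runs,
                               base_seed = base_seed, metapaths = metapaths)
  log_line("stage=select_far_right")
  table <- select_far_right(table)
  log_line("stage=write threshold=", format(table$threshold),
           " n_selected=", table$n_selected)

  write_predictions(table, file.path(out_dir, "ranked.tsv"))
  utils::write.csv(table$histogram, file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  manifest <- list(
    command = "pipeline",
    inputs = list(edges = unname(tools::md5sum(edge_path)),
                  nodes = unname(tools::md5sum(node_path)),
                  seeds = unname(tools::md5sum(seeds_path))),
    positives = positives, negatives = negatives,
    n_runs = n_runs, base_seed = base_seed, run_seeds = table$run_seeds,
    threshold = table$threshold, n_selected = table$n_selected,
    config = config, meta = meta,
    package_version = as.character(utils::packageVersion("metadhgnn")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(table)
}
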