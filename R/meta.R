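#' Episodic meta-learning (meta-learner)
#'
#' MAML-style pre-training of the model's initial parameters: each episode
#' samples M support/query tasks from the labeled nodes, adapts a copy of
#' the parameters on each task's support loss (inner loop), accumulates the
#' query-set gradients of the adapted parameters (first-order
#' approximation), and takes one outer Adam step. The parameters with the
#' best mean query loss are returned and used to initialize the base
#' learner.
#'
#' @name meta_learning
NULL

#' Meta-training configuration
#'
#' @param tasks_per_episode number M of tasks sampled per episode (the
#'   source study uses 2)
#' @param k_shot labeled support nodes per class per task
#' @param query_size query nodes per class per task (defaults to `k_shot`)
#' @param inner_lr inner-loop (adaptation) learning rate
#' @param meta_lr outer-loop Adam learning rate
#' @param inner_steps gradient steps per adaptation
#' @param episodes episode cap (the source study caps meta-training at 50)
#' @param patience early-stopping patience on mean query loss (episodes)
#' @param l2_weight L2 weight applied by the outer optimizer
#' @param first_order use the first-order meta-gradient (default)
#' @param seed RNG seed
#' @export
meta_config <- function(tasks_per_episode = 2, k_shot = 30, query_size = NULL,
                        inner_lr = 0.001, meta_lr = 0.001, inner_steps = 1,
                        episodes = 50, patience = 10, l2_weight = 0.001,
                        first_order = TRUE, seed = 1) {
  stopifnot(tasks_per_episode >= 1, inner_lr >= 0, meta_lr > 0, k_shot >= 1,
            episodes >= 1)
  list(tasks_per_episode = tasks_per_episode, k_shot = k_shot,
       query_size = query_size %||% k_shot, inner_lr = inner_lr,
       meta_lr = meta_lr, inner_steps = inner_steps, episodes = episodes,
       patience = patience, l2_weight = l2_weight,
       first_order = first_order, seed = seed)
}

#' Sample one episodic task
#'
#' Draws, per class, `k_shot` support nodes and `query_size` query nodes
#' uniformly without replacement from the labeled pool. Deterministic for a
#' fixed seed; support and query sets are disjoint.
#'
#' @param labels 0-based integer labels with NA for unlabeled nodes
#' @param n_classes number of classes
#' @param k_shot support nodes per class
#' @param query_size query nodes per class
#' @param seed RNG seed
#' @param pool optional integer vector restricting the sampled indices
#' @return object of class `meta_task`: integer vectors `support`, `query`,
#'   plus `n_classes`, `k_shot`
#' @export
sample_meta_task <- function(labels, n_classes, k_shot, query_size = k_shot,
                             seed = 1, pool = NULL) {
  set.seed(seed)
  support <- query <- integer()
  for (cl in 0:(n_classes - 1)) {
    avail <- which(!is.na(labels) & labels == cl)
    if (!is.null(pool)) avail <- intersect(avail, pool)
    if (length(avail) < k_shot + query_size) {
      stop("class ", cl, " has only ", length(avail),
           " labeled nodes; need ", k_shot + query_size)
    }
    pick <- sample(avail, k_shot + query_size)
    support <- c(support, pick[seq_len(k_shot)])
    query <- c(query, pick[k_shot + seq_len(query_size)])
  }
  structure(list(support = sort(support), query = sort(query),
                 n_classes = n_classes, k_shot = k_shot),
            class = "meta_task")
}

#' Inner-loop adaptation
#'
#' Runs `inner_steps` plain gradient steps on the support-set loss starting
#' from `params`, and returns the adapted copy. The caller's `params` are
#' never modified (R's copy-on-write makes this a functional contract).
#' Dropout, when configured, draws from the current seeded RNG stream, so
#' adaptation is deterministic within a seeded run.
#'
#' @param model a [dhgnn()] model
#' @param params starting parameters
#' @param task a [sample_meta_task()] result
#' @param inner_lr inner learning rate (0 returns `params` unchanged)
#' @param inner_steps number of steps (0 returns `params` unchanged)
#' @return adapted parameter list
#' @export
inner_adapt <- function(model, params, task, inner_lr, inner_steps = 1) {
  labels <- model$graph$labels
  n <- n_nodes(model$graph)
  mask <- seq_len(n) %in% task$support
  adapted <- params
  for (s in seq_len(inner_steps)) {
    fw <- dhgnn_forward(model, adapted, training = TRUE)
    loss <- semi_supervised_loss(fw$probs, labels, mask)
    if (!is.finite(loss)) stop("non-finite support loss during adaptation")
    grads <- dhgnn_backward(model, adapted, fw$cache,
                            loss_grad_logits(fw$probs, labels, mask))
    adapted <- sgd_step(adapted, grads, inner_lr)
  }
  adapted
}

#' Meta-train the model
#'
#' Episodic first-order MAML: per episode, sample `tasks_per_episode`
#' tasks, adapt on each support set, evaluate the query loss at the adapted
#' parameters, average the query gradients and take one outer Adam step on
#' the initial parameters. Early stopping tracks the mean query loss; the
#' best parameters are returned. All randomness derives from
#' `config$seed`.
#'
#' @param model a [dhgnn()] model with labeled nodes
#' @param config a [meta_config()]
#' @param pool optional integer vector restricting task sampling (e.g. to
#'   the training split so validation/test nodes stay unseen)
#' @return list with `params` (best initial parameters), `history`
#'   data.frame (episode, mean_query_loss) and `best_episode`
#' @export
meta_train <- function(model, config = meta_config(), pool = NULL) {
  if (!config$first_order) {
    stop("second-order meta-gradients are not implemented; use first_order = TRUE")
  }
  set.seed(config$seed)
  labels <- model$graph$labels
  n <- n_nodes(model$graph)
  C <- model$n_classes
  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, episode = 0L, params = params)
  history <- data.frame(episode = integer(), mean_query_loss = numeric())
  stall <- 0L
  for (ep in seq_len(config$episodes)) {
    task_seeds <- sample.int(.Machine$integer.max, config$tasks_per_episode)
    acc <- NULL
    qloss <- 0
    for (m in seq_len(config$tasks_per_episode)) {
      task <- sample_meta_task(labels, C, config$k_shot, config$query_size,
                               seed = task_seeds[m], pool = pool)
      adapted <- inner_adapt(model, params, task, config$inner_lr,
                             config$inner_steps)
      qmask <- seq_len(n) %in% task$query
      fw <- dhgnn_forward(model, adapted, training = TRUE)
      loss <- semi_supervised_loss(fw$probs, labels, qmask)
      if (!is.finite(loss)) stop("non-finite query loss in episode ", ep)
      qloss <- qloss + loss
      # first-order meta-gradient: query gradient evaluated at the adapted
      # parameters stands in for the gradient w.r.t. the initial ones
      g <- dhgnn_backward(model, adapted, fw$cache,
                          loss_grad_logits(fw$probs, labels, qmask))
      acc <- if (is.null(acc)) g else param_map(`+`, acc, g)
    }
    acc <- param_map(function(x) x / config$tasks_per_episode, acc)
    upd <- adam_step(params, acc, state, lr = config$meta_lr,
                     l2 = config$l2_weight)
    params <- upd$params
    state <- upd$state
    qloss <- qloss / config$tasks_per_episode
    history <- rbind(history, data.frame(episode = ep, mean_query_loss = qloss))
    if (qloss < best$loss) {
      best <- list(loss = qloss, episode = ep, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  list(params = best$params, history = history, best_episode = best$episode)
}
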