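#' Directed-graph spectral machinery
#'
#' Transition matrices, stationary distributions, exact and approximate
#' personalized-PageRank digraph Laplacians, and the k-order proximity
#' stacks that drive multi-scale directed propagation.
#'
#' @name digraph_spectral
NULL

assert_square_nonneg <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be a square matrix")
  if (any(A < 0)) stop("adjacency must be non-negative")
  invisible(A)
}

new_transition_matrix <- function(P, kind, alpha = NA_real_) {
  structure(list(P = P, kind = kind, alpha = alpha), class = "transition_matrix")
}

tm_matrix <- function(P) if (inherits(P, "transition_matrix")) P$P else P

#' Random-walk transition matrix with self-loops
#'
#' Returns the row-stochastic matrix of the lazy-free random walk on the
#' self-loop-augmented graph: `P = D̃⁻¹Ã` with `Ã = A + I`, so every row sum
#' is positive even for sink nodes. Set `self_loops = FALSE` to use `A`
#' directly (all row sums of `A` must then be positive).
#'
#' @param A square non-negative adjacency matrix
#' @param self_loops add the identity before normalizing (default TRUE)
#' @return a `transition_matrix` (kind "rw")
#' @export
random_walk_transition <- function(A, self_loops = TRUE) {
  assert_square_nonneg(A)
  At <- if (self_loops) A + diag(nrow(A)) else A
  rs <- rowSums(At)
  if (any(rs <= 0)) stop("zero out-degree row; enable self_loops")
  new_transition_matrix(At / rs, kind = "rw")
}

#' Personalized-PageRank auxiliary-node transition matrix
#'
#' Builds the (n+1) x (n+1) chain with one auxiliary teleport node: real
#' node rows are `(1 - alpha) * P̃` with probability `alpha` of jumping to
#' the auxiliary node, and the auxiliary node jumps uniformly back to the
#' n real nodes. The chain is irreducible and aperiodic for any A, so its
#' stationary distribution is unique.
#'
#' @param A square non-negative adjacency matrix (n x n)
#' @param alpha teleport probability in (0, 1)
#' @return a `transition_matrix` (kind "ppr_augmented", size (n+1) x (n+1))
#' @export
ppr_augmented_transition <- function(A, alpha = 0.1) {
  assert_square_nonneg(A)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  n <- nrow(A)
  Pt <- tm_matrix(random_walk_transition(A))
  P <- rbind(cbind((1 - alpha) * Pt, rep(alpha, n)),
             c(rep(1 / n, n), 0))
  new_transition_matrix(P, kind = "ppr_augmented", alpha = alpha)
}

#' Stationary distribution by power iteration
#'
#' Iterates `pi <- pi %*% P` from the uniform vector until the max-abs
#' fixed-point residual drops below `tol`. Deterministic; requires an
#' irreducible (and, for convergence, aperiodic) chain, which holds for
#' every `ppr_augmented_transition` and for self-loop random walks on
#' strongly connected graphs.
#'
#' @param P a `transition_matrix` or a plain row-stochastic matrix
#' @param tol fixed-point tolerance (max-abs residual)
#' @param max_iter iteration cap
#' @return object of class `stationary_distribution`: `pi` (vector summing
#'   to 1) and `Pi` (its diagonal matrix)
#' @export
stationary_distribution <- function(P, tol = 1e-10, max_iter = 100000) {
  M <- tm_matrix(P)
  n <- nrow(M)
  pi <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pin <- as.vector(pi %*% M)
    pin <- pin / sum(pin)
    if (max(abs(pin - pi)) < tol) {
      return(structure(list(pi = pin, Pi = diag(pin, n)),
                       class = "stationary_distribution"))
    }
    pi <- pin
  }
  stop("power iteration did not converge within ", max_iter,
       " iterations (residual ", format(max(abs(as.vector(pi %*% M) - pi))), ")")
}

# Chung-style symmetrization: I - (Pi^1/2 P Pi^-1/2 + Pi^-1/2 P' Pi^1/2)/2
symmetrized_laplacian <- function(P, pi) {
  if (any(pi <= 0)) stop("stationary distribution has zero mass on some node")
  s <- sqrt(pi)
  M <- outer(s, 1 / s) * P      # Pi^1/2 P Pi^-1/2
  diag(length(pi)) - 0.5 * (M + t(M))
}

#' Exact personalized-PageRank digraph Laplacian
#'
#' Forms the PageRank chain `P_pr = (1 - alpha) * P̃ + (alpha / n) * 11ᵀ`
#' on the self-loop walk `P̃ = D̃⁻¹Ã`, finds its stationary distribution
#' `pi_pr` by power iteration, and returns the symmetric operator
#' `L = I - (Π^{1/2} P_pr Π^{-1/2} + Π^{-1/2} P_prᵀ Π^{1/2}) / 2` with
#' `Π = Diag(pi_pr)`. L is symmetric positive semidefinite.
#'
#' @param A square non-negative adjacency matrix
#' @param alpha teleport probability in (0, 1); small alpha preserves more
#'   of the directed structure
#' @return object of class `digraph_laplacian` with fields `L`, `variant`
#'   ("exact_pr"), `alpha`, `pi`
#' @export
exact_digraph_laplacian <- function(A, alpha = 0.1) {
  assert_square_nonneg(A)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- nrow(A)
  Pt <- tm_matrix(random_walk_transition(A))
  Ppr <- (1 - alpha) * Pt + alpha / n
  pi <- stationary_distribution(Ppr)$pi
  structure(list(L = symmetrized_laplacian(Ppr, pi), variant = "exact_pr",
                 alpha = alpha, pi = pi),
            class = "digraph_laplacian")
}

#' Approximate digraph Laplacian via the auxiliary PPR chain
#'
#' The approximate operator applies the symmetrization to the self-loop
#' walk `P̃` itself, with a diagonal normalizer `Π̃` taken from a stationary
#' distribution:
#' \itemize{
#'   \item `stationary = "exact"` (default): the stationary distribution of
#'     `P̃` computed directly by power iteration. This is the operator's
#'     defining form: it is positive semidefinite, and for a symmetric A
#'     the stationary vector is proportional to the self-loop degrees, so
#'     it reduces exactly to the undirected normalized Laplacian
#'     `I - D̃^{-1/2} Ã D̃^{-1/2}`. On reducible graphs the direct
#'     stationary vector carries zero mass on transient nodes, so this
#'     mode falls back automatically to `"ppr"` (recorded in the returned
#'     `stationary` field).
#'   \item `stationary = "ppr"`: the stationary distribution of the
#'     auxiliary-node chain [ppr_augmented_transition()], restricted to
#'     the n real nodes and renormalized. This alpha-dependent
#'     approximation converges to the defining form as alpha shrinks; it
#'     guarantees a unique stationary vector even on reducible graphs, at
#'     the price of an O(alpha) perturbation (the operator is then only
#'     approximately positive semidefinite).
#' }
#'
#' @param A square non-negative adjacency matrix
#' @param alpha teleport probability in (0, 1) (used by the "ppr" variant)
#' @param stationary which stationary vector to use, see Details
#' @return object of class `digraph_laplacian` with fields `L`, `variant`
#'   ("approx"), `alpha`, `pi`
#' @export
approx_digraph_laplacian <- function(A, alpha = 0.1,
                                     stationary = c("exact", "ppr")) {
  assert_square_nonneg(A)
  stationary <- match.arg(stationary)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- nrow(A)
  Pt <- tm_matrix(random_walk_transition(A))
  if (stationary == "exact") {
    pi <- stationary_distribution(Pt)$pi
    # a reducible chain leaves zero mass on transient nodes; the auxiliary
    # PPR chain guarantees a strictly positive stationary vector there
    if (min(pi) < 1e-10) stationary <- "ppr"
  }
  if (stationary == "ppr") {
    paug <- stationary_distribution(ppr_augmented_transition(A, alpha))$pi
    pi <- paug[seq_len(n)]
    pi <- pi / sum(pi)
  }
  structure(list(L = symmetrized_laplacian(Pt, pi), variant = "approx",
                 alpha = alpha, pi = pi, stationary = stationary),
            class = "digraph_laplacian")
}

#' k-order proximity stack
#'
#' Builds the proximity matrices used for multi-scale directed propagation:
#' `P^(0) = I`; `P^(1) = D̃⁻¹Ã` (row-stochastic); and for k >= 2, with
#' `X = (P^(1))^{k-1} (P^(1)ᵀ)^{k-1}` (diffusion paths) and
#' `Y = (P^(1)ᵀ)^{k-1} (P^(1))^{k-1}` (meeting paths),
#' `P^(k)(i,j) = (X(i,j) + Y(i,j)) / 2` where both entries are strictly
#' positive and 0 otherwise — the element-wise intersection of meeting and
#' diffusion reachability. `P^(k)` is symmetric for k >= 2.
#'
#' @param A square non-negative adjacency matrix
#' @param k_max largest proximity order, >= 0
#' @return object of class `proximity_stack`: list `P` of matrices for
#'   k = 0..k_max plus `k_max`
#' @export
korder_proximity <- function(A, k_max) {
  assert_square_nonneg(A)
  if (!is.numeric(k_max) || length(k_max) != 1 || k_max < 0) {
    stop("k_max must be a non-negative integer")
  }
  k_max <- as.integer(k_max)
  n <- nrow(A)
  P1 <- tm_matrix(random_walk_transition(A))
  out <- vector("list", k_max + 1)
  out[[1]] <- diag(n)
  if (k_max >= 1) out[[2]] <- P1
  if (k_max >= 2) {
    Fw <- P1
    Bw <- t(P1)
    for (k in 2:k_max) {
      # Fw = P1^{k-1}, Bw = (P1')^{k-1}
      if (k > 2) {
        Fw <- Fw %*% P1
        Bw <- Bw %*% t(P1)
      }
      X <- Fw %*% t(Fw)
      Y <- t(Fw) %*% Fw
      Pk <- matrix(0, n, n)
      mask <- X > 0 & Y > 0
      Pk[mask] <- (X[mask] + Y[mask]) / 2
      out[[k + 1]] <- Pk
    }
  }
  structure(list(P = out, k_max = k_max), class = "proximity_stack")
}

#' Attach normalized propagators to a proximity stack
#'
#' Adds the propagator matrices of the multi-scale layer: for k = 0 the
#' identity; for k = 1 the symmetrized directed propagator
#' `(Π^{1/2} P^(1) Π^{-1/2} + Π^{-1/2} P^(1)ᵀ Π^{1/2}) / 2` with `Π` the
#' diagonal of the approximate-Laplacian stationary vector; for k >= 2 the
#' symmetric normalization `W^{-1/2} P^(k) W^{-1/2}` with
#' `W = Diag(row sums of P^(k))`. Zero rows are guarded: they produce zero
#' rows in the propagator rather than division errors.
#'
#' @param stack a `proximity_stack` from [korder_proximity()]
#' @param A the adjacency matrix the stack was built from
#' @param alpha teleport probability for the k = 1 stationary normalizer
#' @param stationary passed to [approx_digraph_laplacian()]
#' @return the stack with an added `propagators` list
#' @export
normalize_proximity <- function(stack, A, alpha = 0.1,
                                stationary = c("exact", "ppr")) {
  stopifnot(inherits(stack, "proximity_stack"))
  stationary <- match.arg(stationary)
  n <- nrow(stack$P[[1]])
  props <- vector("list", stack$k_max + 1)
  props[[1]] <- diag(n)
  if (stack$k_max >= 1) {
    lap <- approx_digraph_laplacian(A, alpha, stationary = stationary)
    s <- sqrt(lap$pi)
    M <- outer(s, 1 / s) * stack$P[[2]]
    props[[2]] <- 0.5 * (M + t(M))
  }
  if (stack$k_max >= 2) {
    for (k in 2:stack$k_max) {
      Pk <- stack$P[[k + 1]]
      w <- rowSums(Pk)
      winv <- ifelse(w > 0, 1 / sqrt(w), 0)
      props[[k + 1]] <- winv * Pk * rep(winv, each = n)  # diag(winv) Pk diag(winv)
    }
  }
  stack$propagators <- props
  stack$alpha <- alpha
  stack
}

#' Export a matrix as a Matrix Market file
#'
#' Convenience export of Laplacians or proximity matrices for external
#' inspection.
#'
#' @param M a numeric matrix
#' @param path output `.mtx` path
#' @export
write_matrix_market <- function(M, path) {
  Matrix::writeMM(Matrix::Matrix(M, sparse = TRUE), path)
  invisible(NULL)
}
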