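#' RESCAL tensor factorisation of a knowledge graph
#'
#' Factorises the stacked per-relation adjacency tensor `X_k ~ A R_k A'`
#' where `A` (n x r) embeds every entity and each `R_k` (r x r) models the
#' interaction pattern of relation k. Fitting uses alternating least squares
#' with ridge regularisation: given `A`, each `R_k` is the exact ridge
#' solution `vec(R_k) = (G (x) G + lambda I)^-1 vec(A' X_k A)` with
#' `G = A'A`; the `A` update uses the standard RESCAL normal equations and is
#' guarded by backtracking -- a candidate update that would increase the
#' penalised loss is shrunk towards the current factor until the loss
#' decreases, so the recorded loss sequence is monotone non-increasing by
#' construction. Initialisation is seeded uniform(-1, 1), making runs
#' bit-reproducible for a given seed.
#'
#' @param kg a [knowledge_graph()]
#' @param rank embedding dimension r, `1 <= r <=` node count.
#' @param iterations maximum ALS sweeps (default 50).
#' @param regularization ridge penalty lambda >= 0 (default 0.01).
#' @param seed integer seed for the initialisation.
#' @param tol stop early when the relative loss improvement falls below this
#'   (default 1e-10).
#' @return An object of class `rescal_embedding`: list with `ids` (node
#'   order), `A` (n x r embedding matrix), `R` (named list of r x r relation
#'   cores), `loss` (penalised loss after every accepted sweep) and
#'   `iterations` (sweeps performed).
#' @export
rescal_fit <- function(kg, rank = 8L, iterations = 50L, regularization = 0.01,
                       seed = 1L, tol = 1e-10) {
  stopifnot(inherits(kg, "knowledge_graph"))
  ids <- kg$nodes$id
  n <- length(ids)
  rels <- sort(unique(kg$edges$relation))
  X <- lapply(rels, function(rel) {
    e <- kg$edges[kg$edges$relation == rel, ]
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    M[cbind(match(e$source, ids), match(e$target, ids))] <- 1
    M
  })
  names(X) <- rels
  rescal_als(X, rank = rank, iterations = iterations,
             regularization = regularization, seed = seed, tol = tol)
}

#' RESCAL alternating least squares on a list of relation matrices
#'
#' The fitting core behind [rescal_fit()], usable on arbitrary real-valued
#' square frontal slices (all n x n, one per relation), e.g. to validate
#' recovery on tensors generated from known factors.
#'
#' @param X named list of n x n numeric matrices sharing row/column order;
#'   dimnames of the first matrix, when present, become the node ids.
#' @inheritParams rescal_fit
#' @return A `rescal_embedding`, see [rescal_fit()].
#' @export
rescal_als <- function(X, rank, iterations = 50L, regularization = 0.01,
                       seed = 1L, tol = 1e-10) {
  stopifnot(is.list(X), length(X) >= 1L)
  n <- nrow(X[[1L]])
  for (M in X) stopifnot(is.matrix(M), nrow(M) == n, ncol(M) == n)
  ids <- rownames(X[[1L]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(names(X))) names(X) <- paste0("relation_", seq_along(X))
  if (rank < 1L) stop("rank must be >= 1")
  if (rank > n) stop(sprintf("rank (%d) exceeds node count (%d)", rank, n))
  lam <- regularization

  loss_fn <- function(A, R) {
    fit <- sum(vapply(seq_along(X), function(k) {
      sum((X[[k]] - A %*% R[[k]] %*% t(A))^2)
    }, numeric(1)))
    fit + lam * (sum(A^2) + sum(vapply(R, function(r) sum(r^2), numeric(1))))
  }

  update_R <- function(A) {
    G <- crossprod(A)
    H <- kronecker(G, G) + diag(lam, rank * rank)
    lapply(X, function(Xk) {
      rhs <- as.vector(t(A) %*% Xk %*% A)
      matrix(solve(H, rhs), rank, rank)
    })
  }

  update_A <- function(A, R) {
    G <- crossprod(A)
    num <- matrix(0, n, rank)
    den <- diag(lam, rank)
    for (k in seq_along(X)) {
      Rk <- R[[k]]
      num <- num + X[[k]] %*% A %*% t(Rk) + t(X[[k]]) %*% A %*% Rk
      den <- den + Rk %*% G %*% t(Rk) + t(Rk) %*% G %*% Rk
    }
    t(solve(t(den), t(num)))
  }

  set.seed(seed)
  A <- matrix(runif(n * rank, -1, 1), n, rank)
  R <- update_R(A)
  loss <- loss_fn(A, R)
  trace <- numeric(0)
  iters_done <- 0L
  for (it in seq_len(iterations)) {
    A_cand <- update_A(A, R)
    R_cand <- update_R(A_cand)
    l_cand <- loss_fn(A_cand, R_cand)
    if (!is.finite(l_cand) || l_cand > loss) {
      # damped step: the R update is exact so any accepted A keeps loss down
      step <- 0.5
      accepted <- FALSE
      while (step > 1e-8) {
        A_try <- A + step * (A_cand - A)
        R_try <- update_R(A_try)
        l_try <- loss_fn(A_try, R_try)
        if (is.finite(l_try) && l_try <= loss) {
          A_cand <- A_try; R_cand <- R_try; l_cand <- l_try
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) {         # no descent direction left: converged
        trace <- c(trace, loss)
        iters_done <- it
        break
      }
    }
    improvement <- (loss - l_cand) / max(loss, .Machine$double.eps)
    A <- A_cand; R <- R_cand; loss <- l_cand
    trace <- c(trace, loss)
    iters_done <- it
    if (improvement < tol) break
  }
  rownames(A) <- ids
  structure(list(ids = ids, A = A, R = R, loss = trace,
                 iterations = iters_done,
                 rank = rank, regularization = lam, seed = seed),
            class = "rescal_embedding")
}

#' @export
print.rescal_embedding <- function(x, ...) {
  cat(sprintf("<rescal_embedding> %d nodes, rank %d, %d relation(s), final loss %.4g\n",
              length(x$ids), x$rank, length(x$R),
              if (length(x$loss)) x$loss[length(x$loss)] else NA_real_))
  invisible(x)
}

#' Relative reconstruction error of a RESCAL fit
#'
#' Frobenius norm of the residual over the Frobenius norm of the stacked
#' relation tensor, computed against a [knowledge_graph()] (or any list of
#' adjacency matrices in the embedding's node order).
#'
#' @param emb a [rescal_embedding()]
#' @param kg the graph the embedding was fitted to.
#' @return scalar relative error.
#' @export
rescal_reconstruction_error <- function(emb, kg) {
  stopifnot(inherits(emb, "rescal_embedding"), inherits(kg, "knowledge_graph"))
  ids <- emb$ids
  n <- length(ids)
  num <- 0; den <- 0
  for (rel in names(emb$R)) {
    e <- kg$edges[kg$edges$relation == rel, ]
    M <- matrix(0, n, n)
    M[cbind(match(e$source, ids), match(e$target, ids))] <- 1
    Rhat <- emb$A %*% emb$R[[rel]] %*% t(emb$A)
    num <- num + sum((M - Rhat)^2)
    den <- den + sum(M^2)
  }
  sqrt(num / den)
}

#' Embedding-space distances from genes to anchor entities
#'
#' Exact L2 (Euclidean) distance between embedding vectors, e.g. from every
#' gene to the `EGFR` and `NSCLC` nodes; proximity in embedding space proxies
#' relevance to the anchored disease context. By default vectors are
#' L2-normalised first: raw RESCAL vector norms scale with node degree, so
#' distances on the unit sphere compare connectivity *patterns* rather than
#' connectivity volume. Set `normalize = FALSE` for raw Euclidean distances.
#'
#' @param emb a [rescal_embedding()]
#' @param genes node ids whose distances are wanted.
#' @param anchors node ids of the anchor entities (default
#'   `c("EGFR", "NSCLC")`).
#' @param normalize L2-normalise embedding vectors before measuring
#'   (default TRUE).
#' @return numeric matrix, `length(genes)` x `length(anchors)`, with
#'   dimnames.
#' @export
anchor_distances <- function(emb, genes, anchors = c("EGFR", "NSCLC"),
                             normalize = TRUE) {
  stopifnot(inherits(emb, "rescal_embedding"))
  missing <- setdiff(c(genes, anchors), emb$ids)
  if (length(missing)) {
    stop(sprintf("node(s) absent from the embedding: %s",
                 paste(missing, collapse = ", ")))
  }
  A <- emb$A
  if (normalize) A <- A / pmax(sqrt(rowSums(A^2)), .Machine$double.eps)
  G <- A[genes, , drop = FALSE]
  D <- vapply(anchors, function(a) {
    av <- A[a, ]
    sqrt(rowSums(sweep(G, 2L, av)^2))
  }, numeric(length(genes)))
  matrix(D, nrow = length(genes), dimnames = list(genes, anchors))
}
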