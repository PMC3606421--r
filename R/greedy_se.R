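# Space-efficient greedy selection.
#
# Instead of holding the m x n cache matrix C = G X^T, this variant keeps the
# economy-size SVD X_S = U Sigma V^T of the selected submatrix, from which
# G = V Omega V^T + lambda^{-1} I with Omega = (Sigma^T Sigma + lambda I)^{-1}
# - lambda^{-1} I diagonal. Any column of C is then reconstructible in O(mr)
# time, so only O(m r) floats are stored; candidates are processed in
# constant-width column blocks to keep auxiliary storage at O(m (r + const)).

# test hook: records the widest auxiliary float block allocated during a run
.se_alloc <- new.env(parent = emptyenv())
.se_alloc$enabled <- FALSE
.se_alloc$max_block_cols <- 0L

se_track_block <- function(ncols) {
  if (.se_alloc$enabled)
    .se_alloc$max_block_cols <- max(.se_alloc$max_block_cols, as.integer(ncols))
  invisible(NULL)
}

#' Enable/inspect the space-efficient allocation tracker
#'
#' Test hook recording the widest auxiliary column block (in columns of an
#' m-row double matrix) allocated by
#' \code{\link{greedy_rls_space_efficient}}, so the memory contract — no
#' \eqn{m \times n} double matrix is ever materialized — can be asserted.
#'
#' @param enabled logical; turn tracking on or off (resets the counter).
#' @return The current maximum block width, invisibly when setting.
#' @export
se_allocation_tracker <- function(enabled = NULL) {
  if (is.null(enabled)) return(.se_alloc$max_block_cols)
  .se_alloc$enabled <- isTRUE(enabled)
  .se_alloc$max_block_cols <- 0L
  invisible(.se_alloc$max_block_cols)
}

# economy-size SVD state of X_S; singular values below tol * max are dropped
se_state <- function(X, y, lambda) {
  list(S = integer(0), V = matrix(0, ncol(X), 0), sigma = numeric(0),
       omega = numeric(0), a = y / lambda, d = rep(1 / lambda, ncol(X)),
       lambda = lambda)
}

se_refresh_svd <- function(st, X) {
  Xs <- X[st$S, , drop = FALSE]
  storage.mode(Xs) <- "double"
  sv <- svd(Xs, nu = 0)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  st$sigma <- sv$d[keep]
  st$V <- sv$v[, keep, drop = FALSE]
  st$omega <- 1 / (st$sigma^2 + st$lambda) - 1 / st$lambda
  st
}

#' Reconstruct one cache column from the SVD state
#'
#' Computes column \code{i} of \eqn{C = G X^T} without \eqn{C} being stored:
#' \eqn{c = V (\Omega (V^T X_i^T)) + \lambda^{-1} X_i^T}, costing
#' \eqn{O(mr)}.
#'
#' @param state an SVD selection state (internal to
#'   \code{\link{greedy_rls_space_efficient}}; exposed for testing).
#' @param X the full genotype matrix.
#' @param i feature index.
#' @return The m-vector cache column.
#' @export
se_cache_column <- function(state, X, i) {
  if (i < 1L || i > nrow(X)) stop("feature index out of range: ", i)
  xi <- as.numeric(X[i, ])
  if (length(state$sigma) == 0L) return(xi / state$lambda)
  drop(state$V %*% (state$omega * crossprod(state$V, xi))) + xi / state$lambda
}

# candidate LOO-MSEs over a block of features, reconstructing their cache
# columns from the SVD; returns the block's mse vector
se_block_mses <- function(st, X, block) {
  m <- length(st$a)
  Xb <- t(X[block, , drop = FALSE])            # m x |block|
  storage.mode(Xb) <- "double"
  se_track_block(ncol(Xb))
  if (length(st$sigma) > 0L) {
    Cb <- st$V %*% (st$omega * crossprod(st$V, Xb)) + Xb / st$lambda
  } else {
    Cb <- Xb / st$lambda
  }
  xc <- colSums(Cb * Xb)
  xa <- as.numeric(crossprod(Xb, st$a))
  A <- st$a - Cb * rep(xa / (1 + xc), each = m)
  D <- st$d - Cb * Cb * rep(1 / (1 + xc), each = m)
  if (any(D <= .d_floor_factor / st$lambda))
    stop("numerical breakdown: a candidate update lost diagonal positivity")
  colMeans((A / D)^2)
}

#' Space-efficient greedy forward selection
#'
#' Selection-equivalent to \code{\link{greedy_rls}} but trades running time
#' for memory: the \eqn{m \times n} cache matrix is never stored. After each
#' committed feature the economy-size SVD of the selected submatrix is
#' recomputed (\code{k} SVDs in total), and candidate cache columns are
#' reconstructed on the fly in constant-width blocks, bounding auxiliary
#' floating-point storage by \eqn{O(m (r + \mathrm{block}))} with
#' \eqn{r \le \min(m, |S|)}.
#'
#' @inheritParams greedy_rls
#' @param block_size number of candidate columns reconstructed at a time
#'   (the constant in the memory bound; default 128).
#' @return As \code{\link{greedy_rls}}; selected indices and per-step
#'   LOO-MSEs match the cached algorithm to floating-point tolerance.
#' @export
greedy_rls_space_efficient <- function(X, y, lambda = 1, k, snp_ids = NULL,
                                       block_size = 128L, bias = FALSE) {
  if (k < 0 || k > nrow(X)) stop("k must be between 0 and nrow(X)")
  if (anyNA(X)) stop("X contains missing genotypes; impute first")
  if (length(y) != ncol(X)) stop("length(y) must equal ncol(X)")
  n <- nrow(X)
  if (bias) X <- rbind(X, rep(1L, ncol(X)))
  st <- se_state(X, y, lambda)
  mses <- numeric(0)
  if (bias) {
    ci <- se_cache_column(st, X, n + 1L)
    xi <- rep(1, ncol(X))
    u <- ci / (1 + sum(xi * ci))
    st$a <- st$a - u * sum(xi * st$a)
    st$d <- st$d - u * ci
    st$S <- c(st$S, n + 1L)
    st <- se_refresh_svd(st, X)
  }
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(n), st$S)
    best_mse <- Inf
    best_i <- NA_integer_
    for (start in seq(1L, length(cand), by = block_size)) {
      block <- cand[start:min(start + block_size - 1L, length(cand))]
      bm <- se_block_mses(st, X, block)
      j <- which.min(bm)
      if (bm[j] < best_mse) {  # strict: earlier blocks hold smaller indices
        best_mse <- bm[j]
        best_i <- block[j]
      }
    }
    # commit: rank-one update of a and d using the reconstructed column
    ci <- se_cache_column(st, X, best_i)
    xi <- as.numeric(X[best_i, ])
    u <- ci / (1 + sum(xi * ci))
    st$a <- st$a - u * sum(xi * st$a)
    st$d <- st$d - u * ci
    if (any(st$d <= .d_floor_factor / st$lambda))
      stop("numerical breakdown committing feature ", best_i)
    st$S <- c(st$S, best_i)
    st <- se_refresh_svd(st, X)
    mses <- c(mses, best_mse)
  }
  finish_selection(setdiff(st$S, n + 1L), mses, st$a, X, lambda,
                   "space_efficient", snp_ids, bias = bias)
}
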