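#' Initialize a greedy selection state
#'
#' Sets up the working quantities of the cached greedy algorithm: with no
#' features selected, \eqn{G = \lambda^{-1} I} implicitly, so \eqn{a =
#' \lambda^{-1} y}, \eqn{d = \lambda^{-1} 1} and the cache matrix \eqn{C =
#' G X^T = \lambda^{-1} X^T}.
#'
#' @param X full genotype matrix, SNPs (rows) by samples (columns), dense —
#'   impute missing genotypes first (\code{\link{impute_missing}}).
#' @param y labels in \{-1, +1\}.
#' @param lambda ridge penalty > 0.
#' @return A \code{selection_state}: list with \code{S} (selected indices, in
#'   selection order), \code{a}, \code{d}, \code{C} (\eqn{m \times n} cache),
#'   \code{lambda}, \code{X}, \code{y}.
#' @export
init_selection <- function(X, y, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single value > 0")
  if (anyNA(X))
    stop("X contains missing genotypes; run impute_missing() before selection")
  if (length(y) != ncol(X)) stop("length(y) must equal ncol(X)")
  m <- ncol(X)
  structure(list(S = integer(0),
                 a = y / lambda,
                 d = rep(1 / lambda, m),
                 C = t(X) / lambda,
                 lambda = lambda, X = X, y = as.numeric(y)),
            class = "selection_state")
}

#' Score one candidate feature by its LOO-MSE after addition
#'
#' Evaluates what the leave-one-out mean squared error would be if feature
#' \code{i} were added to the current set, via the rank-one update: with
#' \eqn{u = C_{:,i} (1 + X_i C_{:,i})^{-1}}, the updated dual variables are
#' \eqn{\tilde a = a - u (X_i a)} and \eqn{\tilde d_j = d_j - u_j C_{j,i}},
#' and the criterion is \eqn{\mathrm{mean}_j (\tilde a_j / \tilde d_j)^2}.
#' The state is not modified.
#'
#' @param state a \code{selection_state}.
#' @param i candidate feature index, not already selected.
#' @return The candidate's LOO-MSE (scalar).
#' @export
evaluate_candidate <- function(state, i) {
  stopifnot(inherits(state, "selection_state"))
  if (i < 1L || i > nrow(state$X)) stop("feature index out of range: ", i)
  if (i %in% state$S) stop("feature ", i, " is already selected")
  ci <- state$C[, i]
  xi <- as.numeric(state$X[i, ])
  u <- ci / (1 + sum(xi * ci))
  a_new <- state$a - u * sum(xi * state$a)
  d_new <- state$d - u * ci
  if (any(d_new <= .d_floor_factor / state$lambda))
    stop("numerical breakdown evaluating candidate ", i,
         ": updated diagonal lost positivity")
  mean((a_new / d_new)^2)
}

# vectorized candidate LOO-MSE over all features; Inf at already-selected
candidate_mses <- function(state) {
  X <- state$X
  C <- state$C
  m <- nrow(C)
  xc <- colSums(C * t(X))                 # X_i C_{:,i} for every i
  xa <- as.numeric(X %*% state$a)         # X_i a
  scale <- xa / (1 + xc)                  # per-candidate multiplier of u
  A <- state$a - C * rep(scale, each = m)           # columns = a~ per candidate
  D <- state$d - C * C * rep(1 / (1 + xc), each = m) # columns = d~ per candidate
  if (any(D <= .d_floor_factor / state$lambda))
    stop("numerical breakdown: a candidate update lost diagonal positivity")
  mse <- colMeans((A / D)^2)
  mse[state$S] <- Inf
  mse
}

#' Pick the best next feature
#'
#' Scans every not-yet-selected feature and returns the one whose addition
#' minimizes the LOO-MSE; ties are broken toward the smallest feature index.
#'
#' @param state a \code{selection_state}.
#' @return List with \code{feature} (index) and \code{loo_mse}.
#' @export
select_next <- function(state) {
  stopifnot(inherits(state, "selection_state"))
  if (length(state$S) >= nrow(state$X)) stop("no candidate features remain")
  mse <- candidate_mses(state)
  best <- which.min(mse)  # first minimum = smallest index on ties
  list(feature = as.integer(best), loo_mse = mse[best])
}

#' Permanently add a feature to the selection
#'
#' Applies the rank-one updates to \code{a}, \code{d} and the full cache
#' matrix \eqn{C \leftarrow C - u (X_i C)}, restoring the invariants
#' \eqn{a = Gy}, \eqn{d = diag(G)}, \eqn{C = G X^T} for the enlarged set.
#'
#' @param state a \code{selection_state}.
#' @param i feature index to add, not already selected.
#' @return The updated \code{selection_state}.
#' @export
commit_feature <- function(state, i) {
  stopifnot(inherits(state, "selection_state"))
  if (i %in% state$S) stop("feature ", i, " is already selected")
  if (i < 1L || i > nrow(state$X)) stop("feature index out of range: ", i)
  ci <- state$C[, i]
  xi <- as.numeric(state$X[i, ])
  u <- ci / (1 + sum(xi * ci))
  state$a <- state$a - u * sum(xi * state$a)
  state$d <- state$d - u * ci
  if (any(state$d <= .d_floor_factor / state$lambda))
    stop("numerical breakdown committing feature ", i)
  xiC <- as.numeric(crossprod(state$C, xi))  # X_i C, length n
  state$C <- state$C - tcrossprod(u, xiC)
  state$S <- c(state$S, as.integer(i))
  state
}

selection_trace <- function(features, mses, method, lambda, snp_ids = NULL) {
  k <- length(features)
  data.frame(step = seq_len(k),
             feature = as.integer(features),
             snp_id = if (is.null(snp_ids)) as.character(features)
                      else snp_ids[features],
             loo_mse = as.numeric(mses),
             method = rep(method, k),
             lambda = rep(lambda, k),
             stringsAsFactors = FALSE)
}

finish_selection <- function(S, mses, a, X, lambda, method, snp_ids,
                             bias = FALSE) {
  # w = X_S a over the final dual vector; with a bias the constant row
  # contributes sum(a) as the intercept weight
  w <- if (length(S)) as.numeric(X[S, , drop = FALSE] %*% a) else numeric(0)
  predictor <- structure(list(features = as.integer(S), w = w,
                              lambda = lambda, bias = bias),
                         class = "rls_predictor")
  if (bias) predictor$bias_weight <- sum(a)
  list(trace = selection_trace(S, mses, method, lambda, snp_ids),
       predictor = predictor)
}

#' Greedy forward selection with cached rank-one updates
#'
#' Runs \code{k} rounds of greedy forward selection for a ridge classifier
#' with the leave-one-out mean squared error as the criterion. Each round
#' scores every remaining feature through the constant-time LOO shortcut on
#' rank-one-updated dual variables, so the whole selection costs
#' \eqn{O(kmn)} — linear in examples, features and selected features.
#'
#' @inheritParams init_selection
#' @param k number of features to select, \code{0 <= k <= nrow(X)}.
#' @param snp_ids optional feature identifiers for the trace.
#' @param bias when \code{TRUE}, a constant all-ones feature is appended and
#'   committed before selection starts, giving the model an intercept; the
#'   \code{k} reported picks are genuine features. Off by default so the
#'   selection follows the bias-free closed form exactly.
#' @return List with \code{trace} (data frame: step, feature, snp_id,
#'   loo_mse) and \code{predictor} (an \code{rls_predictor} with
#'   \eqn{w = X_S a}).
#' @export
greedy_rls <- function(X, y, lambda = 1, k, snp_ids = NULL, bias = FALSE) {
  if (k < 0 || k > nrow(X)) stop("k must be between 0 and nrow(X)")
  n <- nrow(X)
  Xw <- if (bias) rbind(X, rep(1L, ncol(X))) else X
  state <- init_selection(Xw, y, lambda)
  if (bias) state <- commit_feature(state, n + 1L)
  mses <- numeric(0)
  for (step in seq_len(k)) {
    pick <- select_next(state)
    state <- commit_feature(state, pick$feature)
    mses <- c(mses, pick$loo_mse)
  }
  S <- setdiff(state$S, n + 1L)
  finish_selection(S, mses, state$a, X, lambda, "greedy", snp_ids,
                   bias = bias)
}

#' Naive wrapper selection (black-box oracle)
#'
#' Reference implementation of greedy forward wrapper selection where every
#' candidate set is evaluated by retraining the ridge model from scratch.
#' The LOO criterion is computed either from a freshly formed dual state
#' (\code{loo = "shortcut"}) or by \eqn{m} explicit per-example retrainings
#' (\code{loo = "explicit"}), which separates the two shortcut layers when
#' testing. Intended for small instances only.
#'
#' @inheritParams greedy_rls
#' @param loo inner LOO computation, \code{"shortcut"} or \code{"explicit"}.
#' @param cost_cap guard: error out when \code{nrow(X) * ncol(X) * k}
#'   exceeds this (default \code{2e7}).
#' @return As \code{\link{greedy_rls}}.
#' @export
naive_wrapper <- function(X, y, lambda = 1, k, snp_ids = NULL,
                          loo = c("shortcut", "explicit"), cost_cap = 2e7,
                          bias = FALSE) {
  loo <- match.arg(loo)
  n <- nrow(X)
  m <- ncol(X)
  if (k < 0 || k > n) stop("k must be between 0 and nrow(X)")
  if (as.numeric(n) * m * max(k, 1) > cost_cap)
    stop("instance too large for the naive oracle (n*m*k > cost_cap)")
  if (anyNA(X)) stop("X contains missing genotypes; impute first")
  candidate_matrix <- function(S) {
    Xs <- X[S, , drop = FALSE]
    if (bias) Xs <- rbind(Xs, rep(1, m))
    storage.mode(Xs) <- "double"
    Xs
  }
  S <- integer(0)
  mses <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(n), S)
    cand_mse <- vapply(cand, function(i) {
      Xs <- candidate_matrix(c(S, i))
      if (loo == "shortcut") {
        loo_mse(rls_dual_state(Xs, y, lambda), y)
      } else {
        mean((y - explicit_loo(Xs, y, lambda))^2)
      }
    }, numeric(1))
    best <- which.min(cand_mse)
    S <- c(S, cand[best])
    mses <- c(mses, cand_mse[best])
  }
  a <- if (length(S) || bias) rls_dual_state(candidate_matrix(S), y, lambda)$a
       else y / lambda
  finish_selection(S, mses, a, X, lambda, "naive", snp_ids, bias = bias)
}

#' Write a selection trace as TSV
#'
#' Columns: step, snp_id, chrom, pos, loo_mse. Chromosome and position are
#' taken from \code{snp_meta} when supplied.
#'
#' @param trace a trace data frame from a selection run.
#' @param path output file.
#' @param snp_meta optional per-SNP data frame with \code{chrom}, \code{pos}
#'   (rows aligned with the full feature indexing).
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, path, snp_meta = NULL) {
  out <- data.frame(step = trace$step, snp_id = trace$snp_id,
                    chrom = if (is.null(snp_meta)) NA
                            else snp_meta$chrom[trace$feature],
                    pos = if (is.null(snp_meta)) NA
                          else snp_meta$pos[trace$feature],
                    loo_mse = trace$loo_mse)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
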