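#' Train a regularized least-squares (ridge) classifier
#'
#' Solves \eqn{\min_w \|X_S^T w - y\|^2 + \lambda w^T w} in closed form for a
#' fixed feature set. The primal form inverts an \eqn{|S| \times |S|} matrix,
#' \eqn{w = (X_S X_S^T + \lambda I)^{-1} X_S y}; the equivalent dual form
#' inverts an \eqn{m \times m} matrix, \eqn{w = X_S (X_S^T X_S + \lambda
#' I)^{-1} y}. By default the cheaper of the two is used.
#'
#' @param X_S numeric matrix, selected features (rows) by examples (columns).
#' @param y numeric label vector of length \code{ncol(X_S)}.
#' @param lambda ridge penalty, must be > 0.
#' @param features optional identifiers (indices or ids) naming the rows of
#'   \code{X_S} in the full dataset; stored on the predictor.
#' @param form \code{"auto"} (primal when \eqn{|S| \le m}), \code{"primal"} or
#'   \code{"dual"}; the two forms agree to numerical tolerance.
#' @return An \code{rls_predictor}: list with \code{features}, weight vector
#'   \code{w}, \code{lambda} and \code{bias} flag.
#' @export
train_rls <- function(X_S, y, lambda = 1, features = NULL,
                      form = c("auto", "primal", "dual")) {
  form <- match.arg(form)
  check_rls_inputs(X_S, y, lambda)
  p <- nrow(X_S)
  m <- ncol(X_S)
  if (is.null(features)) features <- seq_len(p)
  if (p == 0L) {
    w <- numeric(0)
  } else if (form == "primal" || (form == "auto" && p <= m)) {
    w <- drop(solve(tcrossprod(X_S) + lambda * diag(p), X_S %*% y))
  } else {
    w <- drop(X_S %*% solve(crossprod(X_S) + lambda * diag(m), y))
  }
  structure(list(features = features, w = as.numeric(w), lambda = lambda,
                 bias = FALSE),
            class = "rls_predictor")
}

check_rls_inputs <- function(X_S, y, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single value > 0")
  if (!is.matrix(X_S)) stop("X_S must be a matrix")
  if (anyNA(X_S) || any(!is.finite(X_S)))
    stop("X_S contains missing or non-finite entries")
  if (length(y) != ncol(X_S))
    stop("length(y) must equal the number of examples (columns of X_S)")
  invisible(TRUE)
}

#' Predict scores from an RLS predictor
#'
#' Evaluates \eqn{f(x) = w^T x_S}: only the selected feature rows of the test
#' matrix are read, so cost is proportional to \eqn{|S|} per example.
#'
#' @param object an \code{rls_predictor}.
#' @param X test matrix, full feature rows by examples; must contain every
#'   selected feature row.
#' @param ... unused.
#' @return Numeric vector of real-valued scores, one per column of \code{X}.
#' @export
predict.rls_predictor <- function(object, X, ...) {
  S <- object$features
  b <- if (isTRUE(object$bias)) object$bias_weight else 0
  if (length(S) == 0L) return(rep(b, ncol(X)))
  if (is.numeric(S) && max(S) > nrow(X))
    stop("feature index ", max(S), " out of range for a matrix with ",
         nrow(X), " rows")
  drop(crossprod(X[S, , drop = FALSE], object$w)) + b
}

#' Dual-variable state of an RLS model
#'
#' Forms \eqn{G = (X_S^T X_S + \lambda I)^{-1}} explicitly and returns the
#' dual vector \eqn{a = G y} and the diagonal \eqn{d = diag(G)} from which
#' leave-one-out predictions are available in constant time per example. The
#' explicit \eqn{m \times m} inverse limits this to test/validation scale;
#' the greedy selection maintains the same quantities incrementally.
#'
#' @inheritParams train_rls
#' @return An \code{rls_dual_state}: list with \code{a}, \code{d},
#'   \code{lambda} and \code{n_features}. With no features, \eqn{a =
#'   \lambda^{-1} y} and \eqn{d = \lambda^{-1} 1}.
#' @export
rls_dual_state <- function(X_S, y, lambda = 1) {
  check_rls_inputs(X_S, y, lambda)
  m <- ncol(X_S)
  if (nrow(X_S) == 0L) {
    a <- y / lambda
    d <- rep(1 / lambda, m)
  } else {
    G <- solve(crossprod(X_S) + lambda * diag(m))
    a <- drop(G %*% y)
    d <- diag(G)
  }
  structure(list(a = a, d = d, lambda = lambda, n_features = nrow(X_S)),
            class = "rls_dual_state")
}

# relative floor under which a diagonal entry of G signals numerical breakdown
.d_floor_factor <- 1e-12

#' Leave-one-out predictions via the dual shortcut
#'
#' The LOO prediction for example \eqn{j} of a ridge model is
#' \eqn{y_j - a_j / d_j}, a constant number of floating point operations per
#' example once the dual variables are available — no retraining.
#'
#' @param state an \code{rls_dual_state}.
#' @param y the label vector the state was built from.
#' @return Numeric vector of LOO predictions, one per example.
#' @export
loo_predictions <- function(state, y) {
  stopifnot(inherits(state, "rls_dual_state"))
  if (any(state$d <= .d_floor_factor / state$lambda))
    stop("numerical breakdown: diagonal of G has lost positive definiteness")
  y - state$a / state$d
}

#' Leave-one-out predictions by explicit retraining
#'
#' Brute-force reference: for every example, trains a ridge model from
#' scratch on the other \eqn{m - 1} examples and predicts the held-out one.
#' Intended as an independent oracle for tests; cost is \eqn{m} full trains.
#'
#' @inheritParams train_rls
#' @return Numeric vector of LOO predictions, one per example.
#' @export
explicit_loo <- function(X_S, y, lambda = 1) {
  check_rls_inputs(X_S, y, lambda)
  m <- ncol(X_S)
  if (m < 2L) stop("explicit LOO needs at least 2 examples")
  vapply(seq_len(m), function(j) {
    fit <- train_rls(X_S[, -j, drop = FALSE], y[-j], lambda)
    if (length(fit$w) == 0L) 0 else sum(fit$w * X_S[, j])
  }, numeric(1))
}

#' Leave-one-out mean squared error
#'
#' The selection criterion: \eqn{\mathrm{mean}_j (a_j / d_j)^2}, which equals
#' the mean squared difference between the labels and the LOO predictions.
#' With no features selected and labels in \{-1, +1\} this is exactly 1.
#'
#' @inheritParams loo_predictions
#' @return The LOO-MSE (scalar).
#' @export
loo_mse <- function(state, y) {
  stopifnot(inherits(state, "rls_dual_state"))
  if (any(state$d <= .d_floor_factor / state$lambda))
    stop("numerical breakdown: diagonal of G has lost positive definiteness")
  mean((state$a / state$d)^2)
}

#' @rdname loo_mse
#' @export
loo_rmse <- function(state, y) sqrt(loo_mse(state, y))

#' Serialize / restore an RLS predictor
#'
#' The predictor is written as a small JSON document: lambda, the ordered
#' selected SNP ids (or indices), weights, bias flag and free-form provenance
#' (selection method, seed).
#'
#' @param p an \code{rls_predictor}.
#' @param path output file.
#' @param provenance optional named list recorded verbatim.
#' @return \code{write_predictor}: invisibly, the path;
#'   \code{read_predictor}: the restored \code{rls_predictor}.
#' @export
write_predictor <- function(p, path, provenance = NULL) {
  stopifnot(inherits(p, "rls_predictor"))
  doc <- list(lambda = p$lambda, features = p$features, weights = p$w,
              bias = p$bias)
  if (isTRUE(p$bias)) doc$bias_weight <- p$bias_weight
  if (!is.null(provenance)) doc$provenance <- provenance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- doc$features
  if (is.list(feats)) feats <- unlist(feats)
  p <- structure(list(features = feats, w = as.numeric(doc$weights),
                      lambda = doc$lambda, bias = isTRUE(doc$bias)),
                 class = "rls_predictor")
  if (p$bias) p$bias_weight <- doc$bias_weight
  p
}

#' Append a constant bias feature
#'
#' A bias term, when wanted, is realized as an extra all-ones feature row so
#' the unbiased equations apply unchanged.
#'
#' @param X feature-by-example matrix.
#' @return \code{X} with an all-ones row appended.
#' @export
add_bias_feature <- function(X) rbind(X, bias = rep(1, ncol(X)))
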