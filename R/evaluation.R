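#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks: the probability that a randomly
#' chosen case outranks a randomly chosen control, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels labels in \{-1, +1\}; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  neg <- labels == -1
  n_pos <- sum(pos)
  n_neg <- sum(neg)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' Partitions samples into \code{n_folds} disjoint folds of near-equal size
#' with per-fold class proportions within one sample of the global
#' proportions. Deterministic given the seed.
#'
#' @param labels labels in \{-1, +1\}.
#' @param n_folds number of folds (default 3).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..n_folds), one per sample.
#' @export
stratified_folds <- function(labels, n_folds = 3, seed = 1) {
  for (cls in c(-1, 1))
    if (sum(labels == cls) < n_folds)
      stop("class ", cls, " has fewer members than folds")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  fold
}

run_selection_method <- function(X, y, method, lambda, k, prefilter,
                                 bias = FALSE) {
  switch(method,
    greedy = greedy_rls(X, y, lambda, k, bias = bias),
    space_efficient = greedy_rls_space_efficient(X, y, lambda, k,
                                                 bias = bias),
    hybrid = hybrid_select(X, y, lambda, k, prefilter = prefilter,
                           bias = bias),
    filter = {
      flt <- filter_select(X, y, k)
      list(trace = data.frame(step = seq_len(k), feature = flt$feature,
                              snp_id = flt$snp_id, loo_mse = NA_real_,
                              method = "filter", lambda = lambda,
                              stringsAsFactors = FALSE))
    },
    stop("unknown method: ", method))
}

#' Nested cross-validation of a feature-selection method
#'
#' External stratified folds estimate generalization; the internal LOO
#' criterion drives selection inside each training fold only. For each
#' external fold, selection runs on the training two-thirds; for every
#' \code{k} up to \code{k_max} a ridge model on the first \code{k} selected
#' features (trained on the training fold) is scored on the held-out fold by
#' AUC. Test-fold samples never influence selection.
#'
#' @param ds a fully imputed \code{\link{genotype_dataset}}.
#' @param method \code{"greedy"}, \code{"space_efficient"}, \code{"filter"}
#'   or \code{"hybrid"}.
#' @param lambda ridge penalty.
#' @param k_max maximum number of selected features (default 50).
#' @param n_folds external folds (default 3).
#' @param seed seed for the fold split.
#' @param prefilter hybrid prefilter size (default 50).
#' @param folds optional explicit fold assignment (overrides
#'   \code{stratified_folds}); used by the permutation control to keep
#'   splits identical.
#' @param bias give selection and the per-k models a constant intercept
#'   feature (see \code{\link{greedy_rls}}); default off.
#' @return A \code{nested_cv_result}: list with \code{folds}, per-fold
#'   \code{selection} (feature index vectors in selection order), \code{auc}
#'   (folds x k matrix), \code{loo_mse} (folds x k matrix of internal
#'   criteria; NA for the filter), \code{mean_auc} (fold-averaged curve),
#'   \code{peak_k}, \code{peak_auc}, \code{method}, \code{seed}.
#' @export
nested_cv <- function(ds, method = c("greedy", "space_efficient", "filter",
                                     "hybrid"),
                      lambda = 1, k_max = 50, n_folds = 3, seed = 1,
                      prefilter = 50, folds = NULL, bias = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "genotype_dataset"))
  if (anyNA(ds$X)) stop("dataset has missing genotypes; impute before CV")
  if (k_max > nrow(ds$X)) stop("k_max exceeds the number of SNPs")
  if (is.null(folds)) folds <- stratified_folds(ds$y, n_folds, seed)
  n_folds <- max(folds)

  auc_mat <- matrix(NA_real_, n_folds, k_max)
  mse_mat <- matrix(NA_real_, n_folds, k_max)
  selections <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    test <- which(folds == f)
    X_tr <- ds$X[, train, drop = FALSE]
    y_tr <- ds$y[train]
    sel <- run_selection_method(X_tr, y_tr, method, lambda, k_max, prefilter,
                                bias = bias)
    feats <- sel$trace$feature
    selections[[f]] <- feats
    mse_mat[f, ] <- sel$trace$loo_mse
    for (k in seq_len(k_max)) {
      Sk <- feats[seq_len(k)]
      Xk <- X_tr[Sk, , drop = FALSE]
      if (bias) Xk <- rbind(Xk, rep(1L, ncol(Xk)))
      storage.mode(Xk) <- "double"
      fit <- train_rls(Xk, y_tr, lambda)
      Xte <- ds$X[Sk, test, drop = FALSE]
      if (bias) Xte <- rbind(Xte, rep(1L, ncol(Xte)))
      storage.mode(Xte) <- "double"
      scores <- drop(crossprod(Xte, fit$w))
      auc_mat[f, k] <- roc_auc(scores, ds$y[test])
    }
  }
  mean_auc <- colMeans(auc_mat)
  structure(list(folds = folds, selection = selections, auc = auc_mat,
                 loo_mse = mse_mat, mean_auc = mean_auc,
                 peak_k = which.max(mean_auc),
                 peak_auc = max(mean_auc),
                 method = method, lambda = lambda, seed = seed),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested CV (%s, lambda=%g): %d folds, k up to %d\n",
              x$method, x$lambda, nrow(x$auc), ncol(x$auc)))
  cat(sprintf("  peak fold-averaged test AUC %.3f at k = %d\n",
              x$peak_auc, x$peak_k))
  invisible(x)
}

#' Single-SNP discriminative power
#'
#' AUC of the raw minor-allele count used directly as a score, per feature.
#' Because the minor allele can be protective, the reported value is
#' \code{max(AUC, 1 - AUC)} together with the direction (+1 when the minor
#' allele scores toward cases, -1 otherwise).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param features feature indices to score (default all).
#' @return Data frame with \code{feature}, \code{snp_id}, \code{auc}
#'   (oriented), \code{direction}.
#' @export
per_feature_auc <- function(ds, features = seq_len(nrow(ds$X))) {
  stopifnot(inherits(ds, "genotype_dataset"))
  raw <- vapply(features, function(i) {
    x <- ds$X[i, ]
    keep <- !is.na(x)
    roc_auc(as.numeric(x[keep]), ds$y[keep])
  }, numeric(1))
  data.frame(feature = features, snp_id = ds$snp_ids[features],
             auc = pmax(raw, 1 - raw),
             direction = ifelse(raw >= 0.5, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Permutation control for the nested-CV experiment
#'
#' Randomly permutes the class labels once, then reruns the identical
#' nested-CV experiment — the fold splits are computed from the original
#' labels so the data and splits match the unpermuted run exactly. With the
#' label-genotype link broken, the fold-averaged test AUC is expected to sit
#' at the random level for every k.
#'
#' @inheritParams nested_cv
#' @param perm_seed seed for the label permutation (defaults to
#'   \code{seed}).
#' @return A \code{nested_cv_result} (on the permuted labels), with
#'   attribute \code{"permutation"} holding the permutation used.
#' @export
permutation_control <- function(ds, method = "greedy", lambda = 1,
                                k_max = 50, n_folds = 3, seed = 1,
                                prefilter = 50, perm_seed = seed,
                                bias = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  folds <- stratified_folds(ds$y, n_folds, seed)
  perm <- with_seed(perm_seed, sample(length(ds$y)))
  ds_perm <- genotype_dataset(ds$X, ds$y[perm], ds$snp_ids, ds$sample_ids,
                              ds$snp_meta)
  res <- nested_cv(ds_perm, method, lambda, k_max, n_folds, seed,
                   prefilter, folds = folds, bias = bias)
  attr(res, "permutation") <- perm
  res
}

#' Write a nested-CV result as TSV + JSON summary
#'
#' The TSV holds one row per (fold, k) with the test AUC and internal
#' LOO-MSE; the JSON summary records the peak k and peak fold-averaged AUC.
#'
#' @param res a \code{nested_cv_result}.
#' @param tsv_path output TSV path.
#' @param json_path optional JSON summary path.
#' @return Invisibly, \code{tsv_path}.
#' @export
write_cv_result <- function(res, tsv_path, json_path = NULL) {
  n_folds <- nrow(res$auc)
  k_max <- ncol(res$auc)
  out <- data.frame(fold = rep(seq_len(n_folds), each = k_max),
                    k = rep(seq_len(k_max), n_folds),
                    auc = as.vector(t(res$auc)),
                    loo_mse = as.vector(t(res$loo_mse)))
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(method = res$method, lambda = res$lambda,
                              peak_k = res$peak_k, peak_auc = res$peak_auc,
                              mean_auc = res$mean_auc),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
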