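#' Genotype-by-status contingency table
#'
#' Tabulates one SNP's genotypes against case/control status into a 3x2
#' table (rows: genotype 0/1/2; columns: case, control). Missing genotypes
#' are excluded.
#'
#' @param x_i genotype vector of one SNP (0/1/2, \code{NA} allowed).
#' @param y labels in \{-1, +1\}.
#' @return Integer 3x2 matrix with dimnames.
#' @export
genotype_contingency <- function(x_i, y) {
  if (length(x_i) != length(y)) stop("genotype and label lengths differ")
  keep <- !is.na(x_i)
  if (!any(keep)) stop("all genotypes missing for this SNP")
  x <- x_i[keep]
  yy <- y[keep]
  tab <- matrix(0L, nrow = 3, ncol = 2,
                dimnames = list(genotype = c("0", "1", "2"),
                                status = c("case", "control")))
  for (g in 0:2) {
    tab[g + 1L, 1L] <- sum(x == g & yy == 1)
    tab[g + 1L, 2L] <- sum(x == g & yy == -1)
  }
  tab
}

#' Exact association test on a 3x2 genotype table
#'
#' Conditional exact test: all 3x2 tables with the observed row and column
#' margins are enumerated (two free cells), each table's multivariate
#' hypergeometric probability is computed in log-gamma arithmetic, and the
#' p-value is the total probability of tables no more probable than the
#' observed one (probability ordering, with relative tolerance \code{1e-7}
#' on the comparison). When one genotype row is empty this reduces to the
#' 2x2 Fisher exact test.
#'
#' @param tab integer 3x2 matrix of genotype-by-status counts.
#' @param enumeration_cap totals above this fall back to the chi-square test
#'   on the same table, with a warning (default 5000; the enumeration costs
#'   O(total^2) probability evaluations).
#' @return The p-value.
#' @export
fisher_exact_3x2 <- function(tab, enumeration_cap = 5000) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3L, 2L))) stop("tab must be a 3x2 matrix")
  if (any(tab < 0)) stop("negative counts")
  N <- sum(tab)
  if (N == 0) stop("empty table")
  if (N > enumeration_cap) {
    warning("table total ", N, " exceeds the enumeration cap; ",
            "falling back to the chi-square test")
    return(suppressWarnings(stats::chisq.test(tab[rowSums(tab) > 0, ,
                                                  drop = FALSE])$p.value))
  }
  r <- rowSums(tab)
  cc <- colSums(tab)[1L]  # cases
  # log-probability of the table with case-column cells (x0, x1, x2):
  # prod_g C(r_g, x_g) / C(N, cases)
  denom <- lchoose(N, cc)
  logp_obs <- sum(lchoose(r, tab[, 1L])) - denom
  total <- 0
  for (x0 in 0:min(r[1L], cc)) {
    lo <- max(0, cc - x0 - r[3L])
    hi <- min(r[2L], cc - x0)
    if (lo > hi) next
    x1 <- lo:hi
    x2 <- cc - x0 - x1
    logp <- lchoose(r[1L], x0) + lchoose(r[2L], x1) + lchoose(r[3L], x2) -
      denom
    total <- total + sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
  }
  min(total, 1)
}

#' Rank SNPs by association p-value (filter selection)
#'
#' Univariate filter: every SNP is scored by the exact 3x2 genotype
#' association test on the supplied (training) data and ranked by ascending
#' p-value, ties broken toward the smaller feature index.
#'
#' @param X genotype matrix, SNPs by samples (missing allowed; excluded
#'   per-SNP from the table).
#' @param y labels in \{-1, +1\}.
#' @param k number of top features to return (default all).
#' @param snp_ids optional feature identifiers.
#' @return Data frame with \code{rank}, \code{feature}, \code{snp_id},
#'   \code{p_value}, ordered by rank, \code{k} rows.
#' @export
filter_select <- function(X, y, k = nrow(X), snp_ids = NULL) {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of features")
  p <- vapply(seq_len(n), function(i)
    fisher_exact_3x2(genotype_contingency(X[i, ], y)), numeric(1))
  ord <- order(p, seq_len(n))[seq_len(k)]
  data.frame(rank = seq_len(k), feature = ord,
             snp_id = if (is.null(snp_ids)) as.character(ord)
                      else snp_ids[ord],
             p_value = p[ord], stringsAsFactors = FALSE)
}

#' Hybrid filter-then-wrapper selection
#'
#' The p-value filter first keeps the \code{prefilter} SNPs with the
#' smallest p-values; greedy forward selection then picks \code{k} features
#' from that reduced set. Reported feature indices refer to the original
#' matrix.
#'
#' @inheritParams greedy_rls
#' @param prefilter number of SNPs retained by the filter stage (default
#'   50).
#' @return As \code{\link{greedy_rls}}, plus element \code{prefilter} (the
#'   filter ranking used).
#' @export
hybrid_select <- function(X, y, lambda = 1, k, prefilter = 50,
                          snp_ids = NULL, bias = FALSE) {
  if (prefilter > nrow(X)) stop("prefilter exceeds the number of features")
  if (k > prefilter) stop("k exceeds the prefilter size")
  flt <- filter_select(X, y, k = prefilter, snp_ids = snp_ids)
  keep <- flt$feature
  res <- greedy_rls(X[keep, , drop = FALSE], y, lambda, k, bias = bias)
  # map back to original indexing
  res$trace$feature <- keep[res$trace$feature]
  res$trace$snp_id <- if (is.null(snp_ids)) as.character(res$trace$feature)
                      else snp_ids[res$trace$feature]
  res$trace$method <- "hybrid"
  res$predictor$features <- keep[res$predictor$features]
  res$prefilter <- flt
  res
}

#' Write a filter ranking as TSV
#'
#' @param ranking data frame from \code{\link{filter_select}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_filter_ranking <- function(ranking, path) {
  utils::write.table(ranking[, c("rank", "snp_id", "p_value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
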