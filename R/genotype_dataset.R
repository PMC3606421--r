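#' Case-control genotype dataset
#'
#' Container for a SNP-by-sample matrix of minor-allele counts together with
#' case/control labels and marker metadata. This is the common currency of the
#' package: every reader returns one, every selection and evaluation routine
#' consumes one.
#'
#' @param X integer matrix, one row per SNP and one column per sample; entries
#'   are minor-allele counts in \{0, 1, 2\} or \code{NA} for a missing call.
#' @param y numeric vector of class labels, one per sample; \code{+1} marks a
#'   case and \code{-1} a control.
#' @param snp_ids character vector of unique SNP identifiers (one per row of
#'   \code{X}). Defaults to \code{rownames(X)} or generated ids.
#' @param sample_ids character vector of unique sample identifiers (one per
#'   column). Defaults to \code{colnames(X)} or generated ids.
#' @param snp_meta optional data frame with columns \code{chrom} and \code{pos}
#'   giving the chromosome and base-pair position of each SNP.
#'
#' @return An object of class \code{genotype_dataset}: a list with elements
#'   \code{X}, \code{y}, \code{snp_ids}, \code{sample_ids}, \code{snp_meta}.
#' @export
genotype_dataset <- function(X, y, snp_ids = NULL, sample_ids = NULL,
                             snp_meta = NULL) {
  if (!is.matrix(X)) stop("X must be a matrix of minor-allele counts")
  storage.mode(X) <- "integer"
  n <- nrow(X)
  m <- ncol(X)
  bad <- !is.na(X) & !(X %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype out of range at SNP row %d, sample column %d: %s",
                 idx[1L], idx[2L], X[idx[1L], idx[2L]]))
  }
  y <- as.numeric(y)
  if (length(y) != m)
    stop(sprintf("length(y) = %d but X has %d samples", length(y), m))
  if (!all(y %in% c(-1, 1)))
    stop("labels must be exactly +1 (case) or -1 (control)")
  if (is.null(snp_ids)) {
    snp_ids <- rownames(X)
    if (is.null(snp_ids)) snp_ids <- sprintf("snp%06d", seq_len(n))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(X)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample%05d", seq_len(m))
  }
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != n) stop("snp_ids length must equal nrow(X)")
  if (length(sample_ids) != m) stop("sample_ids length must equal ncol(X)")
  if (anyDuplicated(snp_ids))
    stop("duplicated SNP ids: ", paste(unique(snp_ids[duplicated(snp_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(chrom = rep("1", n), pos = seq_len(n),
                           stringsAsFactors = FALSE)
  } else {
    snp_meta <- as.data.frame(snp_meta)
    if (!all(c("chrom", "pos") %in% names(snp_meta)))
      stop("snp_meta must have columns 'chrom' and 'pos'")
    if (nrow(snp_meta) != n) stop("snp_meta must have one row per SNP")
  }
  dimnames(X) <- list(snp_ids, sample_ids)
  structure(list(X = X, y = y, snp_ids = snp_ids, sample_ids = sample_ids,
                 snp_meta = snp_meta),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_case <- sum(x$y == 1)
  n_ctrl <- sum(x$y == -1)
  n_miss <- sum(is.na(x$X))
  cat(sprintf("genotype_dataset: %d SNPs x %d samples (%d cases, %d controls)\n",
              nrow(x$X), ncol(x$X), n_case, n_ctrl))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$X)))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param ds a \code{genotype_dataset}.
#' @param snps integer or logical index over SNP rows (default all).
#' @param samples integer or logical index over sample columns (default all).
#' @return The subsetted \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, snps = NULL, samples = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(snps)) snps <- seq_len(nrow(ds$X))
  if (is.null(samples)) samples <- seq_len(ncol(ds$X))
  genotype_dataset(ds$X[snps, samples, drop = FALSE],
                   ds$y[samples],
                   snp_ids = ds$snp_ids[snps],
                   sample_ids = ds$sample_ids[samples],
                   snp_meta = ds$snp_meta[snps, , drop = FALSE])
}

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
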