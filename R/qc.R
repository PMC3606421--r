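#' Per-SNP and per-sample allele statistics
#'
#' Computes, for every SNP, the minor allele frequency and missing rate, and
#' for every sample its missing rate. The allele frequency of the counted
#' allele is \eqn{f = \sum g / (2 n_{obs})} over non-missing genotypes
#' \eqn{g}; the MAF is \eqn{\min(f, 1 - f)}.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @return A list with \code{snp}: data frame (\code{snp_id}, \code{maf},
#'   \code{missing_rate}, \code{maf_defined}), and \code{sample}: data frame
#'   (\code{sample_id}, \code{missing_rate}). SNPs with no observed genotype
#'   get \code{maf = NA}, \code{maf_defined = FALSE} and missing rate 1.
#' @export
allele_stats <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  X <- ds$X
  m <- ncol(X)
  miss <- is.na(X)
  n_obs <- m - rowSums(miss)
  f <- rowSums(X, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(f, 1 - f)
  maf[n_obs == 0L] <- NA_real_
  list(
    snp = data.frame(snp_id = ds$snp_ids, maf = maf,
                     missing_rate = 1 - n_obs / m,
                     maf_defined = n_obs > 0L,
                     stringsAsFactors = FALSE),
    sample = data.frame(sample_id = ds$sample_ids,
                        missing_rate = colMeans(miss),
                        stringsAsFactors = FALSE)
  )
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the Hardy-Weinberg expectation
#' \eqn{N(1-f)^2, 2Nf(1-f), Nf^2} where \eqn{f} is the sample minor allele
#' frequency. The default is the 1-df chi-square goodness-of-fit test; an
#' exact mid-p test (full enumeration of heterozygote counts conditional on
#' the allele counts) is available with \code{method = "exact"}. Monomorphic
#' input returns \code{p = 1} by convention.
#'
#' @param n_hom_major count of major-allele homozygotes (genotype 0).
#' @param n_het count of heterozygotes (genotype 1).
#' @param n_hom_minor count of minor-allele homozygotes (genotype 2).
#' @param method \code{"chisq"} (default) or \code{"exact"} (mid-p).
#' @return The p-value.
#' @export
hwe_test <- function(n_hom_major, n_het, n_hom_minor,
                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  N <- sum(counts)
  if (N == 0) stop("total genotype count is zero")
  n_minor <- n_het + 2 * n_hom_minor
  f <- n_minor / (2 * N)
  if (f == 0 || f == 1) return(1)

  if (method == "chisq") {
    expected <- N * c((1 - f)^2, 2 * f * (1 - f), f^2)
    stat <- sum((counts - expected)^2 / expected)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }

  # exact: P(het = h | allele counts) over h with the parity of n_minor
  na <- min(n_minor, 2 * N - n_minor)
  hs <- seq(na %% 2, na, by = 2)
  logp <- lfactorial(N) + hs * log(2) +
    lfactorial(na) + lfactorial(2 * N - na) - lfactorial(2 * N) -
    lfactorial((na - hs) / 2) - lfactorial(hs) -
    lfactorial(N - (na + hs) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  h_obs <- n_het
  p_obs <- p[match(h_obs, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)]) - 0.5 * p_obs
}

#' Impute missing genotypes
#'
#' Replaces missing genotype calls so that downstream selection can work on a
#' dense matrix. Non-missing entries are never changed.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param strategy \code{"mode"} (per-SNP most frequent genotype, ties broken
#'   toward the smaller genotype value), \code{"mean_rounded"} (per-SNP mean
#'   rounded to the nearest count, half away from zero) or \code{"zero"}.
#' @return The imputed \code{genotype_dataset} (no missing entries).
#' @export
impute_missing <- function(ds, strategy = c("mode", "mean_rounded", "zero")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ds, "genotype_dataset"))
  X <- ds$X
  miss_rows <- which(rowSums(is.na(X)) > 0L)
  if (!length(miss_rows)) return(ds)
  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing))
    stop("cannot impute: SNP(s) with all genotypes missing: ",
         paste(ds$snp_ids[all_missing], collapse = ", "))
  for (i in miss_rows) {
    row <- X[i, ]
    obs <- row[!is.na(row)]
    fill <- switch(strategy,
      mode = {
        tab <- tabulate(obs + 1L, nbins = 3L)
        which.max(tab) - 1L  # which.max takes the first (smallest) on ties
      },
      mean_rounded = as.integer(floor(mean(obs) + 0.5)),
      zero = 0L)
    X[i, is.na(row)] <- fill
  }
  genotype_dataset(X, ds$y, ds$snp_ids, ds$sample_ids, ds$snp_meta)
}

#' Apply standard GWAS quality-control filters
#'
#' Filters samples, then SNPs. Samples with a missing rate above
#' \code{sample_missing_threshold} are dropped first; per-SNP statistics are
#' then recomputed on the surviving samples, and SNPs are dropped when they
#' fail Hardy-Weinberg equilibrium in the controls
#' (\code{p < hwe_threshold}), have \code{MAF < maf_threshold}, or a missing
#' rate above \code{snp_missing_threshold}. Each dropped item records the
#' first filter that triggered (checked in the order hwe, maf, missing).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param hwe_threshold drop SNPs with HWE-in-controls p below this
#'   (default \code{1e-3}).
#' @param maf_threshold drop SNPs with minor allele frequency below this
#'   (default 0.01).
#' @param snp_missing_threshold drop SNPs with missing rate above this
#'   (default 0.05).
#' @param sample_missing_threshold drop samples with missing rate above this
#'   (default 0.05).
#' @param hwe_method HWE test variant, see \code{\link{hwe_test}}.
#' @return A list with \code{dataset} (the filtered \code{genotype_dataset})
#'   and \code{report}, a \code{qc_report} with per-SNP and per-sample
#'   statistics and kept/dropped decisions.
#' @export
apply_qc <- function(ds, hwe_threshold = 1e-3, maf_threshold = 0.01,
                     snp_missing_threshold = 0.05,
                     sample_missing_threshold = 0.05,
                     hwe_method = "chisq") {
  stopifnot(inherits(ds, "genotype_dataset"))
  m0 <- ncol(ds$X)

  sample_missing <- colMeans(is.na(ds$X))
  sample_kept <- sample_missing <= sample_missing_threshold
  if (!any(sample_kept)) stop("QC dropped every sample")
  sample_report <- data.frame(sample_id = ds$sample_ids,
                              missing_rate = sample_missing,
                              kept = sample_kept,
                              reason = ifelse(sample_kept, "", "missing"),
                              stringsAsFactors = FALSE)
  ds2 <- subset_dataset(ds, samples = which(sample_kept))

  st <- allele_stats(ds2)$snp
  ctrl <- ds2$X[, ds2$y == -1, drop = FALSE]
  hwe_p <- vapply(seq_len(nrow(ctrl)), function(i) {
    g <- ctrl[i, ]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_test(sum(g == 0L), sum(g == 1L), sum(g == 2L), method = hwe_method)
  }, numeric(1))

  fail_hwe <- hwe_p < hwe_threshold
  fail_maf <- !st$maf_defined | st$maf < maf_threshold
  fail_missing <- st$missing_rate > snp_missing_threshold
  reason <- rep("", nrow(ds2$X))
  reason[fail_missing] <- "missing"
  reason[fail_maf] <- "maf"
  reason[fail_hwe] <- "hwe"  # first-triggered: hwe, then maf, then missing
  snp_kept <- reason == ""
  if (!any(snp_kept)) stop("QC dropped every SNP")
  snp_report <- data.frame(snp_id = ds2$snp_ids, maf = st$maf,
                           missing_rate = st$missing_rate, hwe_p = hwe_p,
                           kept = snp_kept, reason = reason,
                           stringsAsFactors = FALSE)
  out <- subset_dataset(ds2, snps = which(snp_kept))
  report <- structure(list(snp = snp_report, sample = sample_report,
                           n_samples_in = m0, n_snps_in = nrow(ds$X)),
                      class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: kept %d/%d samples, %d/%d SNPs\n",
              sum(x$sample$kept), x$n_samples_in,
              sum(x$snp$kept), x$n_snps_in))
  dropped <- x$snp$reason[!x$snp$kept]
  if (length(dropped)) {
    tab <- table(dropped)
    cat("  SNPs dropped by reason:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
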