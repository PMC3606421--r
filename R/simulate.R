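#' Define a simulation scenario
#'
#' Presets describing case-control SNP datasets with known causal structure:
#' \describe{
#'   \item{null}{no causal SNPs; 1,000 SNPs x 600 samples.}
#'   \item{strong_signal}{5 causal SNPs with per-allele log-odds effects
#'     evenly spaced over [0.8, 1.5]; 2,000 SNPs x 600 samples.}
#'   \item{redundant_pair}{one causal SNP (effect 1.5) duplicated as an
#'     identical neighbouring SNP, probing filter-vs-wrapper behaviour on
#'     redundant features; 2,000 SNPs x 600 samples.}
#'   \item{weak_polygenic}{50 causal SNPs with small effects (0.7 each,
#'     diluted across the polygenic liability): individually near-random
#'     markers that combine into a predictive model; 2,000 SNPs x 1,000
#'     samples.}
#' }
#' Genotypes are Hardy-Weinberg draws with per-SNP minor allele frequency
#' uniform on \code{[maf_lo, maf_hi]}; the phenotype follows a logistic
#' liability with the target prevalence.
#'
#' @param preset one of \code{"null"}, \code{"strong_signal"},
#'   \code{"redundant_pair"}, \code{"weak_polygenic"}.
#' @param ... overrides for any scenario field (\code{n_snps},
#'   \code{m_samples}, \code{maf_lo}, \code{maf_hi}, \code{causal},
#'   \code{effects}, \code{prevalence}, \code{duplicate_pairs}).
#' @return A \code{sim_scenario} list.
#' @export
make_scenario <- function(preset = c("null", "strong_signal",
                                     "redundant_pair", "weak_polygenic"),
                          ...) {
  preset <- match.arg(preset)
  sc <- list(preset = preset, n_snps = 2000L, m_samples = 600L,
             maf_lo = 0.05, maf_hi = 0.5, causal = integer(0),
             effects = numeric(0), prevalence = 0.5,
             duplicate_pairs = NULL)
  sc <- switch(preset,
    null = within_list(sc, n_snps = 1000L),
    strong_signal = within_list(sc, causal = spread_indices(5L, 2000L),
                                effects = seq(0.8, 1.5, length.out = 5)),
    redundant_pair = within_list(sc, causal = 1000L, effects = 1.5,
                                 duplicate_pairs = list(c(1000L, 1001L))),
    weak_polygenic = within_list(sc, m_samples = 1000L,
                                 causal = spread_indices(50L, 2000L),
                                 effects = rep(0.7, 50)))
  over <- list(...)
  unknown <- setdiff(names(over), names(sc))
  if (length(unknown)) stop("unknown scenario field(s): ",
                            paste(unknown, collapse = ", "))
  sc[names(over)] <- over
  validate_scenario(sc)
  structure(sc, class = "sim_scenario")
}

within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

# k causal indices spread evenly across 1..n
spread_indices <- function(k, n) {
  as.integer(round(seq(n / (k + 1), n * k / (k + 1), length.out = k)))
}

validate_scenario <- function(sc) {
  if (sc$maf_lo <= 0 || sc$maf_hi > 0.5 || sc$maf_lo > sc$maf_hi)
    stop("MAF bounds must satisfy 0 < maf_lo <= maf_hi <= 0.5")
  if (length(sc$causal) != length(sc$effects))
    stop("causal and effects must have equal length")
  if (any(sc$causal < 1L | sc$causal > sc$n_snps))
    stop("causal index out of range")
  if (sc$prevalence <= 0 || sc$prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  invisible(sc)
}

#' Simulate genotypes under a scenario
#'
#' Per SNP, a minor allele frequency is drawn uniformly from the scenario's
#' MAF range and genotypes are i.i.d. Binomial(2, MAF) across samples
#' (Hardy-Weinberg, no linkage disequilibrium). Scenario duplicate pairs are
#' then applied by copying rows, which is the optional block-correlation
#' mechanism used for redundancy tests. Deterministic given the seed.
#'
#' @param scenario a \code{sim_scenario}.
#' @param seed RNG seed.
#' @return List with \code{X} (integer SNP-by-sample matrix) and \code{maf}
#'   (the drawn per-SNP frequencies).
#' @export
simulate_genotypes <- function(scenario, seed = 1) {
  validate_scenario(scenario)
  n <- scenario$n_snps
  m <- scenario$m_samples
  with_seed(seed, {
    maf <- stats::runif(n, scenario$maf_lo, scenario$maf_hi)
    X <- matrix(stats::rbinom(n * m, 2L, rep(maf, m)), nrow = n, ncol = m)
    if (!is.null(scenario$duplicate_pairs)) {
      for (pr in scenario$duplicate_pairs) {
        X[pr[2L], ] <- X[pr[1L], ]
        maf[pr[2L]] <- maf[pr[1L]]
      }
    }
    list(X = X, maf = maf)
  })
}

#' Simulate a case-control phenotype
#'
#' Logistic liability: \eqn{\mathrm{logit}\,P(\mathrm{case}) = \beta_0 +
#' \sum_c \beta_c X_c}, with the intercept solved numerically so the
#' expected prevalence over the simulated genotypes matches the scenario
#' target. Labels are Bernoulli draws mapped to \{+1, -1\}.
#'
#' @param X genotype matrix from \code{\link{simulate_genotypes}}.
#' @param scenario a \code{sim_scenario}.
#' @param seed RNG seed.
#' @return Numeric label vector in \{-1, +1\}.
#' @export
simulate_phenotype <- function(X, scenario, seed = 1) {
  validate_scenario(scenario)
  if (any(scenario$causal > nrow(X))) stop("causal index out of range for X")
  eta <- if (length(scenario$causal))
    as.numeric(crossprod(X[scenario$causal, , drop = FALSE],
                         scenario$effects))
  else rep(0, ncol(X))
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                         scenario$prevalence,
                       interval = c(-50, 50))$root
  with_seed(seed, {
    case <- stats::rbinom(ncol(X), 1L, stats::plogis(b0 + eta))
    ifelse(case == 1L, 1, -1)
  })
}

#' Simulate a complete case-control dataset
#'
#' Convenience wrapper: genotypes then phenotype under one seed, packaged as
#' a \code{\link{genotype_dataset}} with fabricated marker metadata. The
#' scenario plus seed determine the dataset exactly.
#'
#' @param scenario a \code{sim_scenario}.
#' @param seed RNG seed (genotypes use \code{seed}, labels \code{seed + 1};
#'   both kept below 2^31).
#' @return List with \code{dataset} (a \code{genotype_dataset}),
#'   \code{causal} (true causal indices), \code{effects}, \code{maf}.
#' @export
simulate_dataset <- function(scenario, seed = 1) {
  g <- simulate_genotypes(scenario, seed = seed)
  y <- simulate_phenotype(g$X, scenario, seed = (seed %% 2147483546) + 1)
  ds <- genotype_dataset(g$X, y,
                         snp_ids = sprintf("snp%06d", seq_len(nrow(g$X))),
                         snp_meta = data.frame(
                           chrom = rep("1", nrow(g$X)),
                           pos = seq_len(nrow(g$X)) * 1000L,
                           stringsAsFactors = FALSE))
  list(dataset = ds, causal = scenario$causal, effects = scenario$effects,
       maf = g$maf)
}
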