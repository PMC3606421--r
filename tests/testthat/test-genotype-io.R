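test_that("PLINK .bed decoding matches the hand-decoded bit layout", {
  dir <- withr::local_tempdir()
  # 1 SNP, 4 samples, genotype byte 0b11100100: sample 1 in the two lowest
  # bits (00 -> 2), then 01 -> missing, 10 -> 1, 11 -> 0
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0xE4)), file.path(dir, "t.bed"))
  writeLines("1\trs1\t0\t100\tA\tG", file.path(dir, "t.bim"))
  writeLines(sprintf("f%d\ts%d\t0\t0\t0\t%d", 1:4, 1:4, c(2, 1, 2, 1)),
             file.path(dir, "t.fam"))
  ds <- read_plink(file.path(dir, "t.bed"))
  expect_identical(as.vector(ds$X), c(2L, NA, 1L, 0L))
  expect_identical(ds$y, c(1, -1, 1, -1))
  expect_identical(ds$snp_ids, "rs1")
})

test_that("PLINK padding bits beyond the last sample are ignored", {
  dir <- withr::local_tempdir()
  # 1 SNP, 5 samples: first byte 4 genotypes, second byte 1 genotype + pad
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0xE4, 0x03)), file.path(dir, "t.bed"))
  writeLines("2\trs9\t0\t55\tC\tT", file.path(dir, "t.bim"))
  writeLines(sprintf("f%d\ts%d\t0\t0\t0\t%d", 1:5, 1:5, c(2, 1, 2, 1, 2)),
             file.path(dir, "t.fam"))
  ds <- read_plink(file.path(dir, "t.bed"))
  expect_identical(ncol(ds$X), 5L)
  expect_identical(as.vector(ds$X), c(2L, NA, 1L, 0L, 0L))
})

test_that("malformed PLINK filesets are rejected with specific errors", {
  dir <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100\tA\tG", file.path(dir, "t.bim"))
  writeLines("f1\ts1\t0\t0\t0\t2", file.path(dir, "t.fam"))
  bed <- file.path(dir, "t.bed")

  writeBin(as.raw(c(0xAA, 0xBB, 0x01, 0x00)), bed)
  expect_error(read_plink(bed), "magic")
  writeBin(as.raw(c(0x6C, 0x1B, 0x00, 0x00)), bed)
  expect_error(read_plink(bed), "individual-major")
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0x00, 0x00)), bed)
  expect_error(read_plink(bed), "truncated")
  # bad phenotype names the sample
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0x00)), bed)
  writeLines("f1\tsampleX\t0\t0\t0\t-9", file.path(dir, "t.fam"))
  expect_error(read_plink(bed), "sampleX")
})

test_that("PLINK and TSV round trips are identity, missing included", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(n = 10, m = 8, seed = 42, missing = 5)

  write_plink(ds, file.path(dir, "rt"))
  back <- read_plink(file.path(dir, "rt.bed"))
  expect_identical(unname(back$X), unname(ds$X))
  expect_identical(back$y, ds$y)
  expect_identical(back$snp_ids, ds$snp_ids)

  write_genotype_tsv(ds, file.path(dir, "g.tsv"), file.path(dir, "l.tsv"))
  back2 <- read_genotype_tsv(file.path(dir, "g.tsv"), file.path(dir, "l.tsv"))
  expect_identical(unname(back2$X), unname(ds$X))
  expect_identical(back2$y, ds$y)
})

test_that("TSV reader validates values, shape and label coverage", {
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "g.tsv"); lp <- file.path(dir, "l.tsv")
  writeLines(c("snp_id\ts1\ts2\ts3", "snpA\t0\t0\t0", "snpB\t0\t1\t0"), gp)
  writeLines(c("sample_id\tstatus", "s1\tcase", "s2\tcontrol", "s3\t+1"), lp)
  ds <- read_genotype_tsv(gp, lp)
  expect_identical(ds$y, c(1, -1, 1))
  expect_true(all(ds$X[1, ] == 0L))

  writeLines(c("snp_id\ts1\ts2\ts3", "snpA\t0\t3\t0"), gp)
  expect_error(read_genotype_tsv(gp, lp), "'3'.*row 1.*column 2")
  writeLines(c("snp_id\ts1\ts2\ts3", "snpA\t0\t1"), gp)
  expect_error(read_genotype_tsv(gp, lp), "ragged")
  writeLines(c("snp_id\ts1\ts2\ts3", "snpA\t0\t1\t2", "snpA\t0\t1\t2"), gp)
  expect_error(read_genotype_tsv(gp, lp), "duplicated")
  writeLines(c("snp_id\ts1\ts2\ts9", "snpA\t0\t1\t2"), gp)
  expect_error(read_genotype_tsv(gp, lp), "s9")
})

test_that("imputation fills holes per strategy and never touches observed calls", {
  X <- rbind(c(0L, 0L, 1L, NA), c(0L, 1L, 1L, NA))
  ds <- genotype_dataset(X, c(1, -1, 1, -1))
  imp <- impute_missing(ds, "mode")
  expect_identical(as.vector(imp$X[1, ]), c(0L, 0L, 1L, 0L))
  expect_identical(as.vector(imp$X[2, ]), c(0L, 1L, 1L, 1L))

  X2 <- rbind(c(0L, 1L, 1L, NA, 2L))
  ds2 <- genotype_dataset(X2, c(1, -1, 1, -1, 1))
  expect_identical(impute_missing(ds2, "mean_rounded")$X[1, 4], 1L)
  expect_identical(impute_missing(ds2, "zero")$X[1, 4], 0L)

  clean <- tiny_dataset(seed = 3)
  expect_identical(impute_missing(clean)$X, clean$X)

  all_na <- genotype_dataset(rbind(rep(NA_integer_, 3)), c(1, -1, 1))
  expect_error(impute_missing(all_na), "all genotypes missing")
})

test_that("allele statistics follow the definitional counts", {
  ds <- genotype_dataset(rbind(c(0L, 1L, 2L, 2L),
                               c(0L, 0L, 0L, 0L),
                               c(0L, NA, NA, 2L)),
                         c(1, -1, 1, -1))
  st <- allele_stats(ds)
  expect_equal(st$snp$maf, c(3 / 8, 0, 0.5))
  expect_equal(st$snp$missing_rate, c(0, 0, 0.5))
  expect_equal(st$sample$missing_rate, c(0, 1, 1, 0) / 3)
})

test_that("MAF is invariant under swapping the allele coding g -> 2-g", {
  ds <- tiny_dataset(n = 20, m = 30, seed = 5)
  flipped <- genotype_dataset(2L - ds$X, ds$y)
  expect_equal(allele_stats(ds)$snp$maf, allele_stats(flipped)$snp$maf)
})

test_that("HWE chi-square matches hand-summed (obs-exp)^2/exp", {
  expect_equal(hwe_test(25, 50, 25), 1)       # exact HW proportions
  expect_equal(hwe_test(10, 0, 0), 1)         # monomorphic convention
  # counts (50, 20, 30): f = 0.4, expected (36, 48, 16)
  stat <- (50 - 36)^2 / 36 + (20 - 48)^2 / 48 + (30 - 16)^2 / 16
  expect_equal(hwe_test(50, 20, 30), pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("exact mid-p HWE test sums the heterozygote-count distribution", {
  # N=5, 4 minor alleles: h in {0,2,4}; probabilities from direct counting
  # of genotype configurations: P(h) = 2^h * N! * na! * (2N-na)! /
  #   (n0! n1! n2! (2N)!)
  direct <- function(h, N, na) {
    2^h * factorial(N) * factorial(na) * factorial(2 * N - na) /
      (factorial((na - h) / 2) * factorial(h) *
         factorial(N - (na + h) / 2) * factorial(2 * N))
  }
  ps <- sapply(c(0, 2, 4), direct, N = 5, na = 4)
  obs <- 2  # n = (2, 2, 1)
  expected <- sum(ps[ps <= ps[2] * (1 + 1e-12)]) - 0.5 * ps[2]
  expect_equal(hwe_test(2, 2, 1, method = "exact"), expected,
               tolerance = 1e-12)
  expect_equal(hwe_test(10, 0, 0, method = "exact"), 1)
})

test_that("QC drops a planted low-MAF SNP with reason 'maf'", {
  set.seed(9)
  m <- 400
  X <- matrix(rbinom(10 * m, 2L, rep(runif(10, 0.2, 0.5), m)), nrow = 10)
  X[4, ] <- rbinom(m, 2L, 0.005)
  ds <- genotype_dataset(X, rep(c(1, -1), m / 2))
  qc <- apply_qc(ds)
  expect_false(qc$report$snp$kept[4])
  expect_identical(qc$report$snp$reason[4], "maf")
  expect_true(all(qc$report$snp$kept[-4]))
})

test_that("high-missingness samples are dropped before SNP statistics", {
  ds <- tiny_dataset(n = 20, m = 40, seed = 6)
  X <- ds$X
  X[sample(20, 12), 7] <- NA_integer_  # sample 7: 60% missing
  ds <- genotype_dataset(X, ds$y)
  qc <- apply_qc(ds, snp_missing_threshold = 0.5)
  expect_false(qc$report$sample$kept[7])
  expect_identical(ncol(qc$dataset$X), 39L)
  # SNP missing rates in the report are computed after the sample drop
  expect_true(all(qc$report$snp$missing_rate == 0))
})

test_that("QC is idempotent and keeps already-clean data unchanged", {
  sim <- simulate_dataset(make_scenario("null", n_snps = 50L,
                                        m_samples = 300L), seed = 2)
  qc1 <- apply_qc(sim$dataset)
  qc2 <- apply_qc(qc1$dataset)
  expect_identical(qc2$dataset$X, qc1$dataset$X)
  expect_true(all(qc2$report$snp$kept))
})
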