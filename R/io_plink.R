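#' Read a PLINK binary fileset
#'
#' Reads a SNP-major PLINK 1 binary fileset (.bed/.bim/.fam) into a
#' \code{\link{genotype_dataset}}. Genotypes are decoded to minor-allele
#' counts of the A1 allele: 2-bit code \code{00} maps to 2 copies, \code{10}
#' to 1, \code{11} to 0 and \code{01} to missing. The phenotype column of the
#' .fam file must use the PLINK case/control coding (2 = case, 1 = control),
#' which becomes \code{+1}/\code{-1}.
#'
#' @param bed_path path to the .bed file (magic bytes 0x6C 0x1B, mode 0x01).
#' @param bim_path path to the .bim file; defaults to \code{bed_path} with the
#'   extension swapped.
#' @param fam_path path to the .fam file; defaults analogously.
#' @return A \code{genotype_dataset} with SNP rows ordered as in the .bim file
#'   and sample columns ordered as in the .fam file.
#' @seealso \code{\link{write_plink}} for the inverse operation.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)

  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam) < 6) stop(".fam file must have 6 columns")
  names(fam)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")

  n <- nrow(bim)
  m <- nrow(fam)
  pheno <- suppressWarnings(as.integer(fam$pheno))
  bad_ph <- which(is.na(pheno) | !(pheno %in% c(1L, 2L)))
  if (length(bad_ph))
    stop(sprintf("phenotype of sample '%s' is '%s'; expected 1 (control) or 2 (case)",
                 fam$iid[bad_ph[1L]], fam$pheno[bad_ph[1L]]))
  y <- ifelse(pheno == 2L, 1, -1)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6C) || raw[2L] != as.raw(0x1B))
    stop(".bed format error: missing magic bytes 0x6C 0x1B in ", bed_path)
  if (raw[3L] == as.raw(0x00))
    stop(".bed is individual-major (mode byte 0x00); only SNP-major mode is supported")
  if (raw[3L] != as.raw(0x01))
    stop(".bed mode byte is ", as.integer(raw[3L]), "; expected 0x01 (SNP-major)")
  bps <- ceiling(m / 4)  # bytes per SNP row
  if (length(raw) != 3L + bps * n)
    stop(sprintf(".bed truncated or padded: %d data bytes, expected %d (%d SNPs x %d bytes)",
                 length(raw) - 3L, bps * n, n, bps))

  # 256 x 4 lookup: genotypes packed 4 per byte from the least significant bits
  lut <- plink_byte_lut()
  body <- as.integer(raw[-(1:3)]) + 1L
  g4 <- lut[body, , drop = FALSE]           # (bps*n) x 4, byte-major order
  g <- t(g4)                                # 4 x (bps*n)
  dim(g) <- c(4L * bps, n)                  # column j = padded genotypes of SNP j
  X <- t(g[seq_len(m), , drop = FALSE])     # n x m, padding bits dropped

  genotype_dataset(X, y, snp_ids = bim$id, sample_ids = fam$iid,
                   snp_meta = data.frame(chrom = bim$chrom, pos = bim$pos,
                                         stringsAsFactors = FALSE))
}

# decode table: 2-bit genotype codes for each byte value, sample 1 in the two
# lowest-order bits; code 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing
plink_byte_lut <- function() {
  code_map <- c(2L, NA_integer_, 1L, 0L)  # indexed by code value 0..3
  b <- 0:255
  cbind(code_map[bitwAnd(b, 3L) + 1L],
        code_map[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        code_map[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        code_map[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Write a PLINK binary fileset
#'
#' Writes a \code{genotype_dataset} as a SNP-major PLINK 1 binary fileset.
#' A1 is recorded as the counted (minor) allele, arbitrarily labelled
#' \code{A}/\code{B} when allele letters are unknown.
#'
#' @param ds a \code{genotype_dataset}.
#' @param prefix output path prefix; \code{<prefix>.bed/.bim/.fam} are written.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  X <- ds$X
  n <- nrow(X)
  m <- ncol(X)
  bps <- ceiling(m / 4)

  # encode: genotype -> 2-bit code (2->00, 1->10, 0->11, NA->01)
  enc <- matrix(3L, nrow = n, ncol = m)
  enc[!is.na(X) & X == 2L] <- 0L
  enc[!is.na(X) & X == 1L] <- 2L
  enc[is.na(X)] <- 1L
  pad <- matrix(0L, nrow = n, ncol = 4L * bps - m)  # zero-padded high bits
  codes <- t(cbind(enc, pad))                        # (4*bps) x n, sample-major
  dim(codes) <- c(4L, bps * n)
  bytes <- as.raw(codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] +
                    64L * codes[4L, ])

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(chrom = ds$snp_meta$chrom, id = ds$snp_ids, cm = 0,
                    pos = ds$snp_meta$pos, a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = ds$sample_ids, iid = ds$sample_ids, pat = 0, mat = 0,
                    sex = 0, pheno = ifelse(ds$y == 1, 2L, 1L))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
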