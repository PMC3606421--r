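#' Read genotypes and labels from tab-separated text
#'
#' The genotype file is a rectangular table with a header row of sample ids,
#' one SNP per row, first column the SNP id, values in \{0, 1, 2, NA\}. The
#' label file has two columns, \code{sample_id} and \code{status}, where the
#' status is \code{case}/\code{control} (or \code{+1}/\code{-1}, \code{1}/
#' \code{-1}).
#'
#' @param genotype_path path to the genotype TSV.
#' @param label_path path to the label TSV.
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_genotype_tsv <- function(genotype_path, label_path) {
  lines <- readLines(genotype_path)
  if (length(lines) < 2L) stop("genotype TSV has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  m <- length(header) - 1L
  if (m < 1L) stop("genotype TSV header has no sample ids")
  widths <- lengths(fields[-1L])
  if (any(widths != m + 1L))
    stop(sprintf("ragged genotype TSV: row %d has %d fields, expected %d",
                 which(widths != m + 1L)[1L] + 1L, widths[widths != m + 1L][1L],
                 m + 1L))
  sample_ids <- header[-1L]
  snp_ids <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(snp_ids))
    stop("duplicated SNP ids in genotype TSV: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  vals <- unlist(lapply(fields[-1L], `[`, -1L), use.names = FALSE)
  ok <- vals %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    j <- which(!ok)[1L]
    stop(sprintf("invalid genotype '%s' at SNP row %d, sample column %d (allowed: 0/1/2/NA)",
                 vals[j], (j - 1L) %/% m + 1L, (j - 1L) %% m + 1L))
  }
  X <- matrix(suppressWarnings(as.integer(vals)), nrow = length(snp_ids),
              ncol = m, byrow = TRUE)

  lab <- utils::read.table(label_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  if (!all(c("sample_id", "status") %in% names(lab)))
    stop("label file must have columns 'sample_id' and 'status'")
  missing_samples <- setdiff(sample_ids, lab$sample_id)
  if (length(missing_samples))
    stop("samples present in genotypes but absent from labels: ",
         paste(missing_samples, collapse = ", "))
  status <- lab$status[match(sample_ids, lab$sample_id)]
  y <- ifelse(status %in% c("case", "1", "+1"), 1,
              ifelse(status %in% c("control", "-1"), -1, NA))
  if (anyNA(y))
    stop("unrecognized status value(s): ",
         paste(unique(status[is.na(y)]), collapse = ", "))
  genotype_dataset(X, y, snp_ids = snp_ids, sample_ids = sample_ids)
}

#' Write genotypes and labels as tab-separated text
#'
#' Inverse of \code{\link{read_genotype_tsv}}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param genotype_path output path for the genotype table.
#' @param label_path output path for the label table.
#' @return Invisibly, \code{ds}.
#' @export
write_genotype_tsv <- function(ds, genotype_path, label_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  vals <- ds$X
  out <- cbind(ds$snp_ids, matrix(ifelse(is.na(vals), "NA", as.character(vals)),
                                  nrow = nrow(vals)))
  lines <- c(paste(c("snp_id", ds$sample_ids), collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, genotype_path)
  lab <- data.frame(sample_id = ds$sample_ids,
                    status = ifelse(ds$y == 1, "case", "control"))
  utils::write.table(lab, label_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}
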