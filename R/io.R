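# Readers and writers for the plain-text formats the pipeline exchanges:
# BED3/BED6/narrowPeak, chromosome sizes, count tables + sample sheets,
# TSS tables and differential-expression tables. All tabular files are
# uncompressed TSV without quoting so that reruns are byte-identical.

#' Read peak intervals from a BED or narrowPeak file
#'
#' BED coordinates are 0-based half-open and carried through unchanged.
#' For narrowPeak input (10 columns) the summit is reconstructed as
#' `start + offset` from the 10th column when the offset is non-negative.
#'
#' @param path file path.
#' @param format `"auto"` (by column count), `"bed"`, or `"narrowPeak"`.
#' @return an [interval_set()].
#' @export
read_bed <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         quote = "")
  nc <- ncol(x)
  if (nc < 3) nr_stop("BED file %s has fewer than 3 columns", path)
  if (format == "auto") format <- if (nc >= 10) "narrowPeak" else "bed"
  if (any(x[[2]] >= x[[3]])) {
    bad <- which(x[[2]] >= x[[3]])[1]
    nr_stop("malformed interval (start >= end) at %s line %d", path, bad)
  }
  summit <- NULL
  if (format == "narrowPeak" && nc >= 10) {
    off <- x[[10]]
    summit <- ifelse(off >= 0, x[[2]] + off, NA_real_)
  }
  interval_set(x[[1]], x[[2]], x[[3]],
               name = if (nc >= 4) x[[4]] else NULL,
               summit = summit,
               score = if (nc >= 5) suppressWarnings(as.numeric(x[[5]])) else NULL)
}

#' Write an interval set as BED6 or narrowPeak
#'
#' @param x interval set.
#' @param path output path.
#' @param format `"bed"` (BED6) or `"narrowPeak"` (summit offset in column
#'   10, `-1` when absent).
#' @export
write_bed <- function(x, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  x <- as_interval_set(x)
  score <- ifelse(is.na(x$score), 0, x$score)
  if (format == "bed") {
    out <- data.frame(x$chrom, format_num(x$start), format_num(x$end),
                      x$name, format_num(score), ".")
  } else {
    off <- ifelse(is.na(x$summit), -1, x$summit - x$start)
    out <- data.frame(x$chrom, format_num(x$start), format_num(x$end),
                      x$name, format_num(score), ".",
                      "0", "-1", "-1", format_num(off))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# deterministic plain formatting for coordinates/scores (no sci notation)
format_num <- function(x) {
  ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), format_num(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write per-region count tables with their sample sheet
#'
#' The count table is a TSV whose first column `region` holds region names
#' and whose remaining columns are per-sample integer counts. The sample
#' sheet is a TSV with columns `sample_id`, `condition`, `replicate`,
#' `library_size` describing those columns.
#'
#' @param counts_path,samples_path file paths.
#' @return `read_count_table`: list with `counts` (matrix, regions x samples)
#'   and `samples` (data frame).
#' @export
read_count_table <- function(counts_path, samples_path) {
  ct <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "library_size")
  if (!all(need %in% names(samples))) {
    nr_stop("sample sheet needs columns: %s", paste(need, collapse = ", "))
  }
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct[[1]]
  if (!setequal(colnames(m), samples$sample_id)) {
    nr_stop("count table columns and sample sheet sample_id disagree")
  }
  m <- m[, samples$sample_id, drop = FALSE]
  list(counts = m, samples = samples)
}

#' @rdname read_count_table
#' @param counts matrix of counts (regions x samples, named dimensions).
#' @param samples sample sheet data frame.
#' @export
write_count_table <- function(counts, samples, counts_path, samples_path) {
  out <- data.frame(region = rownames(counts), counts, check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a TSS table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss` (0-based), `strand`
#'   and optionally `symbol`, `biotype`.
#' @return data frame of gene records.
#' @export
read_tss_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(x))) {
    nr_stop("TSS table needs columns: %s", paste(need, collapse = ", "))
  }
  x
}

#' Read a differential-expression summary table
#'
#' @param path TSV with columns `gene_id`, `fc`, `fdr`.
#' @return data frame.
#' @export
read_de_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fc", "fdr") %in% names(x))) {
    nr_stop("DE table needs columns gene_id, fc, fdr")
  }
  x
}
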