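# Genomic interval data model and peak-set algebra.
#
# Coordinates are 0-based half-open throughout (BED convention). 1-based
# inputs (GTF) are converted at the boundary by their readers. Internally the
# algebra delegates to GenomicRanges/IRanges; the conversion to 1-based
# closed coordinates happens only inside this file.

#' Construct a set of genomic intervals
#'
#' The unit of all peak algebra in the package. Coordinates are 0-based
#' half-open: a peak covering the first ten bases of a chromosome is
#' `start = 0, end = 10`. An optional summit (0-based position of maximal
#' signal, as in narrowPeak files) and score may be carried along.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param name optional identifiers (generated as `region_i` when missing).
#' @param summit optional 0-based summit positions with
#'   `start <= summit < end`.
#' @param score optional numeric scores.
#' @return an `interval_set`: a data frame with columns `chrom`, `start`,
#'   `end`, `name`, `summit`, `score`, sorted by (chrom, start, end).
#' @examples
#' interval_set(c("chr1", "chr1"), c(100, 500), c(300, 900))
#' @export
interval_set <- function(chrom, start, end, name = NULL, summit = NULL,
                         score = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    nr_stop("chrom/start/end lengths differ (%d/%d/%d)",
            length(chrom), n, length(end))
  }
  if (is.null(name)) name <- if (n) paste0("region_", seq_len(n)) else character(0)
  if (is.null(summit)) summit <- rep(NA_real_, n)
  if (is.null(score)) score <- rep(NA_real_, n)
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  name = as.character(name), summit = as.numeric(summit),
                  score = as.numeric(score), stringsAsFactors = FALSE)
  validate_interval_set(x)
  x <- x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

#' Coerce a data frame to an interval set
#'
#' @param x data frame with at least `chrom`, `start`, `end` columns.
#' @return an [interval_set()].
#' @export
as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    nr_stop("interval data frame needs columns: %s", paste(need, collapse = ", "))
  }
  interval_set(x$chrom, x$start, x$end,
               name = if ("name" %in% names(x)) x$name else NULL,
               summit = if ("summit" %in% names(x)) x$summit else NULL,
               score = if ("score" %in% names(x)) x$score else NULL)
}

validate_interval_set <- function(x) {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    nr_stop("malformed interval (start >= end or start < 0) at record %d: %s:%s-%s",
            bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  }
  s <- x$summit
  bads <- which(!is.na(s) & !(s >= x$start & s < x$end))
  if (length(bads)) {
    nr_stop("summit outside interval at record %d (%s)", bads[1], x$name[bads[1]])
  }
  invisible(x)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set with %d intervals on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

# ---- GRanges bridge (1-based closed <-> 0-based half-open) ------------------

# overlapsAny without the "no sequence levels in common" chatter: disjoint
# chromosome sets are a legitimate no-overlap answer here
iset_overlaps_any <- function(query, subject, ...) {
  suppressWarnings(IRanges::overlapsAny(query, subject, ...))
}

iset_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end),
                         name = x$name)
}

granges_to_iset <- function(gr, name = NULL) {
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr),
               name = name)
}

# ---- peak-set algebra -------------------------------------------------------

#' Intervals of one set overlapping another
#'
#' bedtools `intersectBed -u`-like: returns the records of `a` (with their
#' original coordinates, names and summits) that overlap at least one interval
#' of `b` by at least `min_overlap_bp` bases.
#'
#' @param a,b interval sets.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return the overlapping subset of `a`.
#' @export
intersect_regions <- function(a, b, min_overlap_bp = 1L) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  if (min_overlap_bp < 1) nr_stop("min_overlap_bp must be >= 1")
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  hit <- iset_overlaps_any(iset_to_granges(a), iset_to_granges(b),
                              minoverlap = as.integer(min_overlap_bp))
  out <- a[hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Merge overlapping or near-adjacent intervals
#'
#' bedtools `mergeBed`-like. With `max_gap_bp = 0` only overlapping or
#' book-ended intervals (end of one equals start of the next, half-open) are
#' merged; larger gaps bridge intervals up to that many bases apart.
#'
#' @param a interval set.
#' @param max_gap_bp non-negative gap tolerated between merged intervals.
#' @return merged `interval_set`; names are regenerated, summits dropped.
#' @export
merge_regions <- function(a, max_gap_bp = 0L) {
  a <- as_interval_set(a)
  if (max_gap_bp < 0) nr_stop("max_gap_bp must be >= 0")
  if (nrow(a) == 0) return(a)
  gr <- GenomicRanges::reduce(iset_to_granges(a),
                              min.gapwidth = as.integer(max_gap_bp) + 1L)
  granges_to_iset(gr)
}

#' Reproducible peaks supported by both replicates
#'
#' Peaks detected in both biological replicates of one condition. Default is
#' bedtools-faithful: intervals of `rep1` overlapping `rep2`, then merged
#' (so reported coordinates derive from replicate 1). `mode = "covered"`
#' returns the merged replicate-symmetric covered-base intersection instead.
#'
#' @param rep1,rep2 replicate peak sets.
#' @param mode `"rep1"` (default) or `"covered"`.
#' @param min_overlap_bp minimum replicate overlap (default 1).
#' @return merged `interval_set` of reproducible peaks.
#' @export
reproducible_peaks <- function(rep1, rep2, mode = c("rep1", "covered"),
                               min_overlap_bp = 1L) {
  mode <- match.arg(mode)
  rep1 <- as_interval_set(rep1); rep2 <- as_interval_set(rep2)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    warning("empty replicate peak set; no reproducible peaks")
    return(rep1[0, , drop = FALSE])
  }
  if (mode == "rep1") {
    merge_regions(intersect_regions(rep1, rep2, min_overlap_bp))
  } else {
    gr <- GenomicRanges::intersect(iset_to_granges(rep1), iset_to_granges(rep2))
    granges_to_iset(GenomicRanges::reduce(gr))
  }
}

#' Consensus regions supported by a minimum number of samples
#'
#' Merged regions in which at least `min_samples` distinct input peak sets
#' contribute coverage. The default counts support base by base: a base
#' belongs to the consensus when covered by `min_samples` or more sample sets
#' (each set counted once per base), and surviving bases are merged into
#' intervals. `mode = "region"` instead merges the union of all sets and
#' retains merged regions overlapped by at least `min_samples` sets.
#'
#' With a single sample and `min_samples = 1` the merged sample itself is the
#' consensus (the single-replicate rule).
#'
#' @param samples list of interval sets.
#' @param min_samples minimum supporting sample count. Default: 2 when more
#'   than one sample is given, else 1.
#' @param mode `"base"` (default) or `"region"` support counting.
#' @return merged consensus `interval_set`.
#' @export
consensus_regions <- function(samples, min_samples = NULL,
                              mode = c("base", "region")) {
  mode <- match.arg(mode)
  if (!is.list(samples) || length(samples) == 0) {
    nr_stop("samples must be a non-empty list of interval sets")
  }
  samples <- lapply(samples, as_interval_set)
  if (is.null(min_samples)) min_samples <- if (length(samples) > 1) 2L else 1L
  if (min_samples < 1) nr_stop("min_samples must be >= 1")
  if (min_samples > length(samples)) {
    nr_stop("min_samples (%d) exceeds number of samples (%d)",
            min_samples, length(samples))
  }
  # shared seqinfo so per-sample coverage vectors align chromosome-wise
  all_chrom <- sort(unique(unlist(lapply(samples, function(s) s$chrom))))
  max_end <- vapply(all_chrom, function(ch) {
    max(unlist(lapply(samples, function(s) s$end[s$chrom == ch])), 0)
  }, numeric(1))
  si <- GenomeInfoDb::Seqinfo(seqnames = all_chrom,
                              seqlengths = as.integer(max_end))
  grs <- lapply(samples, function(s) {
    gr <- iset_to_granges(s)
    GenomeInfoDb::seqlevels(gr) <- all_chrom
    GenomeInfoDb::seqinfo(gr) <- si
    GenomicRanges::reduce(gr)                 # each set counts once per base
  })
  if (mode == "base") {
    cov <- Reduce(`+`, lapply(grs, GenomicRanges::coverage))
    keep <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
    gr <- GenomicRanges::GRanges(keep)
    granges_to_iset(GenomicRanges::reduce(gr))
  } else {
    un <- GenomicRanges::reduce(do.call(c, grs))
    support <- Reduce(`+`, lapply(grs, function(g) {
      as.integer(iset_overlaps_any(un, g))
    }))
    granges_to_iset(un[support >= min_samples])
  }
}

#' Remove blacklisted and off-pattern intervals
#'
#' Two-stage filter used before any quantification: intervals overlapping a
#' blacklist (artifact catalog) by at least one base are dropped, then
#' intervals on chromosomes whose name does not start with
#' `allowed_chrom_pattern` (a regex anchored at the name start, e.g. `"NC"`
#' to keep complete-assembly sequences only) are dropped.
#'
#' @param a interval set.
#' @param blacklist interval set of artifact regions (may be empty or NULL).
#' @param allowed_chrom_pattern regex anchored at the chromosome-name start;
#'   `NULL` keeps all chromosomes.
#' @return the filtered `interval_set`, with attribute `removed` giving the
#'   per-filter removal counts.
#' @export
filter_regions <- function(a, blacklist = NULL, allowed_chrom_pattern = NULL) {
  a <- as_interval_set(a)
  n0 <- nrow(a)
  if (!is.null(blacklist) && nrow(as_interval_set(blacklist)) > 0 && n0 > 0) {
    hit <- iset_overlaps_any(iset_to_granges(a),
                                iset_to_granges(as_interval_set(blacklist)))
    a <- a[!hit, , drop = FALSE]
  }
  n1 <- nrow(a)
  if (!is.null(allowed_chrom_pattern) && n1 > 0) {
    keep <- grepl(paste0("^(", allowed_chrom_pattern, ")"), a$chrom)
    a <- a[keep, , drop = FALSE]
  }
  rownames(a) <- NULL
  class(a) <- c("interval_set", "data.frame")
  attr(a, "removed") <- c(blacklist = n0 - n1, chromosome = n1 - nrow(a))
  nr_log("filter_regions: removed %d blacklist, %d off-pattern of %d",
         n0 - n1, n1 - nrow(a), n0)
  a
}

#' Fraction of query intervals overlapping a reference set
#'
#' Counts follow the query set's records (not merged spans): the value is the
#' number of query intervals with >= `min_overlap_bp` overlap against any
#' reference interval, divided by the query size.
#'
#' @param query non-empty interval set.
#' @param reference interval set.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(query, reference, min_overlap_bp = 1L) {
  query <- as_interval_set(query); reference <- as_interval_set(reference)
  if (nrow(query) == 0) nr_stop("undefined fraction: empty query set")
  if (nrow(reference) == 0) return(0)
  hit <- iset_overlaps_any(iset_to_granges(query), iset_to_granges(reference),
                              minoverlap = as.integer(min_overlap_bp))
  mean(hit)
}
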