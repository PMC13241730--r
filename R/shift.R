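# Paired comparison of ligand-induced occupancy changes between two factors
# (e.g. VDR versus RXR) at co-occupied regions, within one dataset and
# across studies.

#' Regions co-occupied by two factors
#'
#' Peaks of factor A overlapping at least one peak of factor B (delegates to
#' [intersect_regions()]); the common-region count is attached.
#'
#' @param peaks_a,peaks_b the two factors' peak sets.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return an [interval_set()] of `peaks_a` records overlapping `peaks_b`,
#'   with attribute `n_common`.
#' @export
common_regions <- function(peaks_a, peaks_b, min_overlap_bp = 1L) {
  out <- intersect_regions(peaks_a, peaks_b, min_overlap_bp)
  attr(out, "n_common") <- nrow(out)
  nr_log("common_regions: %d co-occupied regions", nrow(out))
  out
}

#' Paired per-region signal ratios for two factors
#'
#' At common regions quantified for both factors under the same treated and
#' control conditions, computes the per-region ratio pair
#' `(ratio_a, ratio_b)` used for paired scatter/density comparison. Regions
#' missing from either signal matrix are excluded and counted.
#'
#' @param regions common regions (an [interval_set()]).
#' @param signals_a,signals_b [signal_matrix()] objects for the two factors
#'   (replicates averaged internally).
#' @param treated,control condition names.
#' @param pseudocount signal pseudocount (default 0.1).
#' @param study_id optional study label.
#' @return a `paired_ratios` object: data frame `region`, `ratio_a`,
#'   `ratio_b` with attributes `study_id` and `n_excluded`.
#' @export
paired_ratio_table <- function(regions, signals_a, signals_b, treated,
                               control, pseudocount = 0.1,
                               study_id = NA_character_) {
  regions <- as_interval_set(regions)
  ra <- signal_ratio(signals_a, treated, control, pseudocount = pseudocount)
  rb <- signal_ratio(signals_b, treated, control, pseudocount = pseudocount)
  pa <- ra$per_region_ratio[regions$name]
  pb <- rb$per_region_ratio[regions$name]
  ok <- !is.na(pa) & !is.na(pb)
  n_excl <- sum(!ok)
  if (n_excl) nr_log("paired_ratio_table: %d region(s) missing signal excluded", n_excl)
  out <- data.frame(region = regions$name[ok], ratio_a = unname(pa[ok]),
                    ratio_b = unname(pb[ok]), stringsAsFactors = FALSE)
  attr(out, "study_id") <- study_id
  attr(out, "n_excluded") <- n_excl
  class(out) <- c("paired_ratios", "data.frame")
  out
}

#' Construct a paired-ratio table directly from ratio vectors
#'
#' @param region region names.
#' @param ratio_a,ratio_b positive per-region ratios for the two factors.
#' @param study_id optional study label.
#' @return a `paired_ratios` object.
#' @export
paired_ratios <- function(region, ratio_a, ratio_b,
                          study_id = NA_character_) {
  stopifnot(length(region) == length(ratio_a),
            length(region) == length(ratio_b))
  if (any(ratio_a <= 0) || any(ratio_b <= 0)) {
    nr_stop("paired ratios must be > 0")
  }
  out <- data.frame(region = as.character(region), ratio_a = ratio_a,
                    ratio_b = ratio_b, stringsAsFactors = FALSE)
  attr(out, "study_id") <- study_id
  attr(out, "n_excluded") <- 0L
  class(out) <- c("paired_ratios", "data.frame")
  out
}

#' Systematic-shift statistic for paired factor ratios
#'
#' Operationalizes "systematic shift toward one factor" as the median paired
#' log2 difference `median(log2(ratio_a) - log2(ratio_b))`, with a two-sided
#' exact sign test on the paired differences (ties excluded, the standard
#' exact procedure) and the fraction of regions strictly above the diagonal
#' (`ratio_a > ratio_b`, ties in the denominator). A Wilcoxon signed-rank
#' alternative is available.
#'
#' @param p a `paired_ratios` table with >= 10 pairs.
#' @param test `"sign"` (exact, default) or `"wilcoxon"`.
#' @return list with `delta_log2`, `p_value`, `fraction_above`, `n`,
#'   `n_ties`, `test`.
#' @export
shift_statistic <- function(p, test = c("sign", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(p), all(c("ratio_a", "ratio_b") %in% names(p)))
  if (nrow(p) < 10) nr_stop("need >= 10 paired regions (got %d)", nrow(p))
  d <- log2(p$ratio_a) - log2(p$ratio_b)
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  n_tie <- sum(d == 0)
  pv <- if (test == "sign") {
    if (n_pos + n_neg == 0) 1 else
      stats::binom.test(n_pos, n_pos + n_neg, p = 0.5)$p.value
  } else {
    stats::wilcox.test(d[d != 0], mu = 0, exact = FALSE)$p.value
  }
  list(delta_log2 = stats::median(d), p_value = pv,
       fraction_above = n_pos / nrow(p), n = nrow(p), n_ties = n_tie,
       test = test)
}

#' Per-study average factor ratios
#'
#' Arithmetic mean of the per-region ratios of each factor within each study
#' — the data behind cross-study factor-versus-factor scatter plots. A
#' geometric mean is selectable.
#'
#' @param studies list of `paired_ratios` tables (each with a `study_id`
#'   attribute, or named list entries).
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return data frame with `study_id`, `n_regions`, `mean_ratio_a`,
#'   `mean_ratio_b`.
#' @export
per_study_average_ratios <- function(studies,
                                     mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!is.list(studies) || !length(studies)) nr_stop("need >= 1 study")
  if (is.data.frame(studies)) studies <- list(studies)
  avg <- function(x) if (mean_type == "arithmetic") mean(x) else exp(mean(log(x)))
  rows <- lapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    id <- attr(s, "study_id")
    if (is.null(id) || is.na(id)) id <- names(studies)[i] %||% paste0("study_", i)
    data.frame(study_id = id, n_regions = nrow(s),
               mean_ratio_a = avg(s$ratio_a), mean_ratio_b = avg(s$ratio_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2D histogram of paired ratios for pseudocolor scatter export
#'
#' Counts of region pairs per 2D bin on the log2 scale, for rendering a
#' density scatter externally.
#'
#' @param p a `paired_ratios` table.
#' @param n_bins bins per axis (default 50).
#' @return data frame with bin centers `log2_ratio_a`, `log2_ratio_b` and
#'   `count` (only non-empty bins).
#' @export
paired_density_grid <- function(p, n_bins = 50) {
  la <- log2(p$ratio_a); lb <- log2(p$ratio_b)
  rng <- range(c(la, lb))
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ia <- pmin(findInterval(la, brk, rightmost.closed = TRUE), n_bins)
  ib <- pmin(findInterval(lb, brk, rightmost.closed = TRUE), n_bins)
  tab <- table(ia, ib)
  idx <- which(tab > 0, arr.ind = TRUE)
  ctr <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  data.frame(log2_ratio_a = ctr[as.integer(rownames(tab))[idx[, 1]]],
             log2_ratio_b = ctr[as.integer(colnames(tab))[idx[, 2]]],
             count = as.integer(tab[idx]))
}
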