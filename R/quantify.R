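# Tag counting, RPKM normalization, summit-window signals, replicate
# averaging and the ligand-versus-control signal-ratio statistics.

#' Construct a tag library
#'
#' Holds a sample's sequencing tags either as per-chromosome 0-based tag
#' start positions or (when tags are unavailable) as precomputed per-region
#' counts, together with the library size used for RPKM normalization.
#'
#' @param sample_id,condition sample metadata strings.
#' @param replicate integer replicate index.
#' @param placements named list (by chromosome) of 0-based tag positions, or
#'   `NULL` when only counts are available.
#' @param total_mapped total mapped reads in the library (> 0).
#' @return a `tag_library` object.
#' @export
tag_library <- function(sample_id, condition, replicate, placements = NULL,
                        total_mapped) {
  if (total_mapped <= 0) nr_stop("total_mapped must be > 0")
  if (!is.null(placements)) {
    if (!is.list(placements) || is.null(names(placements))) {
      nr_stop("placements must be a named list of positions per chromosome")
    }
    placements <- lapply(placements, function(p) sort(as.numeric(p)))
    if (total_mapped < sum(lengths(placements))) {
      nr_stop("total_mapped (%s) is below the number of placements", total_mapped)
    }
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = as.integer(replicate), placements = placements,
                 total_mapped = as.numeric(total_mapped)),
            class = "tag_library")
}

#' Count tags falling in regions
#'
#' A tag is counted for a region when its start position lies in
#' `[start, end)` (half-open). Regions on chromosomes absent from the library
#' get count 0.
#'
#' @param tags a [tag_library()] with placements.
#' @param regions an [interval_set()].
#' @return integer vector of counts, one per region (named by region).
#' @export
count_in_regions <- function(tags, regions) {
  stopifnot(inherits(tags, "tag_library"))
  if (is.null(tags$placements)) nr_stop("tag library has no placements")
  regions <- as_interval_set(regions)
  out <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    pos <- tags$placements[[ch]]
    if (is.null(pos)) {
      nr_log("count_in_regions: chromosome %s absent from tags", ch)
      next
    }
    # positions sorted; tags with start <= x counted by findInterval(x, pos)
    hi <- findInterval(regions$end[idx] - 0.5, pos)
    lo <- findInterval(regions$start[idx] - 0.5, pos)
    out[idx] <- hi - lo
  }
  names(out) <- regions$name
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((region_len_bp / 1000) * (total_mapped / 1e6))`.
#'
#' @param count non-negative counts (vectorized).
#' @param region_len_bp region lengths in bases (> 0).
#' @param total_mapped library size (> 0).
#' @return non-negative RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(count, region_len_bp, total_mapped) {
  if (any(total_mapped <= 0)) nr_stop("total_mapped must be > 0")
  if (any(region_len_bp <= 0)) nr_stop("region_len_bp must be > 0")
  count / ((region_len_bp / 1000) * (total_mapped / 1e6))
}

#' Construct a signal matrix (regions x samples)
#'
#' @param regions an [interval_set()].
#' @param samples sample sheet data frame with `sample_id`, `condition`,
#'   `replicate`, `library_size`.
#' @param values numeric matrix, `nrow(regions)` x `nrow(samples)`.
#' @return a `signal_matrix` object.
#' @export
signal_matrix <- function(regions, samples, values) {
  regions <- as_interval_set(regions)
  values <- as.matrix(values)
  if (nrow(values) != nrow(regions) || ncol(values) != nrow(samples)) {
    nr_stop("signal matrix dimensions (%dx%d) do not match regions (%d) x samples (%d)",
            nrow(values), ncol(values), nrow(regions), nrow(samples))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    nr_stop("signal values must be finite and non-negative")
  }
  rownames(values) <- regions$name
  colnames(values) <- samples$sample_id
  structure(list(regions = regions, samples = samples, values = values),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d regions x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' RPKM signal matrix from tag libraries or a count matrix
#'
#' @param regions an [interval_set()].
#' @param tag_libs list of [tag_library()] objects (with placements), or
#'   `NULL` when `counts` is given.
#' @param counts optional precomputed count matrix (regions x samples).
#' @param samples sample sheet; required with `counts`, derived from the tag
#'   libraries otherwise.
#' @return a [signal_matrix()] of RPKM values.
#' @export
rpkm_matrix <- function(regions, tag_libs = NULL, counts = NULL, samples = NULL) {
  regions <- as_interval_set(regions)
  len <- regions$end - regions$start
  if (is.null(counts)) {
    if (is.null(tag_libs)) nr_stop("either tag_libs or counts is required")
    counts <- vapply(tag_libs, count_in_regions, numeric(nrow(regions)),
                     regions = regions)
    samples <- data.frame(
      sample_id = vapply(tag_libs, `[[`, "", "sample_id"),
      condition = vapply(tag_libs, `[[`, "", "condition"),
      replicate = vapply(tag_libs, function(t) t$replicate, 1L),
      library_size = vapply(tag_libs, function(t) t$total_mapped, 1))
  }
  counts <- as.matrix(counts)
  vals <- sweep(counts / (len / 1000), 2, samples$library_size / 1e6, "/")
  signal_matrix(regions, samples, vals)
}

#' RPKM signal in fixed windows around peak summits
#'
#' Windows span `[summit - half_width_bp, summit + half_width_bp)`, truncated
#' at position 0 (truncation is logged); RPKM uses the realized window length.
#'
#' @param tags a [tag_library()].
#' @param summits data frame with `chrom` and `summit` (0-based) columns.
#' @param half_width_bp window half width in bases (e.g. 750 or 1000).
#' @return numeric vector of RPKM values, one per summit.
#' @export
summit_window_signal <- function(tags, summits, half_width_bp = 750) {
  if (half_width_bp <= 0) nr_stop("half_width_bp must be > 0")
  start <- summits$summit - half_width_bp
  if (any(start < 0)) {
    nr_log("summit_window_signal: %d window(s) truncated at chromosome start",
           sum(start < 0))
    start <- pmax(start, 0)
  }
  end <- summits$summit + half_width_bp
  win <- interval_set(summits$chrom, start, end,
                      name = paste0("window_", seq_along(start)))
  # interval_set sorts; map back to input order
  ord <- match(paste0("window_", seq_along(start)), win$name)
  counts <- count_in_regions(tags, win)
  unname(rpkm(counts, win$end - win$start, tags$total_mapped)[ord])
}

#' Binned read distribution around peak summits
#'
#' Signals in windows of `2 * half_width_bp` centered on summits, split into
#' `bin_bp` bins — the data behind summit-centered read-distribution heatmaps.
#' Values are raw counts (`value = "count"`) or counts per million mapped
#' reads (`value = "cpm"`, default); in either unit bin sums conserve window
#' totals exactly.
#'
#' @param tag_libs list of [tag_library()] objects.
#' @param summits data frame with `chrom` and `summit` columns.
#' @param half_width_bp window half width (default 1000, i.e. 2 kb windows).
#' @param bin_bp bin width; must divide `2 * half_width_bp`.
#' @param value `"cpm"` or `"count"`.
#' @param sort_rows order rows by decreasing total signal (summed over
#'   samples) for heatmap export; the ordering is recorded in the result.
#' @return list with one summits x bins matrix per sample and the row order.
#' @export
read_distribution <- function(tag_libs, summits, half_width_bp = 1000,
                              bin_bp = 50, value = c("cpm", "count"),
                              sort_rows = FALSE) {
  value <- match.arg(value)
  if ((2 * half_width_bp) %% bin_bp != 0) {
    nr_stop("bin_bp must divide 2 * half_width_bp")
  }
  nb <- as.integer(2 * half_width_bp / bin_bp)
  ns <- nrow(summits)
  mats <- lapply(tag_libs, function(tg) {
    m <- matrix(0, ns, nb)
    for (i in seq_len(ns)) {
      pos <- tg$placements[[summits$chrom[i]]]
      if (is.null(pos)) next
      lo <- summits$summit[i] - half_width_bp
      edges <- lo + bin_bp * (0:nb)
      cnt <- findInterval(edges[-1] - 0.5, pos) - findInterval(edges[-(nb + 1)] - 0.5, pos)
      m[i, ] <- cnt
    }
    if (value == "cpm") m <- m / (tg$total_mapped / 1e6)
    dimnames(m) <- list(summit = NULL,
                        bin = paste0("bin_", seq_len(nb)))
    m
  })
  names(mats) <- vapply(tag_libs, `[[`, "", "sample_id")
  ord <- seq_len(ns)
  if (sort_rows && ns > 0) {
    ord <- order(-Reduce(`+`, lapply(mats, rowSums)))
    mats <- lapply(mats, function(m) m[ord, , drop = FALSE])
  }
  list(matrices = mats, row_order = ord, bin_bp = bin_bp,
       half_width_bp = half_width_bp, value = value)
}

#' Average replicate columns of a signal matrix by condition
#'
#' @param m a [signal_matrix()].
#' @param grouping optional named map `sample_id -> condition`; defaults to
#'   the sample sheet's `condition` column.
#' @return a [signal_matrix()] with one column per condition (arithmetic mean
#'   of its replicates), replicate set to `NA`, library size to the replicate
#'   mean.
#' @export
replicate_average <- function(m, grouping = NULL) {
  stopifnot(inherits(m, "signal_matrix"))
  cond <- if (is.null(grouping)) m$samples$condition else
    unname(grouping[m$samples$sample_id])
  if (anyNA(cond)) nr_stop("every sample must be assigned a condition")
  conds <- unique(cond)
  vals <- vapply(conds, function(cc) {
    rowMeans(m$values[, cond == cc, drop = FALSE])
  }, numeric(nrow(m$values)))
  vals <- matrix(vals, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), conds))
  samples <- data.frame(
    sample_id = conds, condition = conds, replicate = NA_integer_,
    library_size = vapply(conds, function(cc)
      mean(m$samples$library_size[cond == cc]), 1))
  signal_matrix(m$regions, samples, vals)
}

#' Ligand-versus-control signal-ratio summary
#'
#' The study-level statistic of the occupancy comparison: after averaging
#' replicates within conditions, the global ratio is
#' `median(treated) / median(control)` (ratio of medians, the default) or the
#' median of per-region ratios. Per-region ratios are
#' `(treated + pseudocount) / (control + pseudocount)`.
#'
#' @param m a [signal_matrix()] (replicates are averaged internally when the
#'   two conditions still have several columns).
#' @param treated,control condition names.
#' @param method `"ratio_of_medians"` (default) or `"median_of_ratios"`.
#' @param pseudocount RPKM pseudocount for per-region ratios (default 0.1,
#'   applied symmetrically); the global ratio of medians uses none unless the
#'   control median is 0.
#' @return a `ratio_summary`: list with `per_region_ratio`, `global_ratio`,
#'   `median_treated`, `median_control`, `method`, `pseudocount`.
#' @export
signal_ratio <- function(m, treated, control,
                         method = c("ratio_of_medians", "median_of_ratios"),
                         pseudocount = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(m, "signal_matrix"))
  if (pseudocount < 0) nr_stop("pseudocount must be >= 0")
  if (!all(c(treated, control) %in% m$samples$condition)) {
    nr_stop("conditions %s and %s must both be present", treated, control)
  }
  avg <- replicate_average(m)
  tr <- avg$values[, treated]
  co <- avg$values[, control]
  per <- (tr + pseudocount) / (co + pseudocount)
  med_t <- stats::median(tr)
  med_c <- stats::median(co)
  if (method == "ratio_of_medians") {
    if (med_c == 0) {
      if (pseudocount == 0) nr_stop("control median is 0 and pseudocount is 0")
      global <- (med_t + pseudocount) / (med_c + pseudocount)
    } else {
      global <- med_t / med_c
    }
  } else {
    global <- stats::median(per)
  }
  structure(list(per_region_ratio = per, global_ratio = global,
                 median_treated = med_t, median_control = med_c,
                 method = method, pseudocount = pseudocount,
                 treated = treated, control = control),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("signal ratio (%s vs %s): %.4f [%s; medians %.4f / %.4f; n = %d]\n",
              x$treated, x$control, x$global_ratio, x$method,
              x$median_treated, x$median_control, length(x$per_region_ratio)))
  invisible(x)
}

#' Normalize a signal matrix to its per-sample median
#'
#' Heatmap export transform: every column is divided by its median (columns
#' with median 0 are left unscaled and flagged with a warning).
#'
#' @param m a [signal_matrix()].
#' @return a [signal_matrix()] of median-normalized values.
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  med <- apply(m$values, 2, stats::median)
  if (any(med == 0)) {
    warning("column(s) with median 0 left unscaled")
    med[med == 0] <- 1
  }
  signal_matrix(m$regions, m$samples, sweep(m$values, 2, med, "/"))
}
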