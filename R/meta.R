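# Cross-study meta-analysis harness: declarative study-inclusion filters on
# a local manifest and the per-study consensus -> RPKM -> replicate average
# -> median -> ratio computation, composed from the stage operations.

#' Construct a study manifest
#'
#' One row per study with the metadata the inclusion filters need. Peak and
#' count data are carried separately (see [study_signal_ratio()]); the
#' manifest is the contract for the filtering step — no network retrieval is
#' performed.
#'
#' @param study_id,receptor,organism,ligand,cell_type character vectors.
#' @param n_control_samples,n_treated_samples replicate counts (>= 1 to be
#'   analyzable).
#' @param treatment_hours treatment duration in hours.
#' @param publication_flag associated with a published article?
#' @param year publication year (recency key for truncation).
#' @return data frame of class `study_manifest`.
#' @export
study_manifest <- function(study_id, receptor, organism = "human",
                           n_control_samples, n_treated_samples,
                           treatment_hours, ligand = NA_character_,
                           cell_type = NA_character_, publication_flag = TRUE,
                           year = NA_integer_) {
  out <- data.frame(study_id = as.character(study_id),
                    receptor = as.character(receptor),
                    organism = organism,
                    n_control_samples = as.integer(n_control_samples),
                    n_treated_samples = as.integer(n_treated_samples),
                    treatment_hours = as.numeric(treatment_hours),
                    ligand = ligand, cell_type = cell_type,
                    publication_flag = publication_flag,
                    year = as.integer(year), stringsAsFactors = FALSE)
  miss <- vapply(c("study_id", "receptor", "n_control_samples",
                   "n_treated_samples", "treatment_hours"),
                 function(f) anyNA(out[[f]]), TRUE)
  if (any(miss)) {
    bad <- names(miss)[miss][1]
    nr_stop("manifest field '%s' missing for study %s", bad,
            out$study_id[which(is.na(out[[bad]]))[1]])
  }
  class(out) <- c("study_manifest", "data.frame")
  out
}

#' Apply study-inclusion rules to a manifest
#'
#' Deterministic filters mirroring the meta-analysis selection criteria:
#' both conditions present, treatment duration at most `max_hours`,
#' published, and (when given) a per-study consensus-region count of at
#' least `min_consensus_peaks`. When more than `max_studies_per_receptor`
#' studies qualify for one receptor, studies with at least two replicates
#' per condition are preferred, then the most recent (`year`), with
#' `study_id` (lexicographic) as the final tie-break.
#'
#' @param m a [study_manifest()].
#' @param max_hours maximum treatment duration (default 24).
#' @param min_consensus_peaks minimum consensus-region count (default 2000);
#'   applied only when `consensus_counts` is given.
#' @param max_studies_per_receptor cap per receptor (default 10).
#' @param consensus_counts optional named vector `study_id -> n_consensus`.
#' @return list with `retained` (manifest subset) and `excluded`
#'   (data frame `study_id`, `reason`).
#' @export
filter_manifest <- function(m, max_hours = 24, min_consensus_peaks = 2000,
                            max_studies_per_receptor = 10,
                            consensus_counts = NULL) {
  stopifnot(is.data.frame(m))
  reason <- rep(NA_character_, nrow(m))
  reason[is.na(reason) & !(m$n_control_samples >= 1 & m$n_treated_samples >= 1)] <-
    "missing_condition"
  reason[is.na(reason) & m$treatment_hours > max_hours] <- "duration"
  reason[is.na(reason) & !m$publication_flag] <- "unpublished"
  if (!is.null(consensus_counts)) {
    cc <- consensus_counts[m$study_id]
    reason[is.na(reason) & !is.na(cc) & cc < min_consensus_peaks] <-
      "too_few_consensus_peaks"
  }
  keep <- m[is.na(reason), , drop = FALSE]
  # truncate per receptor: replicate-rich first, then recent, then id
  dropped <- character(0)
  for (r in unique(keep$receptor)) {
    idx <- which(keep$receptor == r)
    if (length(idx) <= max_studies_per_receptor) next
    sub <- keep[idx, ]
    two_rep <- sub$n_control_samples >= 2 & sub$n_treated_samples >= 2
    ord <- order(-as.integer(two_rep), -ifelse(is.na(sub$year), -Inf, sub$year),
                 sub$study_id, method = "radix")
    dropped <- c(dropped, sub$study_id[ord[-seq_len(max_studies_per_receptor)]])
  }
  reason[m$study_id %in% dropped] <- "receptor_cap"
  retained <- m[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  excluded <- data.frame(study_id = m$study_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(retained = retained, excluded = excluded)
}

#' Study-level signal ratio from peaks and counts
#'
#' The per-study computation of the meta-analysis: consensus regions from
#' the per-sample peak sets ([consensus_regions()]; `min_samples = 2` when
#' any condition has two or more replicates, else the single-replicate rule
#' `min_samples = 1`), RPKM quantification over those regions, replicate
#' averaging per condition, and the ratio of the treated to control medians.
#' Studies whose consensus set is smaller than `min_consensus_peaks` are
#' flagged excluded and emit no ratio.
#'
#' @param study list with `study_id`, `receptor`, `peak_sets` (list of
#'   [interval_set()], one per sample), `counts` (matrix over consensus
#'   regions — see `count_fun`), `samples` (sample sheet) OR `tag_libs`
#'   (list of [tag_library()]).
#' @param treated,control condition names (defaults `"ligand"`,
#'   `"vehicle"`).
#' @param min_consensus_peaks exclusion threshold (default 2000).
#' @param count_fun function(`regions`) -> count matrix for studies carrying
#'   counts rather than tags; defaults to requiring `tag_libs`.
#' @return a `study_ratio` row: data frame with `study_id`, `receptor`,
#'   `n_consensus_regions`, `median_control`, `median_treated`, `ratio`,
#'   `excluded`.
#' @export
study_signal_ratio <- function(study, treated = "ligand", control = "vehicle",
                               min_consensus_peaks = 2000, count_fun = NULL) {
  need <- c("study_id", "receptor", "peak_sets")
  if (!all(need %in% names(study))) {
    nr_stop("study needs fields: %s", paste(need, collapse = ", "))
  }
  min_samples <- if (length(study$peak_sets) > 1) 2L else 1L
  cons <- consensus_regions(study$peak_sets, min_samples = min_samples)
  n_cons <- nrow(cons)
  row <- data.frame(study_id = study$study_id, receptor = study$receptor,
                    n_consensus_regions = n_cons,
                    median_control = NA_real_, median_treated = NA_real_,
                    ratio = NA_real_, excluded = FALSE,
                    stringsAsFactors = FALSE)
  if (n_cons < min_consensus_peaks) {
    row$excluded <- TRUE
    nr_log("study %s excluded: %d consensus regions < %d",
           study$study_id, n_cons, min_consensus_peaks)
    return(row)
  }
  sm <- if (!is.null(study$tag_libs)) {
    rpkm_matrix(cons, tag_libs = study$tag_libs)
  } else if (!is.null(count_fun)) {
    rpkm_matrix(cons, counts = count_fun(cons), samples = study$samples)
  } else {
    nr_stop("study %s carries neither tag_libs nor a count_fun", study$study_id)
  }
  rs <- signal_ratio(sm, treated, control)
  row$median_control <- rs$median_control
  row$median_treated <- rs$median_treated
  row$ratio <- rs$global_ratio
  row
}

#' Median study ratio per receptor
#'
#' @param ratios data frame of `study_signal_ratio` rows (excluded studies
#'   are dropped).
#' @return data frame with `receptor`, `n_studies`, `median_ratio`,
#'   `is_median` (FALSE when only one study backs the value).
#' @export
summarize_receptor <- function(ratios) {
  ratios <- ratios[!ratios$excluded & !is.na(ratios$ratio), , drop = FALSE]
  if (!nrow(ratios)) {
    return(data.frame(receptor = character(), n_studies = integer(),
                      median_ratio = numeric(), is_median = logical()))
  }
  rows <- lapply(split(ratios, ratios$receptor), function(s) {
    data.frame(receptor = s$receptor[1], n_studies = nrow(s),
               median_ratio = stats::median(s$ratio),
               is_median = nrow(s) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample-by-sample correlation of shared-region signals
#'
#' Pearson correlation matrix over the RPKM columns of a signal matrix —
#' the numbers behind a sample-correlation heatmap (rendering is left to the
#' caller).
#'
#' @param m a [signal_matrix()].
#' @return correlation matrix (samples x samples).
#' @export
sample_correlation <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  stats::cor(m$values, method = "pearson")
}
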