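# Pipeline orchestration: configuration, input validation, and deterministic
# end-to-end runs over synthetic or user data. Stages execute in dependency
# order (simulate -> intervals -> quantify -> diff -> motifs -> genes) and
# every run writes a provenance record carrying the configuration and its
# content hash — no timestamps, so reruns are byte-identical.

#' Default pipeline configuration
#'
#' Flat named list of every tunable the pipeline applies. All thresholds
#' default to the analysis' printed values: fold-change cutoffs 1.5/0.66,
#' FDR 0.05, motif calibration at 5% empirical FPR on 5000 background
#' sequences, TSS window 25 kb.
#'
#' @param seed master seed (default 1).
#' @return named list; see [simulate_study()] for the generator fields.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    # synthetic-study generator (the study conditions)
    chrom_lengths = c(NC_T1 = 5e6, NC_T2 = 5e6, NW_T1 = 5e4),
    gc = 0.45, n_peaks = 5000,
    class_fractions = c(unresponsive = 0.8, induced = 0.1, reduced = 0.1),
    fc_by_class = c(unresponsive = 1, induced = 3, reduced = 1 / 3),
    width_range = c(200, 800), n_decoy = 20,
    nb_mean = 200, nb_dispersion = 0.05, n_replicates = 2,
    library_sizes = c(2.2e7, 1.8e7, 2.0e7, 2.1e7),
    motif_spacer = 3, rate_in_class = 0.7, background_rate = 0.05,
    n_genes = 400, frac_upregulated = 0.15, frac_linked = 0.95,
    link_window_bp = 25000,
    # analysis thresholds
    fc_up = 1.5, fc_down = 0.66, fdr = 0.05,
    motif_fpr = 0.05, background_n = 5000, tss_window = 25000,
    allowed_chrom_pattern = "NC",
    control = "vehicle", treated = "ligand")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config`: config list merged over [default_config()]
#'   defaults (unknown keys rejected).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    nr_stop("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    v <- user[[k]]
    if (!is.null(names(base[[k]])) && is.list(v)) v <- unlist(v)
    base[[k]] <- v
  }
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(config, function(v)
    if (!is.null(names(v))) as.list(v) else v), path, precision = 15)
  invisible(path)
}

config_hash <- function(config) {
  nr_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

#' Validate pipeline inputs without running stages
#'
#' Schema and coordinate-sanity checks on a written study bundle: files
#' present, BED intervals well formed (start < end, summit inside), count
#' table consistent with the sample sheet, TSS and DE tables complete.
#'
#' @param dir directory holding a study bundle (file naming as written by
#'   [simulate_study()]).
#' @return data frame of problems (`file`, `problem`); zero rows when clean.
#' @export
validate_inputs <- function(dir) {
  problems <- list()
  note <- function(file, problem) {
    problems[[length(problems) + 1]] <<- data.frame(
      file = file, problem = problem, stringsAsFactors = FALSE)
  }
  need <- c("genome.fa", "peaks.narrowPeak", "counts.tsv", "samples.tsv",
            "tss.tsv", "de.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) note(f, "missing file")
  }
  pk_path <- file.path(dir, "peaks.narrowPeak")
  peaks <- NULL
  if (file.exists(pk_path)) {
    peaks <- tryCatch(read_bed(pk_path), error = function(e) {
      note("peaks.narrowPeak", conditionMessage(e)); NULL
    })
  }
  if (file.exists(file.path(dir, "genome.fa")) && !is.null(peaks)) {
    sizes_path <- paste0(file.path(dir, "genome.fa"), ".sizes")
    if (file.exists(sizes_path)) {
      sizes <- read_chrom_sizes(sizes_path)
      bad <- peaks$chrom %in% names(sizes) & peaks$end > sizes[peaks$chrom]
      if (any(bad, na.rm = TRUE)) {
        note("peaks.narrowPeak", sprintf("%d peak(s) beyond chromosome end",
                                         sum(bad, na.rm = TRUE)))
      }
      if (!all(peaks$chrom %in% names(sizes))) {
        note("peaks.narrowPeak", "peak chromosome absent from genome")
      }
    }
  }
  if (all(file.exists(file.path(dir, c("counts.tsv", "samples.tsv"))))) {
    ct <- tryCatch(read_count_table(file.path(dir, "counts.tsv"),
                                    file.path(dir, "samples.tsv")),
                   error = function(e) {
                     note("counts.tsv", conditionMessage(e)); NULL
                   })
    if (!is.null(ct) && !is.null(peaks) &&
        !setequal(rownames(ct$counts), peaks$name)) {
      note("counts.tsv", "count regions do not match peak names")
    }
  }
  for (spec in list(c("tss.tsv", "gene_id", "chrom", "tss", "strand"),
                    c("de.tsv", "gene_id", "fc", "fdr"))) {
    f <- file.path(dir, spec[1])
    if (file.exists(f)) {
      x <- utils::read.table(f, sep = "\t", header = TRUE, nrows = 5)
      missing_cols <- setdiff(spec[-1], names(x))
      if (length(missing_cols)) {
        note(spec[1], paste("missing column(s):",
                            paste(missing_cols, collapse = ", ")))
      }
    }
  }
  if (!length(problems)) {
    return(data.frame(file = character(), problem = character()))
  }
  do.call(rbind, problems)
}

#' Run the full occupancy-analysis pipeline on a synthetic study
#'
#' Executes every stage in dependency order and writes all outputs under
#' `out_dir`:
#' \enumerate{
#'   \item simulate — study bundle plus ground truth ([simulate_study()]);
#'   \item intervals — blacklist/chromosome filtering of the peak set;
#'   \item quantify — RPKM matrix, replicate averages, global signal ratio;
#'   \item diff — fold changes, NB exact-style test, FC-only and FC+FDR
#'     classification, per-class BED files;
#'   \item motifs — background sampling, threshold calibration at the target
#'     FPR, genome-wide scan, per-class prevalence;
#'   \item genes — upregulated-gene selection, TSS-window mapping,
#'     occupancy ratios and c1-c5 clusters.
#' }
#' Reruns with an identical configuration produce byte-identical files.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the file
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    study <- simulate_study(
      seed = config$seed, dir = file.path(out_dir, "input"),
      chrom_lengths = config$chrom_lengths, gc = config$gc,
      n_peaks = config$n_peaks, class_fractions = config$class_fractions,
      fc_by_class = config$fc_by_class, width_range = config$width_range,
      n_decoy = config$n_decoy, nb_mean = config$nb_mean,
      nb_dispersion = config$nb_dispersion,
      n_replicates = config$n_replicates,
      library_sizes = config$library_sizes,
      motif_spacer = config$motif_spacer,
      rate_in_class = config$rate_in_class,
      background_rate = config$background_rate, n_genes = config$n_genes,
      frac_upregulated = config$frac_upregulated,
      frac_linked = config$frac_linked,
      link_window_bp = config$link_window_bp)

    stage <- "intervals"
    peaks <- filter_regions(study$peaks,
                            allowed_chrom_pattern = config$allowed_chrom_pattern)
    write_bed(peaks, file.path(out_dir, "peaks_filtered.bed"))

    stage <- "quantify"
    keep <- match(peaks$name, rownames(study$counts))
    sm <- rpkm_matrix(peaks, counts = study$counts[keep, , drop = FALSE],
                      samples = study$samples)
    ratio <- signal_ratio(sm, config$treated, config$control)
    jsonlite::write_json(
      list(global_ratio = ratio$global_ratio, method = ratio$method,
           median_treated = ratio$median_treated,
           median_control = ratio$median_control,
           pseudocount = ratio$pseudocount),
      file.path(out_dir, "signal_ratio.json"), auto_unbox = TRUE, digits = NA)

    stage <- "diff"
    ct <- count_table(peaks, study$samples,
                      study$counts[keep, , drop = FALSE])
    diff <- diff_occupancy(ct, config$treated, config$control,
                           up_cut = config$fc_up, down_cut = config$fc_down,
                           fdr_cut = config$fdr)
    utils::write.table(
      cbind(diff[1], lapply(diff[-1], function(col)
        if (is.numeric(col)) format_num(signif(col, 10)) else as.character(col))),
      file.path(out_dir, "differential.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (cl in levels(diff$class_fc_only)) {
      sel <- peaks[peaks$name %in% diff$region[diff$class_fc_only == cl], ,
                   drop = FALSE]
      class(sel) <- c("interval_set", "data.frame")
      write_bed(sel, file.path(out_dir, paste0("peaks_", cl, ".bed")))
    }

    stage <- "motifs"
    bg <- sample_background(study$genome, peaks$end - peaks$start,
                            n = config$background_n,
                            allowed_chrom_pattern = config$allowed_chrom_pattern,
                            seed = substream_seed(config$seed, "background"))
    thr <- calibrate_threshold(study$pwm, bg, target_fpr = config$motif_fpr)
    hits <- scan_motif(study$genome, study$pwm, thr)
    write_bed(interval_set(hits$chrom, hits$start, hits$end,
                           score = hits$score),
              file.path(out_dir, "motif_hits.bed"))
    prev <- vapply(levels(diff$class_fc_only), function(cl) {
      sel <- peaks[peaks$name %in% diff$region[diff$class_fc_only == cl], ,
                   drop = FALSE]
      class(sel) <- c("interval_set", "data.frame")
      if (nrow(sel) == 0) NA_real_ else motif_prevalence(sel, hits)
    }, numeric(1))
    jsonlite::write_json(
      list(motif_id = thr$motif_id, cutoff = thr$cutoff,
           target_fpr = thr$target_fpr, background_n = thr$background_n,
           prevalence = as.list(prev)),
      file.path(out_dir, "motif_prevalence.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "genes"
    up <- select_upregulated(study$de, fc_cut = config$fc_up,
                             fdr_cut = config$fdr,
                             coding_list = study$genes$gene_id[
                               study$genes$biotype == "protein_coding"])
    gmap <- map_peaks_to_genes(peaks,
                               study$genes[study$genes$gene_id %in% up$gene_id, ],
                               half_width_bp = config$tss_window)
    gocc <- gene_occupancy_ratio(gmap, sm, config$treated, config$control)
    gocc_out <- gocc
    for (cc in c("occ_a", "occ_b", "ratio_R")) {
      gocc_out[[cc]] <- format_num(signif(gocc_out[[cc]], 10))
    }
    utils::write.table(gocc_out, file.path(out_dir, "gene_occupancy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    list(study = study, peaks = peaks, signal = sm, ratio = ratio,
         diff = diff, threshold = thr, hits = hits, prevalence = prev,
         upregulated = up, gene_map = gmap, gene_occupancy = gocc)
  }, error = function(e) {
    nr_stop("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })

  prov <- list(package = "nrocc",
               version = as.character(utils::packageVersion("nrocc")),
               config = config, config_hash = config_hash(config),
               stages = c("simulate", "intervals", "quantify", "diff",
                          "motifs", "genes"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
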