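# TSS extraction, DE-table thresholding, TSS-window peak-to-gene mapping,
# gene-level occupancy aggregation, ratio clustering (c1-c5), peak-feature
# correlations and gene-subset intersections.

#' Extract one TSS per gene from gene models
#'
#' From a GTF file (1-based closed coordinates, converted here) the
#' gene-level features are used: the TSS is the 5' end of the annotated gene
#' — feature start for `+` strand genes, feature end for `-` strand genes —
#' reported 0-based. A prepared TSS table (see [read_tss_table()]) is passed
#' through with column checks.
#'
#' @param gene_models GTF path or a TSS data frame.
#' @param feature_type GTF feature to use (default `"gene"`).
#' @return data frame with `gene_id`, `symbol`, `chrom`, `tss`, `strand`,
#'   `biotype`.
#' @export
extract_tss <- function(gene_models, feature_type = "gene") {
  if (is.character(gene_models) && length(gene_models) == 1) {
    gr <- rtracklayer::import(gene_models, format = "gtf")
    gr <- gr[gr$type == feature_type]
    if (!length(gr)) nr_stop("no '%s' features in %s", feature_type, gene_models)
    strand <- as.character(GenomicRanges::strand(gr))
    bad <- strand == "*"
    if (any(bad)) {
      warning(sprintf("%d gene(s) without strand skipped", sum(bad)))
      gr <- gr[!bad]; strand <- strand[!bad]
    }
    tss <- ifelse(strand == "+",
                  GenomicRanges::start(gr) - 1,   # 1-based -> 0-based
                  GenomicRanges::end(gr) - 1)
    md <- S4Vectors::mcols(gr)
    data.frame(
      gene_id = as.character(md$gene_id %||% paste0("gene_", seq_along(gr))),
      symbol = as.character(md$gene_name %||% md$gene_id %||% ""),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      tss = tss, strand = strand,
      biotype = as.character(md$gene_biotype %||% "protein_coding"),
      stringsAsFactors = FALSE)
  } else {
    x <- gene_models
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(x))) {
      nr_stop("TSS table needs columns: %s", paste(need, collapse = ", "))
    }
    if (is.null(x$symbol)) x$symbol <- x$gene_id
    if (is.null(x$biotype)) x$biotype <- "protein_coding"
    x
  }
}

#' Select significantly upregulated genes from a DE table
#'
#' Strict thresholds: `fc > fc_cut` and `fdr < fdr_cut`; optionally
#' restricted to a protein-coding symbol list.
#'
#' @param de_table data frame with `gene_id`, `fc`, `fdr` (and optionally
#'   `symbol`).
#' @param fc_cut,fdr_cut thresholds (defaults 1.5 and 0.05).
#' @param coding_list optional character vector of protein-coding symbols or
#'   gene ids to intersect with.
#' @return the selected subset of `de_table`.
#' @export
select_upregulated <- function(de_table, fc_cut = 1.5, fdr_cut = 0.05,
                               coding_list = NULL) {
  if (!all(c("gene_id", "fc", "fdr") %in% names(de_table))) {
    nr_stop("DE table needs columns gene_id, fc, fdr")
  }
  keep <- de_table$fc > fc_cut & de_table$fdr < fdr_cut
  out <- de_table[keep, , drop = FALSE]
  if (!is.null(coding_list)) {
    key <- if ("symbol" %in% names(out)) out$symbol else out$gene_id
    out <- out[out$gene_id %in% coding_list | key %in% coding_list, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Map peaks to genes within a TSS window
#'
#' A peak is assigned to every gene whose window
#' `[tss - half_width_bp, tss + half_width_bp + 1)` (clipped at 0) it
#' overlaps by at least one base — many-to-many, with no nearest-gene
#' tie-breaking. Genes without any mapped peak are reported separately.
#'
#' @param peaks an [interval_set()].
#' @param genes gene data frame with `gene_id`, `chrom`, `tss`.
#' @param half_width_bp window half width (default 25000).
#' @return list with `map` (data frame `gene_id`, `peak`) and
#'   `genes_without_peaks` (character vector).
#' @export
map_peaks_to_genes <- function(peaks, genes, half_width_bp = 25000) {
  peaks <- as_interval_set(peaks)
  if (!all(c("gene_id", "chrom", "tss") %in% names(genes))) {
    nr_stop("genes need columns gene_id, chrom, tss")
  }
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$tss - half_width_bp, 0) + 1,
                     end = genes$tss + half_width_bp + 1))
  ov <- GenomicRanges::findOverlaps(win, iset_to_granges(peaks))
  map <- data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(ov)],
    peak = peaks$name[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  map <- map[order(map$gene_id, map$peak, method = "radix"), , drop = FALSE]
  rownames(map) <- NULL
  list(map = map,
       genes_without_peaks = sort(setdiff(genes$gene_id, map$gene_id)))
}

#' Gene-level occupancy ratio from mapped peaks
#'
#' For each gene, occupancy is summed over its mapped peaks in each
#' condition and the ratio
#' `R = (sum(cond_a) + pc) / (sum(cond_b) + pc)` is computed, together with
#' its c1-c5 cluster label. Genes with no mapped peaks are excluded and
#' counted.
#'
#' @param map result of [map_peaks_to_genes()] (or its `map` data frame).
#' @param signal a [signal_matrix()] whose conditions include `cond_a` and
#'   `cond_b` (replicates are averaged internally).
#' @param cond_a,cond_b condition names (numerator, denominator).
#' @param pseudocount signal pseudocount (default 0.1).
#' @return data frame with `gene_id`, `n_peaks`, `occ_a`, `occ_b`,
#'   `ratio_R`, `cluster`; excluded-gene count as attribute
#'   `n_genes_without_peaks`.
#' @export
gene_occupancy_ratio <- function(map, signal, cond_a, cond_b,
                                 pseudocount = 0.1) {
  if (is.list(map) && !is.data.frame(map)) {
    n_excl <- length(map$genes_without_peaks)
    map <- map$map
  } else {
    n_excl <- NA_integer_
  }
  stopifnot(inherits(signal, "signal_matrix"))
  avg <- replicate_average(signal)
  miss <- setdiff(map$peak, rownames(avg$values))
  if (length(miss)) {
    nr_stop("mapped peak(s) missing from the signal matrix, e.g. %s", miss[1])
  }
  occ_a <- tapply(avg$values[map$peak, cond_a], map$gene_id, sum)
  occ_b <- tapply(avg$values[map$peak, cond_b], map$gene_id, sum)
  genes <- sort(unique(map$gene_id))
  occ_a <- occ_a[genes]; occ_b <- occ_b[genes]
  R <- (occ_a + pseudocount) / (occ_b + pseudocount)
  out <- data.frame(
    gene_id = genes,
    n_peaks = as.integer(table(map$gene_id)[genes]),
    occ_a = as.numeric(occ_a), occ_b = as.numeric(occ_b),
    ratio_R = as.numeric(R),
    cluster = cluster_by_ratio(as.numeric(R)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_genes_without_peaks") <- n_excl
  out
}

#' Cluster genes by occupancy ratio into c1-c5
#'
#' Exhaustive disjoint bins with boundaries closed exactly as printed:
#' c1, R <= 0.66; c2, 0.66 < R <= 0.8; c3, 0.8 < R <= 1.25;
#' c4, 1.25 < R <= 1.5; c5, R > 1.5.
#'
#' @param R vector of positive ratios.
#' @return factor with levels c1-c5.
#' @export
cluster_by_ratio <- function(R) {
  if (any(R <= 0 | !is.finite(R))) nr_stop("ratio R must be finite and > 0")
  cut(R, breaks = c(0, 0.66, 0.8, 1.25, 1.5, Inf),
      labels = paste0("c", 1:5), right = TRUE)
}

#' Correlate per-peak signal ratios with peak features
#'
#' Correlation of a per-peak responsiveness measure (e.g. the ligand-versus-
#' vehicle signal ratio) against feature vectors (basal signal, motif score,
#' cofactor ratios, ...). Spearman by default — robust to the heavy-tailed
#' ratio distributions — with Pearson selectable. Zero-variance features get
#' `NA` and are flagged.
#'
#' @param peak_ratios numeric vector (>= 3 peaks).
#' @param features named list or data frame of aligned feature vectors.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data frame with `feature`, `estimate`, `p_value`, `n`, `method`.
#' @export
peak_feature_correlation <- function(peak_ratios, features,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(peak_ratios) < 3) nr_stop("need >= 3 peaks")
  features <- as.list(features)
  rows <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    if (length(f) != length(peak_ratios)) {
      nr_stop("feature '%s' length mismatch", nm)
    }
    ok <- is.finite(peak_ratios) & is.finite(f)
    if (stats::sd(f[ok]) == 0 || stats::sd(peak_ratios[ok]) == 0) {
      warning(sprintf("feature '%s' has zero variance; coefficient undefined", nm))
      return(data.frame(feature = nm, estimate = NA_real_, p_value = NA_real_,
                        n = sum(ok), method = method))
    }
    ct <- suppressWarnings(
      stats::cor.test(peak_ratios[ok], f[ok], method = method, exact = FALSE))
    data.frame(feature = nm, estimate = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), method = method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect genes reduced in mRNA and reduced in occupancy
#'
#' Subset A: genes whose mRNA ratio (combined versus single treatment) shows
#' at least a `1/mrna_cut`-fold reduction, i.e. `mrna_ratio <= mrna_cut`.
#' Subset B: genes with at least a `1/occ_cut`-fold reduction in summed
#' TSS-window occupancy, i.e. `occ_ratio_R <= occ_cut`. Boundaries are
#' non-strict ("at least"); set `strict = TRUE` for strict inequalities.
#'
#' @param genes character vector: the gene universe.
#' @param mrna_ratio,occ_ratio_R aligned ratio vectors.
#' @param mrna_cut,occ_cut cutoffs (defaults `1/1.5` and `1/1.25`).
#' @param strict use strict inequalities (default FALSE).
#' @return list with `subset_mrna`, `subset_occupancy`, `common`, `counts`,
#'   `fractions` (of the gene universe).
#' @export
intersect_gene_subsets <- function(genes, mrna_ratio, occ_ratio_R,
                                   mrna_cut = 1 / 1.5, occ_cut = 1 / 1.25,
                                   strict = FALSE) {
  stopifnot(length(genes) == length(mrna_ratio),
            length(genes) == length(occ_ratio_R))
  le <- if (strict) `<` else `<=`
  a <- genes[le(mrna_ratio, mrna_cut)]
  b <- genes[le(occ_ratio_R, occ_cut)]
  common <- intersect(a, b)
  n <- length(genes)
  list(subset_mrna = a, subset_occupancy = b, common = common,
       counts = c(mrna = length(a), occupancy = length(b),
                  common = length(common), universe = n),
       fractions = c(mrna = length(a) / n, occupancy = length(b) / n,
                     common = length(common) / n))
}
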