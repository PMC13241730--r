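# Fully seeded synthetic-data generator: genome, peaks, negative-binomial
# tag counts with planted occupancy classes, planted direct-repeat motif
# instances, and a gene/expression layer spatially linked to induced peaks.
# Every artifact draws from its own named random substream
# (see substream_seed()) so regeneration is reproducible piecewise and as a
# whole, and every planted truth is recorded in a machine-readable manifest.

#' Generate a random genome
#'
#' I.i.d. bases at the target GC content over two named complete-assembly
#' chromosomes (`NC_T1`, `NC_T2`) plus one small decoy scaffold (`NW_T1`)
#' that chromosome-pattern filters should remove.
#'
#' @param chrom_lengths named vector of chromosome lengths (default two
#'   5 Mb chromosomes and a 50 kb decoy).
#' @param gc GC content in (0, 1) (default 0.45).
#' @param seed integer seed.
#' @return named character vector of chromosome sequences.
#' @export
sim_genome <- function(chrom_lengths = c(NC_T1 = 5e6, NC_T2 = 5e6,
                                         NW_T1 = 5e4),
                       gc = 0.45, seed = 1) {
  stopifnot(gc > 0, gc < 1, all(chrom_lengths >= 1))
  set.seed(substream_seed(seed, "genome"))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  base_bytes <- as.raw(utf8ToInt("ACGT"))
  out <- vapply(chrom_lengths, function(L) {
    rawToChar(base_bytes[sample.int(4L, L, replace = TRUE, prob = prob)])
  }, "")
  names(out) <- names(chrom_lengths)
  out
}

#' Write a genome to FASTA with a chromosome-sizes sidecar
#'
#' @param genome named character vector of sequences.
#' @param fasta_path output FASTA path; sizes are written to
#'   `<fasta_path>.sizes`.
#' @export
write_genome <- function(genome, fasta_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta_path,
                              width = 80)
  write_chrom_sizes(stats::setNames(nchar(genome), names(genome)),
                    paste0(fasta_path, ".sizes"))
  invisible(fasta_path)
}

#' Generate non-overlapping peaks with planted occupancy classes
#'
#' Peaks are laid out slot-wise along each allowed chromosome (guaranteeing
#' non-overlap), given a summit near the center, and assigned a class —
#' unresponsive, induced or reduced — with the stated fractions and true
#' fold changes. Optionally a handful of decoy peaks on the `NW` scaffold
#' exercise the chromosome filter; they carry counts but are not part of the
#' class fractions.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_peaks number of peaks on NC chromosomes (default 5000).
#' @param class_fractions named fractions summing to 1 (default 80%
#'   unresponsive, 10% induced, 10% reduced).
#' @param fc_by_class named true fold changes (default 1, 3, 1/3).
#' @param width_range min/max peak width (default 200-800 bp).
#' @param n_decoy decoy peaks on non-NC scaffolds (default 20).
#' @param seed integer seed.
#' @return list with `peaks` (an [interval_set()]) and `truth` (data frame
#'   `name`, `class`, `true_fc`, `decoy`).
#' @export
sim_peaks <- function(chrom_lengths, n_peaks = 5000,
                      class_fractions = c(unresponsive = 0.8, induced = 0.1,
                                          reduced = 0.1),
                      fc_by_class = c(unresponsive = 1, induced = 3,
                                      reduced = 1 / 3),
                      width_range = c(200, 800), n_decoy = 20, seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    nr_stop("class fractions must sum to 1")
  }
  if (any(fc_by_class <= 0)) nr_stop("fold changes must be > 0")
  set.seed(substream_seed(seed, "peaks"))
  nc <- grep("^NC", names(chrom_lengths), value = TRUE)
  if (!length(nc)) nr_stop("no NC chromosomes to place peaks on")
  # peaks per chromosome proportional to length
  alloc <- round(n_peaks * chrom_lengths[nc] / sum(chrom_lengths[nc]))
  alloc[length(alloc)] <- n_peaks - sum(alloc[-length(alloc)])
  place <- function(ch, k) {
    L <- chrom_lengths[[ch]]
    slot <- floor(L / k)
    if (slot < width_range[2] + 200) {
      nr_stop("peaks do not fit on %s (%d slots of %d bp)", ch, k, slot)
    }
    w <- sample(width_range[1]:width_range[2], k, replace = TRUE)
    off <- vapply(slot - w - 100, function(m) sample.int(m, 1) + 50L, 1L)
    start <- (seq_len(k) - 1) * slot + off
    summit <- start + floor(w * stats::runif(k, 0.35, 0.65))
    data.frame(chrom = ch, start = start, end = start + w, summit = summit)
  }
  df <- do.call(rbind, lapply(nc, function(ch) place(ch, alloc[[ch]])))
  cls <- sample(rep(names(class_fractions),
                    times = round(n_peaks * class_fractions))[seq_len(n_peaks)])
  decoy <- NULL
  if (n_decoy > 0) {
    other <- setdiff(names(chrom_lengths), nc)
    if (length(other)) {
      decoy <- place(other[1], n_decoy)
      df <- rbind(df, decoy)
      cls <- c(cls, rep("unresponsive", n_decoy))
    }
  }
  name <- sprintf("peak_%05d", seq_len(nrow(df)))
  peaks <- interval_set(df$chrom, df$start, df$end, name = name,
                        summit = df$summit)
  truth <- data.frame(name = name, class = cls,
                      true_fc = unname(fc_by_class[cls]),
                      decoy = !grepl("^NC", df$chrom),
                      stringsAsFactors = FALSE)
  truth <- truth[match(peaks$name, truth$name), ]
  rownames(truth) <- NULL
  list(peaks = peaks, truth = truth)
}

#' Simulate negative-binomial tag counts for peaks
#'
#' Control counts are NB with mean `nb_mean` and dispersion `nb_dispersion`
#' (variance `mu + dispersion * mu^2`; 0 degenerates to Poisson); treated
#' counts use `nb_mean * true_fc`. Per-sample means are additionally scaled
#' by `library_size / mean(library_size)` so sequencing depth acts the way
#' it does in real libraries.
#'
#' @param truth peak truth from [sim_peaks()].
#' @param nb_mean baseline mean count (default 200).
#' @param nb_dispersion NB dispersion (default 0.05).
#' @param n_replicates replicates per condition (default 2).
#' @param library_sizes per-sample library sizes, control replicates first
#'   (default around 20 million reads).
#' @param conditions condition names `(control, treated)`.
#' @param seed integer seed.
#' @return list with `counts` (matrix peaks x samples) and `samples` (sample
#'   sheet).
#' @export
sim_counts <- function(truth, nb_mean = 200, nb_dispersion = 0.05,
                       n_replicates = 2,
                       library_sizes = c(2.2e7, 1.8e7, 2.0e7, 2.1e7),
                       conditions = c("vehicle", "ligand"), seed = 1) {
  stopifnot(nb_mean > 0, nb_dispersion >= 0)
  n_samp <- 2 * n_replicates
  if (length(library_sizes) != n_samp) {
    nr_stop("need %d library sizes (got %d)", n_samp, length(library_sizes))
  }
  set.seed(substream_seed(seed, "counts"))
  samples <- data.frame(
    sample_id = paste0(rep(conditions, each = n_replicates), "_rep",
                       rep(seq_len(n_replicates), 2)),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    library_size = library_sizes, stringsAsFactors = FALSE)
  depth <- library_sizes / mean(library_sizes)
  n <- nrow(truth)
  counts <- matrix(0L, n, n_samp,
                   dimnames = list(truth$name, samples$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- nb_mean * depth[j] *
      (if (samples$condition[j] == conditions[2]) truth$true_fc else 1)
    counts[, j] <- if (nb_dispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = 1 / nb_dispersion, mu = mu)
    }
  }
  list(counts = counts, samples = samples)
}

#' Plant motif instances into peak sequences
#'
#' Writes the motif consensus (random strand) at a random offset inside a
#' fraction `rate_in_class` of the peaks of `target_class` and a fraction
#' `background_rate` of all other non-decoy peaks. Every planted coordinate
#' and strand is recorded. A peak receives at most one plant; offsets keep
#' the instance fully inside the peak.
#'
#' @param genome named character vector of chromosome sequences.
#' @param consensus motif consensus string (e.g. `pwm_consensus(dr_pwm(3))`).
#' @param peaks an [interval_set()].
#' @param truth peak truth from [sim_peaks()].
#' @param target_class class to enrich (default `"induced"`).
#' @param rate_in_class plant rate within the target class (default 0.7).
#' @param background_rate plant rate elsewhere (default 0.05).
#' @param seed integer seed.
#' @return list with `genome` (modified) and `planted` (data frame `name`,
#'   `chrom`, `start`, `end`, `strand`).
#' @export
plant_motifs <- function(genome, consensus, peaks, truth,
                         target_class = "induced", rate_in_class = 0.7,
                         background_rate = 0.05, seed = 1) {
  stopifnot(rate_in_class >= 0, rate_in_class <= 1,
            background_rate >= 0, background_rate <= 1)
  w <- nchar(consensus)
  if (any(peaks$end - peaks$start < w + 4)) {
    nr_stop("motif consensus does not fit inside the narrowest peak")
  }
  set.seed(substream_seed(seed, "motifs"))
  eligible <- !truth$decoy
  in_class <- eligible & truth$class == target_class
  pick <- function(idx, rate) {
    k <- round(length(idx) * rate)
    if (k == 0) integer(0) else sort(sample(idx, k))
  }
  chosen <- c(pick(which(in_class), rate_in_class),
              pick(which(eligible & !in_class), background_rate))
  chosen <- sort(chosen)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  planted <- data.frame(name = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  for (i in chosen) {
    room <- (peaks$end[i] - w) - peaks$start[i] - 2
    off <- sample.int(room, 1) + 1
    s0 <- peaks$start[i] + off                      # 0-based plant start
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") consensus else rc(consensus)
    ch <- peaks$chrom[i]
    substr(genome[[ch]], s0 + 1, s0 + w) <- ins
    planted <- rbind(planted, data.frame(
      name = peaks$name[i], chrom = ch, start = s0, end = s0 + w,
      strand = strand, stringsAsFactors = FALSE))
  }
  list(genome = genome, planted = planted)
}

#' Generate genes and a differential-expression table linked to peaks
#'
#' A fraction of genes is flagged upregulated (DE fold change > 1.5 and
#' FDR < 0.05 by construction); a fraction `frac_linked` of those is placed
#' so that an induced peak's summit lies within `link_window_bp` of the TSS.
#' Remaining genes are placed uniformly on the NC chromosomes with fold
#' changes near 1 and non-significant FDRs.
#'
#' @param peaks an [interval_set()].
#' @param truth peak truth from [sim_peaks()].
#' @param chrom_lengths named chromosome lengths.
#' @param n_genes total genes (default 400).
#' @param frac_upregulated fraction upregulated (default 0.15).
#' @param frac_linked fraction of upregulated genes placed near an induced
#'   peak (default 0.95).
#' @param link_window_bp TSS window used for linking (default 25000).
#' @param seed integer seed.
#' @return list with `genes` (TSS table: `gene_id`, `symbol`, `chrom`,
#'   `tss`, `strand`, `biotype`), `de` (DE table: `gene_id`, `fc`, `fdr`)
#'   and `truth` (data frame `gene_id`, `upregulated`, `linked_peak`).
#' @export
sim_genes <- function(peaks, truth, chrom_lengths, n_genes = 400,
                      frac_upregulated = 0.15, frac_linked = 0.95,
                      link_window_bp = 25000, seed = 1) {
  set.seed(substream_seed(seed, "genes"))
  nc <- grep("^NC", names(chrom_lengths), value = TRUE)
  induced <- which(truth$class == "induced" & !truth$decoy)
  n_up <- round(n_genes * frac_upregulated)
  if (n_up > 0 && !length(induced)) {
    nr_stop("no induced peaks available to link upregulated genes to")
  }
  n_link <- round(n_up * frac_linked)
  gene_id <- sprintf("GENE%04d", seq_len(n_genes))
  chrom <- character(n_genes); tss <- numeric(n_genes)
  linked_peak <- rep(NA_character_, n_genes)
  up <- c(rep(TRUE, n_up), rep(FALSE, n_genes - n_up))
  for (i in seq_len(n_genes)) {
    if (up[i] && i <= n_link) {
      p <- induced[sample.int(length(induced), 1)]
      ch <- peaks$chrom[p]
      lo <- max(peaks$summit[p] - (link_window_bp - 1000), 0)
      hi <- min(peaks$summit[p] + (link_window_bp - 1000),
                chrom_lengths[[ch]] - 1)
      chrom[i] <- ch
      tss[i] <- floor(stats::runif(1, lo, hi))
      linked_peak[i] <- peaks$name[p]
    } else {
      ch <- sample(nc, 1, prob = chrom_lengths[nc])
      chrom[i] <- ch
      tss[i] <- floor(stats::runif(1, 1000, chrom_lengths[[ch]] - 1000))
    }
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- rep("protein_coding", n_genes)
  nonup <- which(!up)
  k_other <- min(length(nonup), max(1, round(0.05 * n_genes)))
  biotype[sample(nonup, k_other)] <- "other"
  fc <- ifelse(up, 2^stats::runif(n_genes, log2(1.6), 3),
               2^stats::rnorm(n_genes, 0, 0.2))
  fdr <- ifelse(up, stats::runif(n_genes, 0, 0.049),
                stats::runif(n_genes, 0.05, 1))
  ord <- order(gene_id)
  list(genes = data.frame(gene_id = gene_id, symbol = gene_id, chrom = chrom,
                          tss = tss, strand = strand, biotype = biotype,
                          stringsAsFactors = FALSE)[ord, ],
       de = data.frame(gene_id = gene_id, fc = fc, fdr = fdr,
                       stringsAsFactors = FALSE)[ord, ],
       truth = data.frame(gene_id = gene_id, upregulated = up,
                          linked_peak = linked_peak,
                          stringsAsFactors = FALSE)[ord, ])
}

#' Simulate a complete synthetic ChIP-seq study
#'
#' Composes the generators into one seeded bundle — genome with planted
#' motifs, peaks with classes, NB counts, genes and expression — and a
#' ground-truth manifest. With `dir` given, all artifacts are written as
#' plain-text files (FASTA + sizes, narrowPeak, count/sample-sheet/TSS/DE
#' TSVs, truth JSON).
#'
#' @param seed master integer seed.
#' @param dir optional output directory.
#' @param chrom_lengths,gc see [sim_genome()].
#' @param n_peaks,class_fractions,fc_by_class,width_range,n_decoy see
#'   [sim_peaks()].
#' @param nb_mean,nb_dispersion,n_replicates,library_sizes see
#'   [sim_counts()].
#' @param motif_spacer direct-repeat spacer of the planted motif (default 3,
#'   the VDR-RXR-type element).
#' @param rate_in_class,background_rate see [plant_motifs()].
#' @param n_genes,frac_upregulated,frac_linked,link_window_bp see
#'   [sim_genes()].
#' @return a `synthetic_study` list: `genome`, `peaks`, `counts`, `samples`,
#'   `genes`, `de`, `pwm`, `truth` (peaks, planted motifs, genes, and the
#'   generator parameters), plus `files` when written.
#' @export
simulate_study <- function(seed = 1, dir = NULL,
                           chrom_lengths = c(NC_T1 = 5e6, NC_T2 = 5e6,
                                             NW_T1 = 5e4),
                           gc = 0.45, n_peaks = 5000,
                           class_fractions = c(unresponsive = 0.8,
                                               induced = 0.1, reduced = 0.1),
                           fc_by_class = c(unresponsive = 1, induced = 3,
                                           reduced = 1 / 3),
                           width_range = c(200, 800), n_decoy = 20,
                           nb_mean = 200, nb_dispersion = 0.05,
                           n_replicates = 2,
                           library_sizes = c(2.2e7, 1.8e7, 2.0e7, 2.1e7),
                           motif_spacer = 3, rate_in_class = 0.7,
                           background_rate = 0.05, n_genes = 400,
                           frac_upregulated = 0.15, frac_linked = 0.95,
                           link_window_bp = 25000) {
  genome <- sim_genome(chrom_lengths, gc, seed)
  pk <- sim_peaks(chrom_lengths, n_peaks, class_fractions, fc_by_class,
                  width_range, n_decoy, seed)
  cnt <- sim_counts(pk$truth, nb_mean, nb_dispersion, n_replicates,
                    library_sizes, seed = seed)
  motif <- dr_pwm(motif_spacer)
  pl <- plant_motifs(genome, pwm_consensus(motif), pk$peaks, pk$truth,
                     rate_in_class = rate_in_class,
                     background_rate = background_rate, seed = seed)
  gn <- sim_genes(pk$peaks, pk$truth, chrom_lengths, n_genes,
                  frac_upregulated, frac_linked, link_window_bp, seed)
  params <- list(seed = seed, chrom_lengths = as.list(chrom_lengths),
                 gc = gc, n_peaks = n_peaks,
                 class_fractions = as.list(class_fractions),
                 fc_by_class = as.list(fc_by_class),
                 width_range = width_range, n_decoy = n_decoy,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 n_replicates = n_replicates, library_sizes = library_sizes,
                 motif_spacer = motif_spacer, rate_in_class = rate_in_class,
                 background_rate = background_rate, n_genes = n_genes,
                 frac_upregulated = frac_upregulated,
                 frac_linked = frac_linked, link_window_bp = link_window_bp)
  study <- list(genome = pl$genome, peaks = pk$peaks, counts = cnt$counts,
                samples = cnt$samples, genes = gn$genes, de = gn$de,
                pwm = motif,
                truth = list(peaks = pk$truth, planted_motifs = pl$planted,
                             genes = gn$truth, params = params))
  class(study) <- "synthetic_study"
  if (!is.null(dir)) {
    study$files <- write_study(study, dir)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study (seed %s): %d peaks on %d chromosomes, %d samples, %d genes, %d planted motifs\n",
    x$truth$params$seed, nrow(x$peaks),
    length(x$truth$params$chrom_lengths), nrow(x$samples),
    nrow(x$genes), nrow(x$truth$planted_motifs)))
  invisible(x)
}

# write every artifact of a synthetic study as plain text
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- list(
    genome = file.path(dir, "genome.fa"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    tss = file.path(dir, "tss.tsv"),
    de = file.path(dir, "de.tsv"),
    pwm = file.path(dir, "motif.homer"),
    truth = file.path(dir, "truth.json"))
  write_genome(study$genome, f$genome)
  write_bed(study$peaks, f$peaks, format = "narrowPeak")
  write_count_table(study$counts, study$samples, f$counts, f$samples)
  utils::write.table(study$genes, f$tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$de, f$de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pwm(study$pwm, f$pwm)
  jsonlite::write_json(study$truth, f$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  f
}
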