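# PWM representation, log-odds scoring, size-matched background sampling,
# threshold calibration at a target empirical false-positive rate,
# genome-wide scanning, and motif prevalence/score summaries.
#
# Scores are base-2 log odds against a uniform background by default
# (genome-composition background selectable). A background sequence is a
# "positive match" when its best window score over both strands reaches the
# cutoff; the cutoff is the smallest score keeping the positive fraction of
# the control set at or below the target rate.

BASES <- c("A", "C", "G", "T")

# byte -> base code lookup (1..4, NA for anything else incl. N)
.base_lut <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 1L; v[utf8ToInt("a") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L; v[utf8ToInt("c") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L; v[utf8ToInt("g") + 1L] <- 3L
  v[utf8ToInt("T") + 1L] <- 4L; v[utf8ToInt("t") + 1L] <- 4L
  v
})

seq_codes <- function(s) .base_lut[as.integer(charToRaw(as.character(s))) + 1L]

#' Construct a position weight matrix
#'
#' @param matrix numeric width x 4 matrix of base probabilities or counts
#'   (columns A, C, G, T). Counts are converted to probabilities with a
#'   pseudocount of 0.25 per cell; probability rows are renormalized to sum
#'   to 1.
#' @param motif_id identifier.
#' @param dialect source dialect, `"homer"` or `"jaspar"`.
#' @return a `pwm` object (list with `motif_id`, `width`, `matrix`,
#'   `dialect`).
#' @export
pwm <- function(matrix, motif_id = "pwm", dialect = c("homer", "jaspar")) {
  dialect <- match.arg(dialect)
  m <- as.matrix(matrix)
  if (ncol(m) != 4) nr_stop("PWM matrix must have 4 columns (A, C, G, T)")
  if (nrow(m) < 4) nr_stop("PWM width must be >= 4")
  if (any(m < 0)) nr_stop("PWM entries must be non-negative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-3)) {           # counts: add pseudocount, normalize
    m <- m + 0.25
    rs <- rowSums(m)
  }
  m <- m / rs
  dimnames(m) <- list(NULL, BASES)
  structure(list(motif_id = motif_id, width = nrow(m), matrix = m,
                 dialect = dialect), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s), width %d, consensus %s\n",
              x$motif_id, x$dialect, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x a [pwm()].
#' @return a [pwm()] scoring the reverse strand of the same sites.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(x$width)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- BASES
  pwm(m, motif_id = paste0(x$motif_id, "_rc"), dialect = x$dialect)
}

#' Direct-repeat response-element PWM
#'
#' Two AGGTCA half sites separated by an uninformative spacer of
#' `spacer` bases (DR0-DR5 family; e.g. DR3 is the canonical VDR-RXR
#' element). The consensus-base probability varies along the half site
#' (`consensus_p`, recycled to 6 positions) the way real receptor half-site
#' logos do, and the remaining probability is split 3:2:1 over the other
#' bases in a position-rotated order — this keeps window log-odds scores
#' close to continuous instead of collapsing onto a handful of
#' match-count levels. Spacer positions are uniform.
#'
#' @param spacer spacer length in bases, 0-5.
#' @param consensus_p per-position consensus probabilities (default a
#'   typical high-information core profile).
#' @param motif_id identifier (default `DR<spacer>`).
#' @return a [pwm()].
#' @export
dr_pwm <- function(spacer = 3,
                   consensus_p = c(0.95, 0.93, 0.88, 0.82, 0.90, 0.85),
                   motif_id = NULL) {
  stopifnot(spacer >= 0, spacer <= 5,
            all(consensus_p > 0.25), all(consensus_p < 1))
  half <- strsplit("AGGTCA", "")[[1]]
  consensus_p <- rep_len(consensus_p, 6)
  halfm <- t(vapply(seq_along(half), function(j) {
    r <- numeric(4)
    others <- setdiff(seq_len(4), match(half[j], BASES))
    # rotate the 3:2:1 split with position for distinct off-base odds
    split3 <- c(3, 2, 1)[(seq_len(3) + j) %% 3 + 1] / 6
    r[others] <- (1 - consensus_p[j]) * split3
    r[match(half[j], BASES)] <- consensus_p[j]
    r
  }, numeric(4)))
  spm <- matrix(0.25, nrow = spacer, ncol = 4)
  pwm(rbind(halfm, spm, halfm),
      motif_id = motif_id %||% paste0("DR", spacer), dialect = "homer")
}

# ---- PWM file dialects ------------------------------------------------------

#' Read a PWM from HOMER `.motif` or JASPAR PFM text
#'
#' HOMER motifs have a `>consensus<TAB>name<TAB>...` header followed by one
#' probability row (A C G T) per position. JASPAR PFMs have a
#' `>ID NAME` header followed by four base rows (`A [ 1 2 3 ]` or bare
#' numbers), which are count matrices normalized on read.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"homer"` or `"jaspar"`.
#' @return a [pwm()] (the first motif in the file).
#' @export
read_pwm <- function(path, dialect = c("auto", "homer", "jaspar")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    nr_stop("%s: expected a '>' header line", path)
  }
  body <- lines[-1]
  body <- body[!startsWith(body, ">")]
  if (dialect == "auto") {
    dialect <- if (any(grepl("^[ACGT]\\s*\\[", body))) "jaspar"
    else if (length(body) == 4 && length(lines) > 1 &&
             length(strsplit(trimws(body[1]), "\\s+")[[1]]) != 4) "jaspar"
    else "homer"
  }
  header <- sub("^>", "", lines[1])
  id <- strsplit(header, "[\t ]+")[[1]][1]
  if (dialect == "homer") {
    rows <- lapply(body, function(l) {
      as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])
    })
    if (any(lengths(rows) != 4)) nr_stop("%s: non-rectangular HOMER matrix", path)
    m <- do.call(rbind, rows)
  } else {
    if (length(body) != 4) nr_stop("%s: JASPAR PFM needs 4 base rows", path)
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      nr_stop("%s: non-rectangular JASPAR matrix", path)
    }
    m <- t(do.call(rbind, rows))   # rows are A,C,G,T across positions
  }
  if (anyNA(m)) nr_stop("%s: non-numeric PWM entries", path)
  pwm(m, motif_id = id, dialect = dialect)
}

#' Write a PWM in HOMER or JASPAR text
#'
#' @param x a [pwm()].
#' @param path output path.
#' @param dialect `"homer"` (probability rows) or `"jaspar"`
#'   (per-base probability rows in brackets).
#' @export
write_pwm <- function(x, path, dialect = c("homer", "jaspar")) {
  dialect <- match.arg(dialect)
  if (dialect == "homer") {
    out <- c(sprintf(">%s\t%s\t0", pwm_consensus(x), x$motif_id),
             apply(x$matrix, 1, function(r)
               paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
                     collapse = "\t")))
  } else {
    out <- c(sprintf(">%s %s", x$motif_id, x$motif_id),
             vapply(seq_len(4), function(j)
               sprintf("%s [ %s ]", BASES[j],
                       paste(format(x$matrix[, j], digits = 15,
                                    scientific = FALSE, trim = TRUE),
                             collapse = " ")), ""))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- scoring ----------------------------------------------------------------

log_odds_matrix <- function(x, background = rep(0.25, 4)) {
  if (any(background <= 0)) nr_stop("background frequencies must be > 0")
  lo <- log2(x$matrix / rep(background, each = x$width))
  dimnames(lo) <- NULL
  lo
}

# score all windows of a code vector against a log-odds matrix; windows
# containing non-ACGT characters score -Inf (skipped)
window_scores_codes <- function(codes, lo) {
  w <- nrow(lo)
  nw <- length(codes) - w + 1L
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(w)) {
    sc <- sc + lo[j, ][codes[j:(j + nw - 1L)]]
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' Log-odds score of one sequence window
#'
#' `sum_i log2(p_i(base_i) / q(base_i))` for a window exactly as wide as the
#' PWM. Windows containing `N` score `-Inf` (skipped by scanning); any other
#' character is an error.
#'
#' @param seq_window character scalar of length `width`.
#' @param x a [pwm()].
#' @param background base frequencies (A, C, G, T), default uniform.
#' @return numeric score.
#' @export
log_odds_score <- function(seq_window, x, background = rep(0.25, 4)) {
  s <- toupper(seq_window)
  if (nchar(s) != x$width) nr_stop("window length != PWM width")
  if (grepl("[^ACGTN]", s)) nr_stop("invalid character in sequence window")
  window_scores_codes(seq_codes(s), log_odds_matrix(x, background))
}

#' Best window log-odds score per sequence
#'
#' The maximum window score over both strands for each sequence — the
#' statistic thresholded during calibration ("positive match" means this
#' score reaches the cutoff). Sequences shorter than the PWM score `-Inf`.
#'
#' @param seqs character vector of sequences (or a `DNAStringSet`).
#' @param x a [pwm()].
#' @param background base frequencies (A, C, G, T), default uniform.
#' @return numeric vector of best scores.
#' @export
score_sequences <- function(seqs, x, background = rep(0.25, 4)) {
  best_scores(seqs, x, background)
}

# per-sequence best window score over both strands
best_scores <- function(seqs, x, background = rep(0.25, 4)) {
  lo_f <- log_odds_matrix(x, background)
  lo_r <- log_odds_matrix(pwm_revcomp(x), background)
  vapply(as.character(seqs), function(s) {
    codes <- seq_codes(s)
    if (length(codes) < x$width) return(-Inf)
    max(window_scores_codes(codes, lo_f), window_scores_codes(codes, lo_r))
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- background sampling and calibration ------------------------------------

#' Sample size-matched random genomic background sequences
#'
#' Draws `n` sequences from the allowed chromosomes, with lengths sampled
#' with replacement from the query length distribution (size matching) and
#' positions uniform over the eligible starts of each chromosome.
#'
#' @param genome a named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or a FASTA path.
#' @param lengths integer vector: the query set's length distribution.
#' @param n number of sequences (default 5000).
#' @param allowed_chrom_pattern regex anchored at the chromosome-name start
#'   (default `"NC"`, complete-assembly sequences); `NULL` allows all.
#' @param seed integer seed; the sample is reproducible under it.
#' @return character vector of sequences named `chrom:start-end` (0-based
#'   half-open).
#' @export
sample_background <- function(genome, lengths, n = 5000,
                              allowed_chrom_pattern = "NC", seed = 1) {
  genome <- load_genome(genome)
  if (!is.null(allowed_chrom_pattern)) {
    keep <- grepl(paste0("^(", allowed_chrom_pattern, ")"), names(genome))
    genome <- genome[keep]
  }
  if (!length(genome)) nr_stop("no chromosomes match the allowed pattern")
  if (n < 1) nr_stop("n must be >= 1")
  chrlen <- nchar(genome)
  if (max(lengths) > max(chrlen)) {
    nr_stop("requested length %d exceeds longest chromosome (%d)",
            max(lengths), max(chrlen))
  }
  set.seed(seed)
  lengths <- as.integer(lengths)
  len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
  # chromosome chosen proportionally to eligible starts for each length
  out <- character(n)
  nm <- character(n)
  for (i in seq_len(n)) {
    ok <- chrlen >= len[i]
    w <- (chrlen - len[i] + 1) * ok
    ch <- sample(seq_along(genome), 1, prob = w)
    s0 <- sample.int(chrlen[ch] - len[i] + 1L, 1) - 1L   # 0-based start
    out[i] <- substr(genome[[ch]], s0 + 1, s0 + len[i])
    nm[i] <- sprintf("%s:%d-%d", names(genome)[ch], s0, s0 + len[i])
  }
  stats::setNames(out, nm)
}

# accept DNAStringSet / character / FASTA path, return named character vector
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    stats::setNames(as.character(g), names(g))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    nr_stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  }
}

#' Calibrate a PWM score threshold at a target empirical false-positive rate
#'
#' A control sequence is a positive match when its best window score over
#' both strands reaches the cutoff. The cutoff is the smallest observed best
#' score such that the fraction of positive control sequences is at or below
#' `target_fpr` — the empirical upper quantile of best scores, with ties
#' resolved toward the smaller positive fraction.
#'
#' @param x a [pwm()].
#' @param background_seqs character vector of control sequences (e.g. from
#'   [sample_background()]).
#' @param target_fpr target positive fraction (default 0.05).
#' @param background base frequencies for scoring (default uniform).
#' @param mode `"sequence"` (per-sequence best score, default) or `"window"`
#'   (pooled window-level scores).
#' @return a `score_threshold`: list with `motif_id`, `cutoff`, `target_fpr`,
#'   `achieved_fpr`, `background_n`, `mode`, `background`.
#' @export
calibrate_threshold <- function(x, background_seqs, target_fpr = 0.05,
                                background = rep(0.25, 4),
                                mode = c("sequence", "window")) {
  mode <- match.arg(mode)
  if (!length(background_seqs)) nr_stop("background set is empty")
  if (target_fpr <= 0 || target_fpr > 1) nr_stop("target_fpr must be in (0, 1]")
  if (mode == "sequence") {
    sc <- best_scores(background_seqs, x, background)
  } else {
    lo_f <- log_odds_matrix(x, background)
    lo_r <- log_odds_matrix(pwm_revcomp(x), background)
    sc <- unlist(lapply(as.character(background_seqs), function(s) {
      codes <- seq_codes(s)
      pmax(window_scores_codes(codes, lo_f), window_scores_codes(codes, lo_r))
    }), use.names = FALSE)
  }
  sc <- sc[is.finite(sc)]
  cand <- sort(unique(sc))
  if (length(cand) < 2) nr_stop("non-calibratable: degenerate score distribution")
  # fraction >= c for each candidate cutoff c (cand ascending)
  frac <- (length(sc) - findInterval(cand - 1e-12, sort(sc))) / length(sc)
  ok <- which(frac <= target_fpr)
  if (!length(ok)) nr_stop("non-calibratable: no cutoff reaches target_fpr")
  cutoff <- cand[ok[1]]
  structure(list(motif_id = x$motif_id, cutoff = cutoff,
                 target_fpr = target_fpr, achieved_fpr = frac[ok[1]],
                 background_n = length(background_seqs), mode = mode,
                 background = background),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("score_threshold for %s: cutoff %.4f (target FPR %.3f, achieved %.4f, n = %d, %s-level)\n",
              x$motif_id, x$cutoff, x$target_fpr, x$achieved_fpr,
              x$background_n, x$mode))
  invisible(x)
}

#' Scan sequences or a genome for motif hits above a threshold
#'
#' All windows on both strands with log-odds score at or above the cutoff.
#' Coordinates are 0-based half-open on the forward strand; reverse-strand
#' hits refer to the forward-strand interval they occupy.
#'
#' @param genome genome as in [sample_background()].
#' @param x a [pwm()].
#' @param threshold a [calibrate_threshold()] result or a numeric cutoff.
#' @param background base frequencies; taken from the threshold object when
#'   one is supplied.
#' @return `motif_hits` data frame: `chrom`, `start`, `end`, `strand`,
#'   `score`, sorted by (chrom, start).
#' @export
scan_motif <- function(genome, x, threshold, background = NULL) {
  genome <- load_genome(genome)
  if (inherits(threshold, "score_threshold")) {
    if (is.null(background)) background <- threshold$background
    cutoff <- threshold$cutoff
  } else {
    cutoff <- as.numeric(threshold)
  }
  if (is.null(background)) background <- rep(0.25, 4)
  lo_f <- log_odds_matrix(x, background)
  lo_r <- log_odds_matrix(pwm_revcomp(x), background)
  res <- list()
  for (ch in names(genome)) {
    codes <- seq_codes(genome[[ch]])
    for (strand in c("+", "-")) {
      sc <- window_scores_codes(codes, if (strand == "+") lo_f else lo_r)
      hit <- which(sc >= cutoff)
      if (length(hit)) {
        res[[length(res) + 1]] <- data.frame(
          chrom = ch, start = hit - 1, end = hit - 1 + x$width,
          strand = strand, score = sc[hit], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), score = numeric())
  out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Fraction of peaks containing a motif hit
#'
#' @param peaks non-empty [interval_set()].
#' @param hits `motif_hits` (or any interval data frame); a peak counts when
#'   it overlaps at least one hit by >= 1 bp.
#' @return fraction in `[0, 1]`.
#' @export
motif_prevalence <- function(peaks, hits) {
  peaks <- as_interval_set(peaks)
  if (nrow(peaks) == 0) nr_stop("empty peak set")
  if (is.null(hits) || nrow(hits) == 0) {
    warning("empty hit set; prevalence 0")
    return(0)
  }
  h <- interval_set(hits$chrom, hits$start, hits$end)
  mean(iset_overlaps_any(iset_to_granges(peaks), iset_to_granges(h)))
}

#' Best motif score per peak
#'
#' Maximum window log-odds score over both strands inside each peak, e.g.
#' for comparing motif strength between induced and unresponsive peak sets
#' (two-sided unpaired t test downstream). Peaks shorter than the PWM get
#' `NA` and a warning.
#'
#' @param peaks an [interval_set()].
#' @param x a [pwm()].
#' @param genome genome as in [sample_background()].
#' @param background base frequencies (default uniform).
#' @return numeric vector named by peak.
#' @export
peak_best_motif_score <- function(peaks, x, genome,
                                  background = rep(0.25, 4)) {
  peaks <- as_interval_set(peaks)
  genome <- load_genome(genome)
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1, peaks$end[i])
  }, "")
  sc <- best_scores(seqs, x, background)
  short <- (peaks$end - peaks$start) < x$width
  if (any(short)) {
    warning(sprintf("%d peak(s) shorter than the PWM; score undefined", sum(short)))
    sc[short] <- NA_real_
  }
  stats::setNames(sc, peaks$name)
}
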