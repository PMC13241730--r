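# Per-region differential-occupancy statistics and peak classification:
# fold-change-only "exploratory" sets, FC + FDR significant sets, and the
# FC-pass significant / non-significant split.
#
# The test is an in-package negative-binomial exact-style test with a
# moderated (common + tagwise) dispersion; numerical parity with external
# differential-binding tools is not claimed — the classification thresholds
# are the primary surface and are applied exactly as printed.

#' Construct a count table for differential-occupancy testing
#'
#' @param regions an [interval_set()].
#' @param samples sample sheet with `sample_id`, `condition`, `replicate`,
#'   `library_size`.
#' @param counts integer matrix, regions x samples.
#' @return a `count_table` object.
#' @export
count_table <- function(regions, samples, counts) {
  regions <- as_interval_set(regions)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions) || ncol(counts) != nrow(samples)) {
    nr_stop("count dimensions do not match regions x samples")
  }
  if (any(counts < 0)) nr_stop("counts must be non-negative")
  rownames(counts) <- regions$name
  colnames(counts) <- samples$sample_id
  structure(list(regions = regions, samples = samples, counts = counts),
            class = "count_table")
}

#' Scale counts to a common library size
#'
#' Each sample's counts are multiplied by `mean(library_size) / library_size`
#' so that all columns are on the scale of the mean sequencing depth. Scaling
#' factors are attached as attribute `scale_factors`.
#'
#' @param t a [count_table()].
#' @return the scaled `count_table` (values no longer integer).
#' @export
normalize_libsize <- function(t) {
  stopifnot(inherits(t, "count_table"))
  lib <- t$samples$library_size
  if (any(lib <= 0)) nr_stop("library sizes must be > 0")
  f <- mean(lib) / lib
  out <- t
  out$counts <- sweep(t$counts, 2, f, "*")
  attr(out, "scale_factors") <- stats::setNames(f, t$samples$sample_id)
  out
}

#' Per-region fold change between two conditions
#'
#' `fc = (mean(treated) + pc) / (mean(control) + pc)` over the (normalized)
#' counts of each region.
#'
#' @param t a [count_table()] (normally after [normalize_libsize()]).
#' @param treated,control condition names.
#' @param pseudocount count pseudocount (default 0.5).
#' @return numeric vector of fold changes named by region.
#' @export
fold_change <- function(t, treated, control, pseudocount = 0.5) {
  stopifnot(inherits(t, "count_table"))
  cond <- t$samples$condition
  mt <- rowMeans(t$counts[, cond == treated, drop = FALSE])
  mc <- rowMeans(t$counts[, cond == control, drop = FALSE])
  (mt + pseudocount) / (mc + pseudocount)
}

# Method-of-moments dispersion with variance mu + alpha * mu^2.
# Per-region moment contributions are pooled across conditions (weighted by
# within-condition degrees of freedom). The common dispersion is the
# ratio-of-sums estimator sum(v - m) / sum(m^2) across regions — consistent,
# unlike a median of the per-region ratios, whose heavy skew at 1-2 residual
# df biases it low. Tagwise values shrink the per-region ratio toward the
# common value with `prior_df` pseudo-degrees of freedom and are floored to
# avoid degenerate Poisson fits.
estimate_dispersion <- function(counts, cond, prior_df = 20, floor = 1e-4) {
  conds <- unique(cond)
  num <- numeric(nrow(counts))
  den <- numeric(nrow(counts))
  adj1 <- numeric(nrow(counts))   # E[m^2] = mu^2 + (mu + a mu^2)/n bias terms
  adj2 <- numeric(nrow(counts))
  df <- 0
  for (cc in conds) {
    y <- counts[, cond == cc, drop = FALSE]
    n <- ncol(y)
    if (n < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    w <- n - 1
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - m[ok])
    den[ok] <- den[ok] + w * m[ok]^2
    adj1[ok] <- adj1[ok] + w * m[ok] / n
    adj2[ok] <- adj2[ok] + w * m[ok]^2 / n
    df <- df + w
  }
  if (df == 0) nr_stop("dispersion estimation needs >= 2 replicates in >= 1 condition")
  # debiased ratio-of-sums: solve a = N / (D - S1 - a * S2) by fixed point
  common <- sum(num) / sum(den)
  for (it in 1:3) {
    common <- sum(num) / max(sum(den) - sum(adj1) - common * sum(adj2),
                             sum(den) / 2)
  }
  common <- max(common, floor)
  raw <- ifelse(den > 0, pmax(num / pmax(den - adj1 - common * adj2,
                                         den / 2), 0), common)
  tag <- (prior_df * common + df * raw) / (prior_df + df)
  list(common = common, tagwise = pmax(tag, floor), residual_df = df)
}

# Exact-style two-sided NB test for one region: condition on the total of the
# two group sums and accumulate the probability of outcomes no more likely
# than the observed split (the "small p-values" two-sided rule).
exact_nb_p <- function(yt, yc, nt, nc, disp) {
  s <- yt + yc
  if (s == 0) return(1)
  mu <- s / (nt + nc)
  a <- 0:s
  lp <- stats::dnbinom(a, size = nt / disp, mu = nt * mu, log = TRUE) +
    stats::dnbinom(s - a, size = nc / disp, mu = nc * mu, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  min(1, sum(p[p <= p[yt + 1] * (1 + 1e-8)]))
}

#' Negative-binomial exact-style test per region
#'
#' Library-size-normalized counts are summed within each condition and the
#' split of the two sums is tested conditionally under a negative-binomial
#' model with moderated common + tagwise dispersion (method-of-moments common
#' dispersion, tagwise values shrunk toward it; dispersion floored at
#' `dispersion_floor`). Two-sided p-values are Benjamini-Hochberg adjusted
#' over all tested regions. Regions with zero counts everywhere get `p = 1`
#' by convention and are flagged.
#'
#' @param t a [count_table()] of raw counts.
#' @param treated,control condition names.
#' @param prior_df prior degrees of freedom for dispersion shrinkage
#'   (default 20).
#' @param dispersion_floor lower bound on the dispersion (default 1e-4).
#' @return data frame with columns `region`, `p_value`, `fdr`, `all_zero`;
#'   dispersion estimates attached as attribute `dispersion`.
#' @export
test_regions <- function(t, treated, control, prior_df = 20,
                         dispersion_floor = 1e-4) {
  stopifnot(inherits(t, "count_table"))
  keep <- t$samples$condition %in% c(treated, control)
  sub <- count_table(t$regions, t$samples[keep, , drop = FALSE],
                     t$counts[, keep, drop = FALSE])
  norm <- normalize_libsize(sub)
  cond <- norm$samples$condition
  disp <- estimate_dispersion(norm$counts, cond, prior_df, dispersion_floor)
  nt <- sum(cond == treated)
  nc <- sum(cond == control)
  yt <- round(rowSums(norm$counts[, cond == treated, drop = FALSE]))
  yc <- round(rowSums(norm$counts[, cond == control, drop = FALSE]))
  p <- vapply(seq_along(yt), function(i) {
    exact_nb_p(yt[i], yc[i], nt, nc, disp$tagwise[i])
  }, numeric(1))
  all_zero <- (yt + yc) == 0
  p[all_zero] <- 1
  out <- data.frame(region = sub$regions$name, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    all_zero = all_zero, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- disp
  out
}

#' Classify peaks by fold change alone (exploratory sets)
#'
#' Strict inequalities exactly as printed: induced iff `fc > up_cut`, reduced
#' iff `fc < down_cut`, otherwise unresponsive.
#'
#' @param fc fold-change vector.
#' @param up_cut,down_cut cutoffs with `0 < down_cut < 1 < up_cut`
#'   (defaults 1.5 and 0.66).
#' @return factor with levels induced, reduced, unresponsive.
#' @export
classify_fc_only <- function(fc, up_cut = 1.5, down_cut = 0.66) {
  if (!(down_cut > 0 && down_cut < 1 && up_cut > 1)) {
    nr_stop("cutoffs must satisfy 0 < down_cut < 1 < up_cut")
  }
  cls <- rep("unresponsive", length(fc))
  cls[fc > up_cut] <- "induced"
  cls[fc < down_cut] <- "reduced"
  factor(cls, levels = c("induced", "reduced", "unresponsive"))
}

#' Classify peaks by fold change plus FDR, with the FC-pass split
#'
#' Significant classes require both gates: induced iff `fc > up_cut` and
#' `fdr < fdr_cut`; reduced iff `fc < down_cut` and `fdr < fdr_cut`. Peaks
#' passing the FC gate are additionally split into
#' `fc_pass_significant` (`fdr < fdr_cut`) and `fc_pass_nonsignificant`
#' (`fdr >= fdr_cut`); peaks failing both FC gates get subset `none`.
#'
#' @param fc,fdr aligned vectors.
#' @param up_cut,down_cut,fdr_cut thresholds (defaults 1.5, 0.66, 0.05).
#' @return data frame with factors `class` and `subset`.
#' @export
classify_fc_fdr <- function(fc, fdr, up_cut = 1.5, down_cut = 0.66,
                            fdr_cut = 0.05) {
  stopifnot(length(fc) == length(fdr))
  sig <- fdr < fdr_cut
  cls <- rep("unresponsive", length(fc))
  cls[fc > up_cut & sig] <- "induced"
  cls[fc < down_cut & sig] <- "reduced"
  fc_pass <- fc > up_cut | fc < down_cut
  sub <- rep("none", length(fc))
  sub[fc_pass & sig] <- "fc_pass_significant"
  sub[fc_pass & !sig] <- "fc_pass_nonsignificant"
  data.frame(
    class = factor(cls, levels = c("induced", "reduced", "unresponsive")),
    subset = factor(sub, levels = c("fc_pass_significant",
                                    "fc_pass_nonsignificant", "none")))
}

#' Full differential-occupancy result for one contrast
#'
#' Runs normalization, fold change, the NB exact-style test and both
#' classification modes, returning the per-region result table.
#'
#' @param t a [count_table()] of raw counts.
#' @param treated,control condition names.
#' @param up_cut,down_cut,fdr_cut classification thresholds.
#' @param pseudocount count pseudocount for the fold change (default 0.5).
#' @return data frame with `region`, `fc`, `log2fc`, `p_value`, `fdr`,
#'   `class_fc_only`, `class_fc_fdr`, `subset`.
#' @export
diff_occupancy <- function(t, treated, control, up_cut = 1.5,
                           down_cut = 0.66, fdr_cut = 0.05,
                           pseudocount = 0.5) {
  norm <- normalize_libsize(t)
  fc <- fold_change(norm, treated, control, pseudocount)
  tst <- test_regions(t, treated, control)
  cf <- classify_fc_fdr(fc, tst$fdr, up_cut, down_cut, fdr_cut)
  data.frame(region = tst$region, fc = fc, log2fc = log2(fc),
             p_value = tst$p_value, fdr = tst$fdr,
             class_fc_only = classify_fc_only(fc, up_cut, down_cut),
             class_fc_fdr = cf$class, subset = cf$subset,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fractions of regions induced or reduced by a ratio criterion
#'
#' For combined-versus-single treatment comparisons: the fraction of regions
#' with per-region signal ratio above `up` (induced) and below `down`
#' (reduced), strict inequalities.
#'
#' @param ratios non-empty vector of per-region ratios.
#' @param up,down cutoffs (defaults 1.5 and 0.66).
#' @return named numeric vector `c(induced = ..., reduced = ...)`.
#' @export
combined_vs_single_proportions <- function(ratios, up = 1.5, down = 0.66) {
  if (length(ratios) == 0) nr_stop("empty ratio vector")
  c(induced = mean(ratios > up), reduced = mean(ratios < down))
}
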