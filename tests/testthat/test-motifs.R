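test_that("PWM construction normalizes rows and validates shape", {
  m <- matrix(0.25, 6, 4)
  p <- pwm(m, "uniform")
  expect_equal(rowSums(p$matrix), rep(1, 6))
  expect_error(pwm(matrix(0.25, 6, 3)), "4 columns")
  expect_error(pwm(matrix(0.25, 3, 4)), "width")
  # count input gets the 0.25 pseudocount then normalization
  cm <- matrix(c(10, 0, 0, 0), 4, 4, byrow = TRUE)
  pc <- pwm(cm)
  expect_equal(unname(pc$matrix[1, ]), c(10.25, 0.25, 0.25, 0.25) / 11)
})

test_that("HOMER and JASPAR dialects round-trip to 1e-9", {
  x <- dr_pwm(3)
  fh <- tempfile(fileext = ".motif")
  fj <- tempfile(fileext = ".pfm")
  write_pwm(x, fh, "homer")
  write_pwm(x, fj, "jaspar")
  expect_equal(read_pwm(fh)$matrix, x$matrix, tolerance = 1e-9)
  expect_equal(read_pwm(fj)$matrix, x$matrix, tolerance = 1e-9)
  expect_equal(read_pwm(fj, dialect = "jaspar")$dialect, "jaspar")

  # JASPAR count matrix is normalized per position
  f <- tempfile()
  writeLines(c(">MA0000.1 TOY",
               "A [ 10  0  5  5 ]",
               "C [  0 10  5  0 ]",
               "G [  0  0  0  5 ]",
               "T [  0  0  0  0 ]"), f)
  p <- read_pwm(f)
  expect_equal(p$width, 4)
  expect_equal(rowSums(p$matrix), rep(1, 4))
  expect_equal(unname(p$matrix[1, 1]), 10.25 / 11)

  bad <- tempfile()
  writeLines(c(">x", "0.25 0.25 0.25", "0.25 0.25 0.25 0.25",
               "0.25 0.25 0.25 0.25", "0.3 0.3 0.2 0.2"), bad)
  expect_error(read_pwm(bad, dialect = "homer"), "non-rectangular")
})

test_that("log-odds scoring matches direct summation and its identities", {
  u <- pwm(matrix(0.25, 5, 4))
  expect_equal(log_odds_score("ACGTA", u), 0)   # uniform vs uniform
  expect_equal(log_odds_score("GGGGG", u), 0)

  x <- dr_pwm(2)
  cons <- pwm_consensus(x)
  set.seed(4)
  for (i in 1:20) {
    win <- random_dna(x$width)
    direct <- sum(vapply(seq_len(x$width), function(k) {
      log2(x$matrix[k, match(substr(win, k, k), c("A", "C", "G", "T"))] / 0.25)
    }, numeric(1)))
    expect_equal(log_odds_score(win, x), direct)
    expect_lte(log_odds_score(win, x), log_odds_score(cons, x))
  }
  expect_identical(log_odds_score(paste0("N", substr(cons, 2, x$width)), x),
                   -Inf)
  expect_error(log_odds_score(gsub("A", "X", cons), x), "invalid character")
})

test_that("background sampling is size-matched, seeded and composition-faithful", {
  g <- sim_genome(c(NC_1 = 40000, NC_2 = 40000), gc = 0.6, seed = 1)
  lens <- c(200L, 300L, 400L)
  bg <- sample_background(g, lens, n = 300, allowed_chrom_pattern = "NC",
                          seed = 5)
  expect_true(all(nchar(bg) %in% lens))
  expect_identical(sample_background(g, lens, 300, seed = 5), bg)
  expect_false(identical(sample_background(g, lens, 300, seed = 6), bg))

  # all sequences of one length when only one length is offered
  expect_true(all(nchar(sample_background(g, 250L, 50, seed = 2)) == 250))

  # GC within 3 sigma of binomial error on a 60% GC genome
  n_b <- sum(nchar(bg))
  gc_obs <- sum(vapply(bg, function(s)
    lengths(regmatches(s, gregexpr("[GC]", s))), 1)) / n_b
  expect_lt(abs(gc_obs - 0.6), 3 * sqrt(0.6 * 0.4 / n_b) + 0.01)

  expect_error(sample_background(g, 1e6, 5, seed = 1), "exceeds")
})

test_that("threshold calibration hits the target rate tightly", {
  g <- sim_genome(c(NC_1 = 3e5), gc = 0.45, seed = 9)
  x <- dr_pwm(3)
  bg <- sample_background(g, sample(200:500, 400, replace = TRUE), n = 400,
                          seed = 13)
  thr <- calibrate_threshold(x, bg, target_fpr = 0.05)

  # oracle best scores via the naive scanner
  best <- vapply(bg, function(s) {
    sc <- oracle_scan(s, x$matrix)
    max(sc$fwd, sc$rev)
  }, numeric(1))
  frac_at <- function(cut) mean(best >= cut)
  expect_lte(frac_at(thr$cutoff), 0.05)
  # tightness: the next smaller observed best score violates the target
  smaller <- max(best[best < thr$cutoff])
  expect_gt(frac_at(smaller), 0.05)
  expect_equal(thr$achieved_fpr, frac_at(thr$cutoff))

  # boundary: target 1 accepts everything
  thr1 <- calibrate_threshold(x, bg, target_fpr = 1)
  expect_equal(thr1$cutoff, min(best))
  expect_error(calibrate_threshold(x, rep("ACGTACGTACGTACGTACG", 5), 0.05),
               "non-calibratable")
})

test_that("scanning equals a naive per-window rescan and is strand-symmetric", {
  set.seed(17)
  x <- dr_pwm(1)
  seq1 <- random_dna(3000)
  cons <- pwm_consensus(x)
  substr(seq1, 1501, 1500 + x$width) <- cons
  g <- c(NC_A = seq1)
  oracle <- oracle_scan(seq1, x$matrix)
  cut <- sort(c(oracle$fwd, oracle$rev), decreasing = TRUE)[25]
  hits <- scan_motif(g, x, cut)
  want_f <- oracle$pos[oracle$fwd >= cut]
  want_r <- oracle$pos[oracle$rev >= cut]
  expect_setequal(hits$start[hits$strand == "+"], want_f)
  expect_setequal(hits$start[hits$strand == "-"], want_r)
  expect_true(1500 %in% hits$start)   # the planted consensus
  expect_equal(hits$score[hits$strand == "+"][match(1500, sort(want_f))],
               log_odds_score(cons, x))

  # cutoff above the maximum achievable score finds nothing
  expect_equal(nrow(scan_motif(g, x, log_odds_score(cons, x) + 1)), 0)

  # palindromic PWM: hits are paired on both strands at the same interval
  pal <- pwm(rbind(c(0.9, 0.04, 0.03, 0.03), c(0.03, 0.9, 0.04, 0.03),
                   c(0.03, 0.04, 0.9, 0.03), c(0.03, 0.03, 0.04, 0.9)))
  hp <- scan_motif(g, pal, 4)
  fw <- hp[hp$strand == "+", c("start", "score")]
  rv <- hp[hp$strand == "-", c("start", "score")]
  expect_equal(fw$start, rv$start)
  expect_equal(fw$score, rv$score)

  # mirrored hits on the reverse-complemented genome
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq1, "")[[1]]), collapse = ""))
  hits_rc <- scan_motif(c(NC_A = rc), x, cut)
  expect_setequal(3000 - x$width - hits_rc$start[hits_rc$strand == "-"], want_f)
  expect_setequal(3000 - x$width - hits_rc$start[hits_rc$strand == "+"], want_r)
})

test_that("prevalence counts peaks containing hits", {
  peaks <- interval_set(rep("NC_A", 4), c(0, 100, 200, 300),
                        c(50, 150, 250, 350))
  hits <- data.frame(chrom = "NC_A", start = c(10, 110, 210, 310),
                     end = c(25, 125, 225, 325))
  expect_equal(motif_prevalence(peaks, hits), 1)
  expect_warning(p0 <- motif_prevalence(peaks, hits[0, ]), "empty hit")
  expect_equal(p0, 0)
  expect_error(motif_prevalence(peaks[0, ], hits), "empty peak")

  set.seed(23)
  for (i in 1:10) {
    pk <- random_iset(15, "NC_A", 5000)
    ht <- random_iset(8, "NC_A", 5000, max_width = 20)
    expect_equal(motif_prevalence(pk, as.data.frame(ht)),
                 mean(oracle_overlap_hits(pk, ht)))
  }
})

test_that("per-peak best scores recover the planted consensus score", {
  x <- dr_pwm(4)
  set.seed(31)
  s <- random_dna(2000)
  cons <- pwm_consensus(x)
  substr(s, 501, 500 + x$width) <- cons
  g <- c(NC_A = s)
  peaks <- interval_set(rep("NC_A", 3), c(400, 400, 1500), c(700, 700, 1510),
                        name = c("with", "with2", "short"))
  expect_warning(sc <- peak_best_motif_score(peaks, x, g), "shorter")
  expect_equal(unname(sc["with"]), log_odds_score(cons, x))
  expect_equal(sc[["with"]], sc[["with2"]])   # identical peaks, equal scores
  expect_true(is.na(sc[["short"]]))

  # oracle agreement on random peaks
  pk <- interval_set(rep("NC_A", 4), c(0, 700, 1200, 1600),
                     c(250, 1000, 1500, 1900))
  sc2 <- peak_best_motif_score(pk, x, g)
  for (i in seq_len(nrow(pk))) {
    sub <- substr(s, pk$start[i] + 1, pk$end[i])
    o <- oracle_scan(sub, x$matrix)
    expect_equal(unname(sc2[i]), max(o$fwd, o$rev))
  }
})
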