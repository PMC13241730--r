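make_tags <- function(pos, chrom = "chr1", total = 1e6, cond = "vehicle",
                      id = "s1", rep = 1L) {
  pl <- split(pos, rep(chrom, length(pos)))
  tag_library(id, cond, rep, placements = pl, total_mapped = total)
}

test_that("count_in_regions is half-open and matches a linear-scan oracle", {
  tg <- make_tags(c(105, 110, 200))
  r <- interval_set("chr1", 100, 200)
  expect_equal(unname(count_in_regions(tg, r)), 2)  # 200 excluded (half-open)

  r2 <- interval_set("chr2", 0, 1000)
  expect_equal(unname(count_in_regions(tg, r2)), 0) # absent chromosome

  set.seed(11)
  for (rep in 1:10) {
    pos <- sort(sample.int(5000, 300, replace = TRUE)) - 1
    tg <- make_tags(pos)
    regions <- random_iset(20, "chr1", 5000)
    oracle <- vapply(seq_len(nrow(regions)), function(i) {
      sum(pos >= regions$start[i] & pos < regions$end[i])
    }, numeric(1))
    expect_equal(unname(count_in_regions(tg, regions)), oracle)
  }
})

test_that("rpkm matches its closed form and scales linearly", {
  expect_identical(rpkm(10, 1000, 1e6), 10)
  expect_identical(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(7, 350, 2.5e6), 8)   # 7 / (0.35 * 2.5)
  expect_equal(rpkm(20, 1000, 1e6), 2 * rpkm(10, 1000, 1e6))
  expect_equal(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6) / 2)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
  expect_error(rpkm(10, 1000, 0), "total_mapped")
})

test_that("summit windows equal explicit intervals and truncate at 0", {
  set.seed(2)
  pos <- sort(sample.int(20000, 2000, replace = TRUE)) - 1
  tg <- make_tags(pos, total = 2e6)
  summits <- data.frame(chrom = "chr1", summit = c(5000, 9000))
  got <- summit_window_signal(tg, summits, half_width_bp = 750)
  explicit <- interval_set("chr1", summits$summit - 750, summits$summit + 750)
  want <- rpkm(count_in_regions(tg, explicit), 1500, 2e6)
  expect_equal(got, unname(want))

  # summit close to the chromosome start: window clipped at 0
  near0 <- data.frame(chrom = "chr1", summit = 100)
  g2 <- summit_window_signal(tg, near0, half_width_bp = 750)
  clip <- rpkm(count_in_regions(tg, interval_set("chr1", 0, 850)), 850, 2e6)
  expect_equal(g2, unname(clip))
})

test_that("read_distribution conserves window totals and localizes signal", {
  tg <- make_tags(5000, total = 1e6)          # single tag exactly at a summit
  summits <- data.frame(chrom = "chr1", summit = 5000)
  rd <- read_distribution(list(tg), summits, half_width_bp = 1000,
                          bin_bp = 100, value = "count")
  m <- rd$matrices[[1]]
  expect_equal(sum(m), 1)
  expect_equal(unname(which(m[1, ] > 0)), 11)  # first bin right of center

  set.seed(3)
  pos <- sort(sample.int(30000, 5000, replace = TRUE)) - 1
  tg <- make_tags(pos, total = 2e6)
  summits <- data.frame(chrom = "chr1", summit = c(4000, 12000, 21000))
  rd <- read_distribution(list(tg), summits, half_width_bp = 1000, bin_bp = 50,
                          value = "count")
  win <- interval_set("chr1", summits$summit - 1000, summits$summit + 1000)
  expect_equal(unname(rowSums(rd$matrices[[1]])),
               unname(count_in_regions(tg, win)))
  # per-bin counting oracle
  oracle_bin <- vapply(0:39, function(b) {
    lo <- summits$summit[2] - 1000 + b * 50
    sum(pos >= lo & pos < lo + 50)
  }, numeric(1))
  expect_equal(unname(rd$matrices[[1]][2, ]), oracle_bin)
})

sheet <- function(libs, conds) {
  data.frame(sample_id = paste0("s", seq_along(libs)), condition = conds,
             replicate = stats::ave(seq_along(libs), conds, FUN = seq_along),
             library_size = libs)
}

test_that("replicate_average averages within conditions", {
  reg <- interval_set("chr1", c(0, 100), c(50, 200))
  m <- signal_matrix(reg, sheet(c(1e6, 1e6, 1e6), c("v", "v", "l")),
                     cbind(c(2, 10), c(4, 20), c(6, 30)))
  avg <- replicate_average(m)
  expect_equal(unname(avg$values[, "v"]), c(3, 15))
  expect_equal(unname(avg$values[, "l"]), c(6, 30))
  single <- replicate_average(signal_matrix(reg, sheet(1e6, "v"),
                                            cbind(c(1, 2))))
  expect_equal(unname(single$values[, 1]), c(1, 2))
})

test_that("signal_ratio has exact closed forms and scale invariance", {
  reg <- interval_set("chr1", 100 * (0:99), 100 * (0:99) + 50)
  set.seed(9)
  v <- exp(rnorm(100, 2, 0.5))
  m_id <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")), cbind(v, v))
  rs <- signal_ratio(m_id, "l", "v")
  expect_identical(rs$global_ratio, 1)
  expect_true(all(rs$per_region_ratio == 1))

  m2 <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")), cbind(v, 2 * v))
  expect_equal(signal_ratio(m2, "l", "v")$global_ratio, 2)

  # common positive scaling leaves the ratio unchanged
  m3 <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")),
                      cbind(7.3 * v, 7.3 * 2 * v))
  expect_equal(signal_ratio(m3, "l", "v")$global_ratio, 2)
})

test_that("signal_ratio matches a naive sort-based median oracle", {
  naive_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  reg <- interval_set("chr1", 100 * (0:999), 100 * (0:999) + 50)
  set.seed(21)
  v <- exp(rnorm(1000, 1, 0.8))
  l <- exp(rnorm(1000, 1.2, 0.8))
  m <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")), cbind(v, l))
  rs <- signal_ratio(m, "l", "v", pseudocount = 0.1)
  expect_equal(rs$global_ratio, naive_median(l) / naive_median(v))
  expect_equal(unname(rs$per_region_ratio), (l + 0.1) / (v + 0.1))
  rs2 <- signal_ratio(m, "l", "v", method = "median_of_ratios")
  expect_equal(rs2$global_ratio, naive_median((l + 0.1) / (v + 0.1)))
})

test_that("global ratio is near 1 under an i.i.d. null count model", {
  reg <- interval_set("chr1", 1000 * (0:4999), 1000 * (0:4999) + 500)
  ok <- vapply(1:10, function(s) {
    set.seed(s + 400)
    v <- rnbinom(5000, size = 20, mu = 200)
    l <- rnbinom(5000, size = 20, mu = 200)
    m <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")),
                       cbind(rpkm(v, 500, 1e6), rpkm(l, 500, 1e6)))
    r <- signal_ratio(m, "l", "v")$global_ratio
    r >= 0.95 && r <= 1.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("median_normalize divides each sample by its median", {
  reg <- interval_set("chr1", c(0, 100, 200), c(50, 150, 250))
  m <- signal_matrix(reg, sheet(c(1e6, 1e6), c("v", "l")),
                     cbind(c(1, 2, 3), c(10, 20, 30)))
  mn <- median_normalize(m)
  expect_equal(unname(mn$values[, 1]), c(0.5, 1, 1.5))
  expect_equal(unname(mn$values[, 2]), c(0.5, 1, 1.5))
})
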