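# Brute-force per-base oracles and small random generators used by the
# property tests. Everything here is deliberately naive (bitmasks and loops)
# and independent of the package's GenomicRanges-backed implementations.

# random interval set on a small toy genome
random_iset <- function(n, chroms = c("chrA", "chrB"), chrom_len = 10000,
                        max_width = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(chrom, start, pmin(start + width, chrom_len))
}

# logical coverage mask per chromosome (positions 1..chrom_len mark bases
# 0..chrom_len-1)
iset_mask <- function(x, chroms, chrom_len) {
  masks <- lapply(chroms, function(ch) logical(chrom_len))
  names(masks) <- chroms
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    masks[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  masks
}

# intervals from a mask (maximal runs of TRUE)
mask_iset <- function(masks) {
  rows <- list()
  for (ch in names(masks)) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      rows[[length(rows) + 1]] <- data.frame(chrom = ch,
                                             start = starts[j] - 1,
                                             end = ends[j])
    }
  }
  if (!length(rows)) {
    return(interval_set(character(0), numeric(0), numeric(0)))
  }
  as_interval_set(do.call(rbind, rows))
}

# brute-force membership: which records of a overlap b by >= minov bases
oracle_overlap_hits <- function(a, b, minov = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      if (a$chrom[i] != b$chrom[j]) return(FALSE)
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      ov >= minov
    }, logical(1)))
  }, logical(1))
}

# per-base support count across a list of sets (each set counted once/base)
oracle_support <- function(sets, chroms, chrom_len) {
  supp <- lapply(chroms, function(ch) integer(chrom_len))
  names(supp) <- chroms
  for (s in sets) {
    m <- iset_mask(s, chroms, chrom_len)
    for (ch in chroms) supp[[ch]] <- supp[[ch]] + m[[ch]]
  }
  supp
}

# naive per-window PWM scorer over both strands (independent of the package
# scanner): returns data frame of all window scores on the forward strand
# coordinates
oracle_scan <- function(seq, mat, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- nrow(mat)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars) - w + 1
  score_one <- function(win) {
    s <- 0
    for (k in seq_len(w)) {
      idx <- match(win[k], bases)
      if (is.na(idx)) return(-Inf)
      s <- s + log2(mat[k, idx] / background[idx])
    }
    s
  }
  fwd <- numeric(n); rev_ <- numeric(n)
  for (i in seq_len(n)) {
    win <- chars[i:(i + w - 1)]
    fwd[i] <- score_one(win)
    rc <- rev(unname(comp[win]))
    rc[is.na(rc)] <- "N"
    rev_[i] <- score_one(rc)
  }
  data.frame(pos = seq_len(n) - 1, fwd = fwd, rev = rev_)
}

# small helper: subset an interval_set by peak names, keeping the class
iset_subset <- function(x, names_keep) {
  out <- x[x$name %in% names_keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
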