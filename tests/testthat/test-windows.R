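test_that("window enumeration matches brute force exactly", {
  # constant delta: every window mean equals the constant
  d <- rep(0.3, 30)
  w <- window_deltas(d, c(1L, 30L), width = 20)
  expect_identical(nrow(w), 11L)                   # L - width + 1
  expect_equal(w$delta_mean, rep(0.3, 11))

  # random fixtures with NA holes: identical to exhaustive enumeration
  set.seed(13)
  for (i in 1:100) {
    L <- sample(25:120, 1)
    width <- sample(c(5, 10, 15, 20), 1)
    step <- sample(1:3, 1)
    v <- rnorm(L)
    v[runif(L) < 0.4] <- NA
    got <- window_deltas(v, c(1L, L), width, step)
    want <- brute_windows(v, width, step)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, want$start)
      expect_equal(got$delta_mean, want$delta_mean, tolerance = 1e-12)
      expect_identical(got$n_defined, as.integer(want$n_defined))
    }
    # enumeration count before the min_defined drop
    all_w <- window_deltas(v, c(1L, L), width, step, min_defined = 0)
    expect_identical(nrow(all_w),
                     as.integer(floor((L - width) / step) + 1))
  }

  # region shorter than the window: empty result
  expect_identical(nrow(window_deltas(rep(1, 10), c(1L, 10L), 20)), 0L)
})

test_that("extreme windows break ties to the smallest start and swap under negation", {
  d <- rep(0.1, 40)
  w <- window_deltas(d, c(1L, 40L), width = 10)
  ext <- extreme_windows(w)
  expect_identical(ext$min$start, 0L)
  expect_identical(ext$max$start, 0L)

  set.seed(3)
  v <- rnorm(60)
  w1 <- window_deltas(v, c(1L, 60L), 15)
  w2 <- window_deltas(-v, c(1L, 60L), 15)
  e1 <- extreme_windows(w1); e2 <- extreme_windows(w2)
  expect_identical(e1$min$start, e2$max$start)
  expect_identical(e1$max$start, e2$min$start)
})

test_that("halving the width can only deepen the minimum window mean", {
  # a window partitions into disjoint halves, so for divisible widths the
  # smaller-width minimum is bounded above by the larger-width minimum
  set.seed(5)
  for (i in 1:10) {
    v <- rnorm(100)
    mins <- vapply(c(40, 20, 10, 5), function(w) {
      extreme_windows(window_deltas(v, c(1L, 100L), w))$min$delta_mean
    }, numeric(1))
    expect_true(all(diff(mins) <= 1e-12))
  }
})

test_that("extreme-window detection is translation-equivariant on clean tracks", {
  base <- rep(0, 200)
  for (shift in c(0, 17, 60)) {
    v <- base
    v[(41 + shift):(60 + shift)] <- -1
    e <- extreme_windows(window_deltas(v, c(1L, 200L), 20))
    expect_identical(e$min$start, as.integer(40 + shift))
  }
})

test_that("relative window positions bin as specified", {
  # window centered at the 5'UTR midpoint: rel 0.5, bin 5 of 10 (0-based)
  d <- rep(NA_real_, 100); d[1:100] <- 0; d[46:55] <- -1
  w <- window_deltas(d, c(1L, 100L), 10)
  e <- extreme_windows(w)
  expect_equal(e$min$rel_pos, 0.5)
  pb <- position_bins(e$min$rel_pos)
  expect_identical(pb$bins$count[pb$bins$bin == 5], 1L)
  # start 0, width = L: rel position exactly 0.5
  w2 <- window_deltas(rep(1, 50), c(1L, 50L), 50)
  expect_equal(w2$rel_pos, 0.5)
  # two-group comparison returns a Wilcoxon p
  set.seed(2)
  pb2 <- position_bins(runif(50, 0.6, 1), runif(50, 0, 1))
  expect_true(pb2$p >= 0 && pb2$p <= 1)
})

test_that("GC windows handle periodic and degenerate sequences", {
  ann <- data.frame(transcript_id = c("g", "p"), utr5_end = c(100L, 100L),
                    cds_end = c(400L, 400L), length = c(800L, 800L),
                    stringsAsFactors = FALSE)
  seqs <- c(g = paste(c(rep("G", 100), rep("A", 700)), collapse = ""),
            p = strrep("GA", 400))
  gw <- gc_windows(seqs, ann)
  expect_true(all(gw$windows$gc[gw$windows$transcript_id == "g"] == 1))
  # alternating G/A: every even-width window is exactly half GC
  expect_true(all(gw$windows$gc[gw$windows$transcript_id == "p"] == 0.5))
  # a region shorter than the window is skipped
  ann2 <- rbind(ann, data.frame(transcript_id = "s", utr5_end = 30L,
                                cds_end = 400L, length = 800L))
  seqs2 <- c(seqs, s = paste(rep("A", 800), collapse = ""))
  gw2 <- gc_windows(seqs2, ann2)
  expect_false("s" %in% gw2$windows$transcript_id)

  # synthetic gradient: binned GC profile decreases 5' -> 3'
  txs <- simulate_transcriptome(sim_config(n_transcripts = 300, seed = 8))$transcripts
  gw3 <- gc_windows(setNames(txs$sequence, txs$transcript_id), txs)
  ct <- cor.test(gw3$profile$mean, gw3$profile$bin, method = "spearman",
                 exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("length matching pairs targets with near-identical pool lengths", {
  target <- setNames(c(100, 220, 300), c("t1", "t2", "t3"))
  pool <- setNames(c(100, 150, 220, 300, 500), paste0("p", 1:5))
  m <- length_match(target, pool, seed = 1)
  expect_identical(sort(m$match_length), sort(c(100, 220, 300)))
  expect_equal(m$log2_ratio, rep(0, 3))
  expect_error(length_match(pool, target), "smaller than")

  set.seed(31)
  tl <- rlnorm(150, log(260), 0.5); names(tl) <- paste0("t", 1:150)
  pl <- rlnorm(750, log(200), 0.6); names(pl) <- paste0("p", 1:750)
  m2 <- length_match(tl, pl, seed = 1)
  expect_lt(mean(abs(m2$log2_ratio)), 0.1)
  expect_identical(anyDuplicated(m2$match_id), 0L)
})

test_that("extreme-delta correlations behave on degenerate and linear input", {
  expect_error(correlate_extreme_vs_feature(c(1, 2, 3), c(5, 5, 5)),
               "zero variance")
  expect_error(correlate_extreme_vs_feature(c(1, 2), c(1, 2)), "at least 3")
  ct <- correlate_extreme_vs_feature(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(ct$r, 1)
  ct2 <- correlate_extreme_vs_feature(c(1, 2, 3, 4), -c(2, 4, 6, 8))
  expect_equal(ct2$r, -1)
})

test_that("the width sweep reports raw per-width Wilcoxon p values", {
  a <- cached_default_analysis()
  tr <- a$sim$truth
  dep <- intersect(a$ids, tr$transcript_id[tr$label == "dep"])
  ind <- intersect(a$ids, tr$transcript_id[tr$label == "indep"])
  sw <- width_sweep(a$delta, a$sim$transcripts, dep, ind,
                    widths = c(10, 15, 20))
  expect_identical(nrow(sw), 6L)
  expect_true(all(sw$p >= 0 & sw$p <= 1, na.rm = TRUE))
  # both groups remodel with the same injected depth (they differ only in
  # window position), so both carry clearly negative minima at every width
  mins <- sw[sw$which == "min", ]
  expect_true(all(mins$median_a < 0))
  expect_true(all(mins$median_b < 0))
})
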