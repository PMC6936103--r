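test_that("substreams are deterministic and order-insensitive", {
  expect_identical(substream_seed(1, 2, 3), substream_seed(1, 2, 3))
  expect_false(substream_seed(1, 2, 3) == substream_seed(1, 3, 2))
  x <- with_seed(42, runif(3))
  y <- with_seed(42, runif(3))
  expect_identical(x, y)
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_transcripts = 10, seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_structure_seq(cfg), d1)
  write_simulation(simulate_structure_seq(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("transcript architecture obeys its invariants", {
  txs <- simulate_transcriptome(sim_config(n_transcripts = 40, seed = 2))$transcripts
  cds_len <- txs$cds_end - txs$utr5_end
  expect_true(all(cds_len %% 3 == 0))
  expect_true(all(txs$utr5_end >= 100))
  expect_true(all(cds_len >= 100))
  expect_true(all(txs$length - txs$cds_end >= 100))
  expect_true(all(nchar(txs$sequence) == txs$length))
  # labels partition the transcripts
  expect_true(all(txs$label %in% c("dep", "indep", "antidep")))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_dep = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_dep = 0.7, frac_antidep = 0.5), "exceed 1")
  expect_error(sim_config(utr5_length_dist = list(dist = "magic")),
               "unknown distribution")
  expect_error(sim_config(utr5_length_dist = list(dist = "fixed", value = 50)),
               "at least 100")
})

test_that("5'UTR GC decreases away from the cap only when a gradient is injected", {
  # no gradient: first/last quintile GC difference within 3 sigma of
  # binomial sampling
  txs0 <- simulate_transcriptome(
    sim_config(n_transcripts = 200, seed = 5, gc_gradient_slope = 0))$transcripts
  q1 <- c(); q5 <- c()
  for (i in seq_len(nrow(txs0))) {
    u5 <- txs0$utr5_end[i]
    ch <- strsplit(substr(txs0$sequence[i], 1, u5), "")[[1]]
    k <- floor(u5 / 5)
    q1 <- c(q1, ch[1:k] %in% c("G", "C"))
    q5 <- c(q5, ch[(u5 - k + 1):u5] %in% c("G", "C"))
  }
  se <- sqrt(0.25 / length(q1) + 0.25 / length(q5))
  expect_lt(abs(mean(q1) - mean(q5)), 3 * se)

  # gradient: window GC correlates negatively with distance from the cap
  txs <- simulate_transcriptome(
    sim_config(n_transcripts = 500, seed = 5))$transcripts
  seqs <- setNames(txs$sequence, txs$transcript_id)
  gw <- gc_windows(seqs, txs, width = 50, step = 10)
  ct <- cor.test(gw$windows$gc, gw$windows$start)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("accessibility remodeling is conservative and positioned as labeled", {
  cfg <- sim_config(n_transcripts = 60, seed = 3)
  txs <- simulate_transcriptome(cfg)$transcripts
  rt <- simulate_reactivity_truth(txs, cfg)

  # depth 0: treated equals control
  cfg0 <- sim_config(n_transcripts = 10, seed = 3, remodel_depth = 0)
  txs0 <- simulate_transcriptome(cfg0)$transcripts
  rt0 <- simulate_reactivity_truth(txs0, cfg0)
  for (id in names(rt0$accessibility)) {
    expect_identical(rt0$accessibility[[id]]$control,
                     rt0$accessibility[[id]]$hipp)
  }

  w <- rt$windows
  dep <- w[w$label == "dep" & !is.na(w$loss_start), ]
  mid_rel <- (dep$loss_start + (dep$loss_end - dep$loss_start) / 2) /
    dep$utr5_length
  expect_true(all(mid_rel > 0.5))
  # loss and gain windows are disjoint and inside the 5'UTR
  ok <- !is.na(w$gain_start)
  expect_true(all(w$loss_end[ok] <= w$gain_start[ok] |
                    w$gain_end[ok] <= w$loss_start[ok]))
  expect_true(all(w$gain_end[ok] <= w$utr5_length[ok]))

  # conservation: mean(treated - control) over the 5'UTR ~ 0 when matched
  comp <- w$transcript_id[!is.na(w$compensated) & w$compensated]
  for (id in comp) {
    u5 <- w$utr5_length[w$transcript_id == id]
    a <- rt$accessibility[[id]]
    expect_lt(abs(mean(a$hipp[1:u5] - a$control[1:u5])), 0.01)
  }
  expect_gt(length(comp), 0.8 * nrow(w))
})

test_that("remodeling wider than the 5'UTR is skipped with a warning", {
  cfg <- sim_config(n_transcripts = 1, seed = 4,
                    utr5_length_dist = list(dist = "fixed", value = 100),
                    remodel_width = 150)
  txs <- simulate_transcriptome(cfg)$transcripts
  expect_warning(rt <- simulate_reactivity_truth(txs, cfg), "skipped")
  expect_true(all(is.na(rt$windows$loss_start)))
})

test_that("stop counts follow single-hit DMS statistics", {
  # background 0: every DMS(+) stop is at an A or C
  cfg <- sim_config(n_transcripts = 5, seed = 6, background_rate = 0,
                    abundance_sdlog = 0)
  txs <- simulate_transcriptome(cfg)$transcripts
  rt <- simulate_reactivity_truth(txs, cfg)
  st <- simulate_stop_counts(txs, rt$accessibility, cfg)
  for (i in seq_len(nrow(txs))) {
    sp <- stop_specificity(st$control_plus_1[[txs$transcript_id[i]]],
                           txs$sequence[i])
    expect_equal(sp$specificity, 1.0)
  }

  # zero accessibility + positive background: DMS(+) and DMS(-)
  # indistinguishable (chi-square on pooled position bins)
  cfg2 <- sim_config(n_transcripts = 1, seed = 3, background_rate = 0.05,
                     end_spike_frac = 0, stops_per_transcript_mean = 1e4,
                     minus_depth_frac = 1, abundance_sdlog = 0)
  txs2 <- simulate_transcriptome(cfg2)$transcripts
  zero <- setNames(list(list(control = rep(0, txs2$length[1]),
                             hipp = rep(0, txs2$length[1]))),
                   txs2$transcript_id)
  st2 <- simulate_stop_counts(txs2, zero, cfg2)
  p <- st2$control_plus_1[[1]]
  m <- st2$control_minus_1[[1]]
  b <- cut(seq_along(p), 50)
  tab <- rbind(tapply(p, b, sum), tapply(m, b, sum))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # replicate correlation of pooled DMS(+) counts is high at default depth
  sim <- cached_default_sim()
  rc <- replicate_correlation(sim$rtsc,
                              c("control_plus_1", "control_plus_2",
                                "control_plus_3"))
  expect_true(all(rc$correlation > 0.8))

  # specificity decreases with background rate, total mass conserved in law
  spec_of <- function(bg) {
    cfgb <- sim_config(n_transcripts = 5, seed = 6, background_rate = bg,
                       abundance_sdlog = 0)
    txb <- simulate_transcriptome(cfgb)$transcripts
    rtb <- simulate_reactivity_truth(txb, cfgb)
    stb <- simulate_stop_counts(txb, rtb$accessibility, cfgb)
    tot <- 0; ac <- 0
    for (i in seq_len(nrow(txb))) {
      cts <- stb$control_plus_1[[txb$transcript_id[i]]]
      ch <- strsplit(txb$sequence[i], "")[[1]]
      tot <- tot + sum(cts); ac <- ac + sum(cts[ch %in% c("A", "C")])
    }
    ac / tot
  }
  s <- vapply(c(0, 0.05, 0.3), spec_of, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_equal(s[1], 1.0)
})

test_that("polysome counts encode the designed translational shifts", {
  # null: no systematic fraction-specific change
  cfg0 <- sim_config(n_transcripts = 1000, seed = 1, te_shift = 0)
  poly0 <- simulate_polysome_counts(fake_genes(1000), cfg0)
  cls0_lfc <- classify_dod(poly0$expression)
  d <- cls0_lfc$poly_lfc - cls0_lfc$sub_lfc
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))

  # dep genes: negative expected sign of polyLFC - subLFC
  cfg1 <- sim_config(n_transcripts = 200, seed = 2, te_shift = 1)
  poly1 <- simulate_polysome_counts(fake_genes(200, label = "dep"), cfg1)
  cls1 <- classify_dod(poly1$expression)
  expect_lt(mean(cls1$dod), 0)
  expect_gt(mean(cls1$dod < 0), 0.95)

  # dispersion -> 0: counts converge to their deterministic means
  cfgd <- sim_config(n_transcripts = 300, seed = 3, te_shift = 0,
                     dispersion = 0, polysome_mean = 5e4,
                     polysome_mean_sdlog = 0)
  polyd <- simulate_polysome_counts(fake_genes(300), cfgd)
  x <- polyd$expression
  tot <- x$count[x$fraction == "total" & x$condition == "control"]
  expect_lt(abs(mean(tot) - 5e4) / 5e4, 0.01)
})

test_that("TIS counts reflect the upstream-initiation mixture", {
  cfg0 <- sim_config(n_transcripts = 50, seed = 1, utis_mix = 0)
  tis0 <- simulate_tis_counts(fake_genes(50), cfg0)
  expect_true(all(tis0$upstream_reads == 0))
  expect_true(all(utis_score(tis0$upstream_reads, tis0$atis_reads) == 0))

  cfg1 <- sim_config(n_transcripts = 200, seed = 1, utis_mix = 1,
                     utis_upstream_frac = 0.5, tis_reads_mean = 1e4)
  tis1 <- simulate_tis_counts(fake_genes(200), cfg1)
  sc <- utis_score(tis1$upstream_reads, tis1$atis_reads)
  expect_lt(abs(mean(sc) - 0.5), 0.02)

  tis1b <- simulate_tis_counts(fake_genes(200), cfg1)
  expect_identical(tis1, tis1b)
})
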