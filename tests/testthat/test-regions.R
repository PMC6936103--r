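test_that("region spans partition the transcript exactly", {
  # utr5 [0,150), cds [150,450), utr3 [450, 800) with 125 trimmed
  u <- region_span(150, 450, 800, "utr5")
  c_ <- region_span(150, 450, 800, "cds")
  t_ <- region_span(150, 450, 800, "utr3")
  expect_identical(u, c(1L, 150L))
  expect_identical(c_, c(151L, 450L))
  expect_identical(t_, c(451L, 675L))
  # untrimmed partition is exact
  t0 <- region_span(150, 450, 800, "utr3", trim_nt = 0)
  expect_identical(as.integer((u[2] - u[1] + 1) + (c_[2] - c_[1] + 1) +
                                (t0[2] - t0[1] + 1)), 800L)
  # fully trimmed-away 3' region is NULL
  expect_null(region_span(150, 450, 500, "utr3"))
})

test_that("the most abundant transcript represents each gene, ties lexicographic", {
  df <- data.frame(
    transcript_id = c("txA", "txB", "txC", "txD", "txE"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    abundance = c(5, 9, 5, 5, 2),
    stringsAsFactors = FALSE)
  rep_ <- select_representative(df)
  expect_identical(sort(rep_$transcript_id), c("txB", "txC", "txE"))
  df$abundance[5] <- NA
  expect_message(rep2 <- select_representative(df), "without abundance")
  expect_false("txE" %in% rep2$transcript_id)
})

test_that("region averages use only defined positions", {
  prof <- rep(NA_real_, 12)
  prof[c(2, 5, 9)] <- c(0.2, 1.0, 0.3)
  expect_equal(region_average(prof, c(1L, 12L)), 0.5)
  expect_equal(region_average(rep(0.7, 10), c(1L, 10L)), 0.7)
  expect_true(is.na(region_average(rep(NA_real_, 10), c(1L, 10L))))
  expect_true(is.na(region_average(prof, NULL)))
})

test_that("gini matches the brute-force pairwise oracle", {
  expect_equal(gini(rep(3, 10)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)
  expect_equal(gini(c(1, 0, 0, 0)), brute_gini(c(1, 0, 0, 0)))
  # random vectors, n <= 8: exact agreement with the oracle,
  # and scale invariance
  set.seed(21)
  for (i in 1:50) {
    x <- runif(sample(2:8, 1))
    expect_equal(gini(x), brute_gini(x), tolerance = 1e-12)
    expect_equal(gini(x * runif(1, 0.1, 50)), gini(x), tolerance = 1e-12)
  }
  expect_true(is.na(gini(c(0, 0, 0))))
  expect_true(is.na(gini(5)))
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("bin assignment follows the flooring rule", {
  expect_identical(bin_index(0, 25, 250), 0L)
  expect_identical(bin_index(249, 25, 250), 24L)
  expect_identical(bin_index(c(0, 9, 10), 25, 250), c(0L, 0L, 1L))
  # bins never exceed the region's bin count
  expect_true(all(bin_index(0:999, 25, 1000) <= 24L))
})

test_that("meta-profiles of constant profiles are flat with CIs covering zero", {
  ann <- data.frame(transcript_id = paste0("t", 1:6),
                    utr5_end = 150, cds_end = 450, length = 800,
                    stringsAsFactors = FALSE)
  prof <- setNames(lapply(1:6, function(i) rep(0.4, 800)), ann$transcript_id)
  mp <- metaprofile_paired(prof, prof, ann)
  expect_identical(nrow(mp), 100L)
  expect_equal(mp$mean_control, rep(0.4, 100))
  expect_equal(mp$delta, rep(0, 100))
  expect_true(all(mp$ci_lo <= 0 & mp$ci_hi >= 0))
  # CI contains the point estimate wherever defined
  a <- cached_default_analysis()
  mp2 <- metaprofile_paired(a$avg_control[a$ids], a$avg_hipp[a$ids],
                            a$sim$transcripts)
  expect_true(all(mp2$ci_lo <= mp2$delta & mp2$delta <= mp2$ci_hi))
  counts <- table(mp2$region)
  expect_identical(as.integer(counts[c("utr5", "cds", "utr3")]),
                   c(25L, 50L, 25L))
})

test_that("transcripts with short regions are excluded from meta-profiles", {
  ann <- data.frame(transcript_id = c("a", "b"),
                    utr5_end = c(150L, 50L), cds_end = c(450L, 350L),
                    length = c(800L, 700L), stringsAsFactors = FALSE)
  prof <- list(a = rep(1, 800), b = rep(1, 700))
  m <- bin_profiles(prof, ann)
  expect_identical(rownames(m), "a")
})

test_that("a shuffled delta set yields a flat meta-profile", {
  a <- cached_default_analysis()
  set.seed(7)
  covered <- 0; n_checks <- 0
  for (s in 1:5) {
    shuffled <- lapply(a$delta, function(d) {
      i <- which(!is.na(d)); d[i] <- sample(d[i]); d
    })
    treated <- setNames(lapply(a$ids, function(id) {
      a$avg_control[[id]] + shuffled[[id]]
    }), a$ids)
    mp <- metaprofile_paired(a$avg_control[a$ids], treated,
                             a$sim$transcripts, conf_level = 0.99)
    half <- (mp$ci_hi - mp$ci_lo) / 2
    ok <- abs(mp$delta) <= half
    covered <- covered + sum(ok, na.rm = TRUE)
    n_checks <- n_checks + sum(!is.na(ok))
  }
  expect_gte(covered / n_checks, 0.95)
})

test_that("terminal profiles aggregate region ends position by position", {
  ann <- data.frame(transcript_id = c("a", "b"),
                    utr5_end = c(150L, 40L), cds_end = c(450L, 340L),
                    length = c(800L, 700L), stringsAsFactors = FALSE)
  prof <- list(a = rep(0.3, 800), b = rep(0.9, 700))
  tp <- terminal_profile(prof, ann, region = "utr5", end = "last", span = 60)
  # b's 40-nt 5'UTR is shorter than the span and is skipped
  expect_equal(tp$mean, rep(0.3, 60))
  expect_equal(tp$n, rep(1, 60))

  # treatment-induced structure gain concentrates in the last 20 nt of
  # dependent 5'UTRs
  a <- cached_default_analysis()
  tr <- a$sim$truth
  last20 <- function(id) {
    an <- a$sim$transcripts[match(id, a$sim$transcripts$transcript_id), ]
    sp <- region_span(an$utr5_end, an$cds_end, an$length, "utr5")
    mean(a$delta[[id]][(sp[2] - 19):sp[2]], na.rm = TRUE)
  }
  dep <- intersect(a$ids, tr$transcript_id[tr$label == "dep"])
  ind <- intersect(a$ids, tr$transcript_id[tr$label == "indep"])
  da <- vapply(dep, last20, numeric(1))
  db <- vapply(ind, last20, numeric(1))
  wt <- wilcox.test(da, db, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
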