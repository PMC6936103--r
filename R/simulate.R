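# RNG stream ids (substream_seed(seed, STREAM, ...))
.STREAM_TRANSCRIPT <- 1L
.STREAM_LABELS     <- 2L
.STREAM_ACCESS     <- 3L
.STREAM_STOPS      <- 4L
.STREAM_POLYSOME   <- 5L
.STREAM_TIS        <- 6L

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

random_bases <- function(L, gc) {
  # gc may be scalar or per-position; GC split evenly G/C, AT evenly A/T
  u <- stats::runif(L)
  v <- stats::runif(L)
  is_gc <- u < gc
  ifelse(is_gc, ifelse(v < 0.5, "G", "C"), ifelse(v < 0.5, "A", "T"))
}

#' Generate a synthetic annotated transcriptome
#'
#' Draws region lengths, sequences (with a 5'-high GC gradient in the
#' 5'UTR when `gc_gradient_slope > 0`), per-transcript abundances, and
#' helicase-dependency labels.  One transcript is generated per gene; every
#' region is at least 100 nt and every CDS length is divisible by 3 and
#' starts with ATG.
#'
#' @param config a [sim_config()].
#' @return A list with `transcripts` (data.frame: `transcript_id`,
#'   `gene_id`, `length`, `utr5_end`, `cds_end` (0-based half-open region
#'   boundaries), `abundance`, `label`, `sequence`) and `truth` (data.frame
#'   of per-transcript ground-truth labels, grown by the downstream
#'   simulators).
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_transcripts)

  n_dep  <- round(n * config$frac_dep)
  n_anti <- round(n * config$frac_antidep)
  n_ind  <- n - n_dep - n_anti
  base_labels <- c(rep("dep", n_dep), rep("antidep", n_anti), rep("indep", n_ind))
  perm <- with_seed(substream_seed(config$seed, .STREAM_LABELS), sample.int(n))
  labels <- base_labels[order(perm)]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- with_seed(substream_seed(config$seed, .STREAM_TRANSCRIPT, i), {
      u5 <- draw_lengths(1, config$utr5_length_dist)
      cds <- draw_lengths(1, config$cds_length_dist)
      cds <- cds - cds %% 3L
      if (cds < 102L) cds <- 102L
      u3 <- draw_lengths(1, config$utr3_length_dist)
      r <- if (u5 > 1) (0:(u5 - 1)) / (u5 - 1) else 0
      gc5 <- clamp(config$gc_utr5 + config$gc_gradient_slope * (0.5 - r), 0.2, 0.8)
      seq5 <- random_bases(u5, gc5)
      seqc <- c("A", "T", "G", random_bases(cds - 3L, config$gc_body))
      seq3 <- random_bases(u3, config$gc_body)
      abundance <- stats::rlnorm(1, 0, config$abundance_sdlog) /
        exp(config$abundance_sdlog^2 / 2)
      data.frame(
        transcript_id = sprintf("g%04d.t1", i),
        gene_id = sprintf("g%04d", i),
        length = u5 + cds + u3,
        utr5_end = u5,
        cds_end = u5 + cds,
        abundance = abundance,
        sequence = paste(c(seq5, seqc, seq3), collapse = ""),
        stringsAsFactors = FALSE
      )
    })
  }
  transcripts <- do.call(rbind, rows)
  transcripts$label <- labels
  transcripts <- transcripts[, c("transcript_id", "gene_id", "length",
                                 "utr5_end", "cds_end", "abundance", "label",
                                 "sequence")]
  truth <- transcripts[, c("transcript_id", "gene_id", "label")]
  list(transcripts = transcripts, truth = truth)
}

#' Simulate ground-truth accessibility under control and treatment
#'
#' Control accessibility is drawn per position from Beta(2, 2).  Treatment
#' accessibility equals control except for two disjoint windows inside the
#' 5'UTR: a loss window where `remodel_depth` is subtracted (clipped at 0)
#' and a compensatory gain window where the realized integrated loss is
#' added back proportionally to headroom (clipped at 1), emulating
#' remodeling (localized gain of structure balanced by adjacent loss)
#' rather than a net structure gain.  Dependent transcripts place the loss
#' window near relative position `remodel_position_bias` of the 5'UTR;
#' independent and antidependent transcripts place it uniformly at random.
#'
#' @param transcripts transcript table from [simulate_transcriptome()].
#' @param config a [sim_config()].
#' @return A list with `accessibility` (named list; per transcript a list
#'   with numeric vectors `control` and `hipp` in `[0, 1]`, one value per
#'   nucleotide) and `windows` (data.frame of injected window coordinates,
#'   0-based half-open, `NA` where remodeling was skipped).
#' @export
simulate_reactivity_truth <- function(transcripts, config) {
  validate_sim_config(config)
  n <- nrow(transcripts)
  acc <- vector("list", n)
  names(acc) <- transcripts$transcript_id
  wrows <- vector("list", n)
  w <- config$remodel_width
  for (i in seq_len(n)) {
    tx <- transcripts[i, ]
    L <- tx$length
    U <- tx$utr5_end
    res <- with_seed(substream_seed(config$seed, .STREAM_ACCESS, i), {
      ctrl <- stats::rbeta(L, 2, 2)
      hipp <- ctrl
      loss_start <- NA_integer_; loss_end <- NA_integer_
      gain_start <- NA_integer_; gain_end <- NA_integer_
      compensated <- NA
      if (w > U) {
        warning("remodel_width ", w, " exceeds 5'UTR length ", U,
                " for ", tx$transcript_id, "; remodeling skipped", call. = FALSE)
      } else if (config$remodel_depth > 0) {
        if (tx$label == "dep") {
          m <- config$remodel_position_bias +
            stats::runif(1, -config$remodel_position_jitter,
                         config$remodel_position_jitter)
          m <- clamp(m, (w / 2) / U, 1 - (w / 2) / U)
          start0 <- as.integer(clamp(round(m * U - w / 2), 0, U - w))
        } else {
          start0 <- sample.int(U - w + 1L, 1) - 1L
        }
        loss_start <- start0
        loss_end <- start0 + w
        idx <- (start0 + 1L):(start0 + w)
        hipp[idx] <- pmax(0, ctrl[idx] - config$remodel_depth)
        loss_total <- sum(ctrl[idx] - hipp[idx])

        wg <- as.integer(config$compensation_width_factor * w)
        cand <- integer(0)
        if (U >= wg) {
          all_starts <- 0:(U - wg)
          ok <- (all_starts + wg <= loss_start) | (all_starts >= loss_end)
          cand <- all_starts[ok]
        }
        if (length(cand) == 0 && U >= w) {
          wg <- w
          all_starts <- 0:(U - wg)
          ok <- (all_starts + wg <= loss_start) | (all_starts >= loss_end)
          cand <- all_starts[ok]
        }
        if (length(cand) > 0 && loss_total > 0) {
          g0 <- cand[sample.int(length(cand), 1)]
          gain_start <- g0
          gain_end <- g0 + wg
          gidx <- (g0 + 1L):(g0 + wg)
          headroom <- 1 - hipp[gidx]
          cc <- if (sum(headroom) > 0) min(loss_total / sum(headroom), 1) else 0
          hipp[gidx] <- hipp[gidx] + cc * headroom
          compensated <- abs(cc * sum(headroom) - loss_total) < 1e-9
        } else {
          compensated <- FALSE
        }
      }
      list(ctrl = ctrl, hipp = hipp,
           row = data.frame(transcript_id = tx$transcript_id, label = tx$label,
                            utr5_length = U,
                            loss_start = loss_start, loss_end = loss_end,
                            gain_start = gain_start, gain_end = gain_end,
                            compensated = compensated,
                            stringsAsFactors = FALSE))
    })
    acc[[i]] <- list(control = res$ctrl, hipp = res$hipp)
    wrows[[i]] <- res$row
  }
  list(accessibility = acc, windows = do.call(rbind, wrows))
}

.sim_conditions <- c(control = 1L, hipp = 2L)
.sim_channels <- c(minus = 1L, plus = 2L)

#' Names of the simulated Structure-seq samples
#'
#' @param config a [sim_config()].
#' @return Character vector `"<condition>_<channel>_<replicate>"` over
#'   conditions control/hipp, channels minus/plus and all replicates.
#' @export
sample_names <- function(config) {
  grid <- expand.grid(rep = seq_len(config$n_replicates),
                      channel = names(.sim_channels),
                      condition = names(.sim_conditions),
                      stringsAsFactors = FALSE)
  sprintf("%s_%s_%d", grid$condition, grid$channel, grid$rep)
}

#' Simulate RT-stop count tracks
#'
#' DMS(+) stops are allocated multinomially with per-position weight
#' `background_rate + accessibility * [base is A or C]` under the relevant
#' condition; the total is Poisson with mean
#' `stops_per_transcript_mean * abundance` (DMS(-): times
#' `minus_depth_frac`).  DMS(-) weights are uniform over all four bases
#' plus a 5'-end spike (`end_spike_frac` of minus stops at position 0)
#' emulating full-length cDNA stops at the annotated 5' end.  Counts are in
#' modified-base coordinates: the count at index i is the number of RT
#' stops whose modified base is at i.
#'
#' @param transcripts transcript table from [simulate_transcriptome()].
#' @param accessibility `accessibility` element of
#'   [simulate_reactivity_truth()].
#' @param config a [sim_config()].
#' @return Named list over [sample_names()]; each element a named list of
#'   integer count vectors, one per transcript.
#' @export
simulate_stop_counts <- function(transcripts, accessibility, config) {
  validate_sim_config(config)
  samples <- sample_names(config)
  out <- lapply(samples, function(s) {
    setNames(vector("list", nrow(transcripts)), transcripts$transcript_id)
  })
  names(out) <- samples

  seqs <- strsplit(transcripts$sequence, "", fixed = TRUE)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    L <- tx$length
    is_ac <- seqs[[i]] %in% c("A", "C")
    for (cond in names(.sim_conditions)) {
      acc <- accessibility[[tx$transcript_id]][[if (cond == "control") "control" else "hipp"]]
      w_plus <- config$background_rate + acc * is_ac
      w_minus <- rep(1, L)
      if (config$end_spike_frac > 0 && config$end_spike_frac < 1) {
        w_minus[1] <- w_minus[1] +
          config$end_spike_frac / (1 - config$end_spike_frac) * L
      }
      for (chan in names(.sim_channels)) {
        depth <- config$stops_per_transcript_mean * tx$abundance
        if (chan == "minus") depth <- depth * config$minus_depth_frac
        wts <- if (chan == "plus") w_plus else w_minus
        for (r in seq_len(config$n_replicates)) {
          seed <- substream_seed(config$seed, .STREAM_STOPS, i,
                                 .sim_conditions[[cond]] * 10L + .sim_channels[[chan]], r)
          counts <- with_seed(seed, {
            total <- stats::rpois(1, depth)
            if (total > 0 && sum(wts) > 0) {
              as.integer(stats::rmultinom(1, total, wts))
            } else {
              integer(L)
            }
          })
          out[[sprintf("%s_%s_%d", cond, chan, r)]][[tx$transcript_id]] <- counts
        }
      }
    }
  }
  out
}

#' Simulate polysome-fraction expression counts
#'
#' Per gene, a lognormal baseline expression is split into polysomal
#' (`poly_fraction`) and sub-polysomal mass.  Under treatment, dependent
#' genes move expression from the polysomal into the sub-polysomal
#' fraction: fraction factors a (polysomal) and b (sub-polysomal) satisfy
#' `log(a/b) = -te_shift` and `poly*a + sub*b = poly + sub`, so the true
#' log-TE shift is exactly `-te_shift` and the gene total is conserved.
#' Antidependent genes use the opposite sign; independent genes get an
#' equal (small, common) shift in both fractions.  Counts per
#' fraction/condition/replicate are negative binomial with the configured
#' dispersion (Poisson at dispersion 0).
#'
#' @param transcripts transcript table with `gene_id` and `label`.
#' @param config a [sim_config()].
#' @return A list with `expression` (long data.frame: `gene_id`,
#'   `fraction` in total/sub/poly, `condition`, `replicate`, `count`) and
#'   `truth` (data.frame: `gene_id`, `label`, `te_ctrl`, `te_hipp`).
#' @export
simulate_polysome_counts <- function(transcripts, config) {
  validate_sim_config(config)
  genes <- transcripts[, c("gene_id", "label")]
  R <- config$n_replicates
  p <- config$poly_fraction
  erows <- vector("list", nrow(genes))
  trows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    res <- with_seed(substream_seed(config$seed, .STREAM_POLYSOME, i), {
      mu <- stats::rlnorm(1, log(config$polysome_mean), config$polysome_mean_sdlog)
      eta <- stats::rnorm(1, 0, 0.05)  # common condition effect, cancels in TE
      poly <- mu * p
      sub <- mu * (1 - p)
      shift <- switch(g$label, dep = config$te_shift,
                      antidep = -config$te_shift, indep = 0)
      a <- (poly + sub) / (poly + sub * exp(shift))
      b <- a * exp(shift)
      means <- list(
        control = c(total = mu, sub = sub, poly = poly),
        hipp = c(total = (poly * a + sub * b) * exp(eta),
                 sub = sub * b * exp(eta), poly = poly * a * exp(eta))
      )
      draw <- function(m) {
        if (config$dispersion < 1e-12) {
          stats::rpois(1, m)
        } else {
          stats::rnbinom(1, mu = m, size = 1 / config$dispersion)
        }
      }
      rows <- list()
      for (cond in c("control", "hipp")) {
        for (fr in c("total", "sub", "poly")) {
          for (r in seq_len(R)) {
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = g$gene_id, fraction = fr, condition = cond,
              replicate = r, count = draw(means[[cond]][[fr]]),
              stringsAsFactors = FALSE)
          }
        }
      }
      list(expr = do.call(rbind, rows),
           truth = data.frame(gene_id = g$gene_id, label = g$label,
                              te_ctrl = p / (1 - p),
                              te_hipp = p / (1 - p) * exp(-shift),
                              stringsAsFactors = FALSE))
    })
    erows[[i]] <- res$expr
    trows[[i]] <- res$truth
  }
  list(expression = do.call(rbind, erows), truth = do.call(rbind, trows))
}

#' Simulate translation-initiation-site read counts
#'
#' A gene has upstream initiation with probability `utis_mix`; its reads
#' split binomially between upstream and annotated start sites with
#' upstream probability `utis_upstream_frac`.  Genes without upstream
#' initiation have zero upstream reads.
#'
#' @param transcripts transcript table with `gene_id`.
#' @param config a [sim_config()].
#' @return data.frame: `gene_id`, `upstream_reads`, `atis_reads`,
#'   `has_upstream`.
#' @export
simulate_tis_counts <- function(transcripts, config) {
  validate_sim_config(config)
  n <- nrow(transcripts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- with_seed(substream_seed(config$seed, .STREAM_TIS, i), {
      has_up <- stats::runif(1) < config$utis_mix
      total <- stats::rpois(1, config$tis_reads_mean)
      up <- if (has_up && total > 0) {
        stats::rbinom(1, total, config$utis_upstream_frac)
      } else 0L
      data.frame(gene_id = transcripts$gene_id[i],
                 upstream_reads = as.integer(up),
                 atis_reads = as.integer(total - up),
                 has_upstream = has_up,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' Simulate a complete Structure-seq-style experiment
#'
#' Runs all component generators under one master seed and returns the
#' full experiment: transcriptome, ground-truth accessibility and injected
#' windows, RT-stop tracks for DMS(+/-) x control/treated x replicates,
#' polysome expression counts, and TIS read counts.
#'
#' @param config a [sim_config()].
#' @return A list with elements `config`, `transcripts`, `truth`
#'   (labels + injected windows + true TE), `accessibility`, `rtsc`,
#'   `polysome` (expression data.frame), `tis`.
#' @export
simulate_structure_seq <- function(config = sim_config()) {
  txs <- simulate_transcriptome(config)
  rt <- simulate_reactivity_truth(txs$transcripts, config)
  stops <- simulate_stop_counts(txs$transcripts, rt$accessibility, config)
  poly <- simulate_polysome_counts(txs$transcripts, config)
  tis <- simulate_tis_counts(txs$transcripts, config)
  truth <- rt$windows
  truth$gene_id <- sub("\\.t[0-9]+$", "", truth$transcript_id)
  truth <- merge(truth, poly$truth[, c("gene_id", "te_ctrl", "te_hipp")],
                 by = "gene_id", sort = FALSE)
  truth <- truth[match(rt$windows$transcript_id, truth$transcript_id), ]
  rownames(truth) <- NULL
  list(config = config, transcripts = txs$transcripts, truth = truth,
       accessibility = rt$accessibility, rtsc = stops,
       polysome = poly$expression, tis = tis)
}
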