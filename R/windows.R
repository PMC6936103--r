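#' Sliding-window delta reactivity within a region
#'
#' Computes the mean delta reactivity of every window of the given width
#' (step 1 enumerates every possible window).  Windows use only their
#' defined positions and are dropped when fewer than `min_defined`
#' positions are defined (dropping windows with any undefined position
#' outright would bias against GC-rich, A/C-poor regions).
#'
#' @param delta delta reactivity vector for one transcript.
#' @param span 1-based inclusive region span (from [region_span()]),
#'   usually the 5'UTR.
#' @param width window width (nt).
#' @param step start-to-start step (nt, default 1).
#' @param min_defined minimum defined positions per window (default 3).
#' @return data.frame: `start`, `end` (0-based half-open, region
#'   coordinates), `width`, `delta_mean`, `n_defined`, `rel_pos`
#'   (`(start + width/2) / region length`).  Empty when the region is
#'   shorter than the window.
#' @export
window_deltas <- function(delta, span, width, step = 1, min_defined = 3) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      width = integer(0), delta_mean = numeric(0),
                      n_defined = integer(0), rel_pos = numeric(0))
  if (is.null(span)) return(empty)
  v <- delta[span[1]:span[2]]
  Lr <- length(v)
  width <- as.integer(width)
  step <- as.integer(step)
  if (Lr < width) return(empty)
  starts <- as.integer(seq.int(0L, Lr - width, by = step))
  ok <- !is.na(v)
  cs <- cumsum(ifelse(ok, v, 0))
  cn <- cumsum(ok)
  sum_win <- cs[starts + width] - c(0, cs)[starts + 1]
  n_win <- as.integer(cn[starts + width] - c(0, cn)[starts + 1])
  keep <- n_win >= min_defined
  data.frame(start = starts[keep], end = starts[keep] + width,
             width = width,
             delta_mean = sum_win[keep] / n_win[keep],
             n_defined = n_win[keep],
             rel_pos = (starts[keep] + width / 2) / Lr,
             stringsAsFactors = FALSE)
}

#' Extreme windows per transcript
#'
#' The windows with the biggest decrease (minimum mean delta: largest
#' localized gain of structure) and biggest increase (maximum) per
#' region; ties break to the smallest start.
#'
#' @param windows data.frame from [window_deltas()].
#' @return List with rows `min` and `max` (or `NULL` when no windows).
#' @export
extreme_windows <- function(windows, tol = 1e-12) {
  if (nrow(windows) == 0) return(NULL)
  # tolerance guards against cumulative-sum rounding breaking exact ties
  lo <- min(windows$delta_mean)
  hi <- max(windows$delta_mean)
  i_min <- which(windows$delta_mean <= lo + tol)[1]
  i_max <- which(windows$delta_mean >= hi - tol)[1]
  list(min = windows[i_min, , drop = FALSE],
       max = windows[i_max, , drop = FALSE])
}

#' Extreme 5'UTR windows for a set of transcripts
#'
#' @param deltas named list of delta reactivity vectors.
#' @param transcripts annotation data.frame.
#' @inheritParams window_deltas
#' @param trim_nt 3' trim (irrelevant for the 5'UTR but kept for
#'   uniformity).
#' @return data.frame with one `min` and one `max` row per transcript that
#'   has at least one valid window: `transcript_id`, `which`, window
#'   columns, `utr5_length`.
#' @export
extreme_windows_set <- function(deltas, transcripts, width = 20, step = 1,
                                min_defined = 3, trim_nt = 125) {
  rows <- list()
  for (id in names(deltas)) {
    a <- transcripts[match(id, transcripts$transcript_id), ]
    if (is.na(a$transcript_id)) next
    span <- region_span(a$utr5_end, a$cds_end, a$length, "utr5", trim_nt)
    win <- window_deltas(deltas[[id]], span, width, step, min_defined)
    ext <- extreme_windows(win)
    if (is.null(ext)) next
    for (w in c("min", "max")) {
      r <- ext[[w]]
      r$transcript_id <- id
      r$which <- w
      r$utr5_length <- a$utr5_end
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0) {
    stop("no transcript yielded a valid window", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("transcript_id", "which", "start", "end", "width", "delta_mean",
          "n_defined", "rel_pos", "utr5_length")]
}

#' Binned relative positions of extreme windows, with a group test
#'
#' Bins the relative 5'UTR positions of extreme windows into `n_bins`
#' equal bins of `[0, 1]` and, when two groups are given, compares the
#' positions by an unpaired two-sided Wilcoxon rank test.
#'
#' @param rel_pos_a,rel_pos_b relative positions of the two groups
#'   (`rel_pos_b` optional).
#' @param n_bins number of bins (default 10).
#' @return List with `bins` (data.frame of per-group bin counts; `bin` is
#'   the 0-based bin index) and, for two groups, `test` (the
#'   `htest`) and `p`.
#' @export
position_bins <- function(rel_pos_a, rel_pos_b = NULL, n_bins = 10) {
  bin_of <- function(x) pmin(n_bins - 1L, as.integer(floor(x * n_bins)))
  tab <- function(x, g) {
    b <- factor(bin_of(x), levels = 0:(n_bins - 1L))
    data.frame(group = g, bin = 0:(n_bins - 1L),
               count = as.integer(table(b)), stringsAsFactors = FALSE)
  }
  bins <- tab(rel_pos_a, "a")
  out <- list(bins = bins)
  if (!is.null(rel_pos_b)) {
    out$bins <- rbind(bins, tab(rel_pos_b, "b"))
    out$test <- stats::wilcox.test(rel_pos_a, rel_pos_b)
    out$p <- out$test$p.value
  }
  out
}

#' GC content in sliding windows, binned by relative position
#'
#' GC fraction of every window of `width` nt (step `step`) within a
#' region, plus the per-transcript windows binned by relative position and
#' averaged across transcripts with a normal-approximation confidence
#' interval of the mean.
#'
#' @param sequences named character vector of transcript sequences.
#' @param transcripts annotation data.frame.
#' @param region region to scan (default `"utr5"`).
#' @param width,step window geometry (defaults 50 and 10 nt).
#' @param n_bins bins of relative position (default 25).
#' @param trim_nt 3' trim.
#' @param conf_level confidence level.
#' @return List with `windows` (data.frame: `transcript_id`, `start`
#'   (0-based), `gc`, `rel_pos`) and `profile` (data.frame: `bin`, `mean`,
#'   `ci_lo`, `ci_hi`, `n`).
#' @export
gc_windows <- function(sequences, transcripts, region = "utr5",
                       width = 50, step = 10, n_bins = 25, trim_nt = 125,
                       conf_level = 0.95) {
  rows <- list()
  for (id in names(sequences)) {
    a <- transcripts[match(id, transcripts$transcript_id), ]
    if (is.na(a$transcript_id)) next
    span <- region_span(a$utr5_end, a$cds_end, a$length, region, trim_nt)
    if (is.null(span)) next
    Lr <- span[2] - span[1] + 1L
    if (Lr < width) next
    ch <- seq_chars(sequences[[id]])[span[1]:span[2]]
    isgc <- as.numeric(ch %in% c("G", "C"))
    cg <- cumsum(isgc)
    starts <- seq(0L, Lr - width, by = step)
    gc <- (cg[starts + width] - c(0, cg)[starts + 1]) / width
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = id, start = starts, gc = gc,
      rel_pos = (starts + width / 2) / Lr, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no region long enough for a window", call. = FALSE)
  win <- do.call(rbind, rows)

  # per-transcript bin means first, then across transcripts
  win$bin <- pmin(n_bins - 1L, as.integer(floor(win$rel_pos * n_bins)))
  per_tx <- stats::aggregate(gc ~ transcript_id + bin, data = win, FUN = mean)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  prof <- do.call(rbind, lapply(0:(n_bins - 1L), function(b) {
    v <- per_tx$gc[per_tx$bin == b]
    n <- length(v)
    m <- if (n > 0) mean(v) else NA_real_
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(bin = b, mean = m,
               ci_lo = m - z * se, ci_hi = m + z * se, n = n)
  }))
  list(windows = win[, c("transcript_id", "start", "gc", "rel_pos")],
       profile = prof)
}

#' Length-matched control group
#'
#' Greedy nearest-neighbour matching on log length, without replacement,
#' processing the target in random order under a fixed seed; used to build
#' e.g. an independent-group control matched by 5'UTR length.
#'
#' @param target_lengths named numeric vector (the group to match).
#' @param pool_lengths named numeric vector (candidates).
#' @param seed integer seed for the processing order.
#' @param tolerance warn when a matched pair's `|log2 ratio|` exceeds this
#'   (default 1, i.e. a twofold length difference).
#' @return data.frame: `target_id`, `match_id`, `target_length`,
#'   `match_length`, `log2_ratio`.
#' @export
length_match <- function(target_lengths, pool_lengths, seed = 1,
                         tolerance = 1) {
  if (length(pool_lengths) < length(target_lengths)) {
    stop("candidate pool smaller than target group", call. = FALSE)
  }
  ord <- with_seed(seed, sample.int(length(target_lengths)))
  remaining <- pool_lengths
  rows <- vector("list", length(target_lengths))
  for (k in seq_along(ord)) {
    i <- ord[k]
    lt <- log(target_lengths[i])
    j <- which.min(abs(log(remaining) - lt))
    rows[[k]] <- data.frame(
      target_id = names(target_lengths)[i],
      match_id = names(remaining)[j],
      target_length = target_lengths[[i]],
      match_length = remaining[[j]],
      log2_ratio = (lt - log(remaining[[j]])) / log(2),
      stringsAsFactors = FALSE)
    remaining <- remaining[-j]
  }
  out <- do.call(rbind, rows)
  bad <- sum(abs(out$log2_ratio) > tolerance)
  if (bad > 0) {
    warning(bad, " matched pairs exceed the length-ratio tolerance",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Correlate per-transcript extreme window deltas with a feature
#'
#' Pearson correlation (with two-sided p) between, e.g., the most negative
#' 20-nt window delta per transcript and its 5'UTR length or GC content.
#'
#' @param extreme_delta numeric vector (one value per transcript).
#' @param feature numeric vector of the same length.
#' @return List with `r`, `p`, `n` and the underlying `htest`.
#' @export
correlate_extreme_vs_feature <- function(extreme_delta, feature) {
  ok <- !is.na(extreme_delta) & !is.na(feature)
  if (sum(ok) < 3) stop("need at least 3 transcripts", call. = FALSE)
  if (stats::sd(feature[ok]) == 0 || stats::sd(extreme_delta[ok]) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(extreme_delta[ok], feature[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), test = ct)
}

#' Width sweep of extreme-window statistics
#'
#' Repeats the extreme-window analysis over a set of widths and, when two
#' groups are supplied, reports the raw (uncorrected) unpaired Wilcoxon p
#' value per width for both the most-decreasing and most-increasing
#' windows.
#'
#' @param deltas named list of delta vectors.
#' @param transcripts annotation data.frame.
#' @param group_a,group_b transcript id groups.
#' @param widths window widths (default `c(5, 10, 15, 20, 25, 30, 40, 50)`).
#' @inheritParams extreme_windows_set
#' @return data.frame: `width`, `which`, `median_a`, `median_b`, `p`.
#' @export
width_sweep <- function(deltas, transcripts, group_a, group_b,
                        widths = c(5, 10, 15, 20, 25, 30, 40, 50),
                        step = 1, min_defined = 3, trim_nt = 125) {
  rows <- list()
  for (w in widths) {
    ext <- extreme_windows_set(deltas, transcripts, width = w, step = step,
                               min_defined = min_defined, trim_nt = trim_nt)
    for (side in c("min", "max")) {
      e <- ext[ext$which == side, ]
      a <- e$delta_mean[e$transcript_id %in% group_a]
      b <- e$delta_mean[e$transcript_id %in% group_b]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        stats::wilcox.test(a, b)$p.value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        width = w, which = side,
        median_a = stats::median(a), median_b = stats::median(b), p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
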