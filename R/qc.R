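seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Per-transcript coverage score
#'
#' Coverage is the number of RT stops at A/C positions divided by
#' (transcript length x AC content), i.e. stops per A/C nucleotide.  A
#' 2000-nt transcript with 50% AC content and 1000 stops at A/C positions
#' has coverage 1.
#'
#' @param counts integer stop-count vector.
#' @param sequence transcript sequence (same length).
#' @return Coverage score (numeric).
#' @export
coverage_score <- function(counts, sequence) {
  ch <- seq_chars(sequence)
  if (length(counts) != length(ch)) {
    stop("counts and sequence lengths differ", call. = FALSE)
  }
  ac <- ch %in% c("A", "C")
  if (!any(ac)) stop("transcript has no A or C positions", call. = FALSE)
  L <- length(ch)
  f_ac <- sum(ac) / L
  sum(counts[ac]) / (L * f_ac)
}

#' 5' end coverage score
#'
#' Enrichment of stop signal in the 5'-most `ceiling(L/n)` positions,
#' normalized so a uniform stop distribution scores 1:
#' `score = n * stops(5' segment) / total stops`.  Used to flag transcripts
#' whose annotated 5' end has no read support (score below ~1.5 on DMS(-)
#' samples suggests a mis-annotated transcription start site).
#'
#' @param counts integer stop-count vector.
#' @param n number of segments (default 10; the score uses the first).
#' @return Score in `[0, n]`, or `NA` when the track has no stops.
#' @export
end_coverage_score <- function(counts, n = 10) {
  L <- length(counts)
  if (n < 2 || L < n) stop("need n >= 2 and track length >= n", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  seg <- ceiling(L / n)
  n * sum(counts[seq_len(seg)]) / total
}

#' Stop specificity and per-base composition
#'
#' Fraction of RT stops attributed to each base, in modified-base
#' coordinates.  In a DMS(+) library most stops should fall on A/C.
#'
#' @param counts integer stop-count vector.
#' @param sequence transcript sequence.
#' @return List with `composition` (named fractions over A/C/G/T summing
#'   to 1) and `specificity` (A+C fraction).
#' @export
stop_specificity <- function(counts, sequence) {
  ch <- seq_chars(sequence)
  total <- sum(counts)
  if (total == 0) stop("no stops: specificity undefined", call. = FALSE)
  comp <- vapply(c("A", "C", "G", "T"),
                 function(b) sum(counts[ch == b]) / total, numeric(1))
  list(composition = comp, specificity = comp[["A"]] + comp[["C"]])
}

#' Ligation-bias check
#'
#' Composition of the nucleotide immediately 3' of each stop (the first
#' sequenced nucleotide in the library design), compared against the
#' overall base composition of the same transcripts.  A large deviation
#' would indicate that the ligation step prefers particular bases.
#'
#' @param tracks named list of count vectors (one sample).
#' @param sequences named character vector of sequences.
#' @return List with `composition` (stop-adjacent base fractions),
#'   `background` (overall base composition) and `max_deviation`.
#' @export
ligation_bias <- function(tracks, sequences) {
  bases <- c("A", "C", "G", "T")
  adj <- setNames(numeric(4), bases)
  bg <- setNames(numeric(4), bases)
  for (id in names(tracks)) {
    ch <- seq_chars(sequences[[id]])
    counts <- tracks[[id]]
    L <- length(ch)
    if (L < 2) next
    nb <- ch[-1]                      # 3' neighbor of positions 1..L-1
    cc <- counts[-L]                  # stops with a defined 3' neighbor
    for (b in bases) {
      adj[b] <- adj[b] + sum(cc[nb == b])
      bg[b] <- bg[b] + sum(ch == b)
    }
  }
  if (sum(adj) == 0) stop("no stops with a defined 3' neighbor", call. = FALSE)
  adj <- adj / sum(adj)
  bg <- bg / sum(bg)
  list(composition = adj, background = bg,
       max_deviation = max(abs(adj - bg)))
}

#' Analyzable span after 3' trimming
#'
#' The 3'-most `trim_nt` nucleotides are excluded from every downstream
#' statistic (coordinates are preserved, positions are only masked).
#' Transcripts no longer than `trim_nt` are excluded entirely.
#'
#' @param length transcript length (nt).
#' @param trim_nt nucleotides to mask at the 3' end (default 125).
#' @return Length of the analyzable 5' span `[0, length - trim_nt)`, or
#'   `NA` if the transcript is excluded.
#' @export
analyzable_span <- function(length, trim_nt = 125) {
  if (trim_nt < 0) stop("trim_nt must be nonnegative", call. = FALSE)
  ifelse(length > trim_nt, as.integer(length - trim_nt), NA_integer_)
}

#' Coverage filter across replicates
#'
#' A transcript passes when its coverage score is at least `threshold` in
#' every supplied DMS(+) sample (all replicates of both conditions).
#' Idempotent: filtering a filtered set changes nothing.
#'
#' @param rtsc named list of samples, each a named list of count vectors.
#' @param sequences named character vector of sequences.
#' @param samples names of the DMS(+) samples to require.
#' @param threshold minimum coverage (default 1).
#' @return Character vector of passing transcript ids.
#' @export
filter_by_coverage <- function(rtsc, sequences, samples = names(rtsc),
                               threshold = 1) {
  ids <- names(rtsc[[samples[1]]])
  pass <- vapply(ids, function(id) {
    all(vapply(samples, function(s) {
      coverage_score(rtsc[[s]][[id]], sequences[[id]]) >= threshold
    }, logical(1)))
  }, logical(1))
  ids[pass]
}

#' 5' end coverage filter
#'
#' A transcript passes when its 5' end coverage score is at least
#' `threshold` in every supplied sample (by default this is applied to the
#' DMS(-) samples of both conditions).  Tracks with zero stops score `NA`
#' and fail.
#'
#' @inheritParams filter_by_coverage
#' @param n segment count for [end_coverage_score()].
#' @param threshold minimum score (default 1.5).
#' @return Character vector of passing transcript ids.
#' @export
filter_by_end_coverage <- function(rtsc, samples = names(rtsc),
                                   threshold = 1.5, n = 10) {
  ids <- names(rtsc[[samples[1]]])
  pass <- vapply(ids, function(id) {
    sc <- vapply(samples, function(s) {
      end_coverage_score(rtsc[[s]][[id]], n = n)
    }, numeric(1))
    all(!is.na(sc) & sc >= threshold)
  }, logical(1))
  ids[pass]
}

#' Replicate correlation of stop counts
#'
#' Correlation of pooled per-position stop counts between every pair of
#' the given samples, across the whole transcript set.
#'
#' @param rtsc named list of samples (named lists of count vectors).
#' @param samples sample names to compare (default all).
#' @param method correlation method passed to [stats::cor()].
#' @return data.frame: `sample_a`, `sample_b`, `correlation`.
#' @export
replicate_correlation <- function(rtsc, samples = names(rtsc),
                                  method = "pearson") {
  pooled <- lapply(samples, function(s) unlist(rtsc[[s]], use.names = FALSE))
  names(pooled) <- samples
  rows <- list()
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j <= i) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = samples[i], sample_b = samples[j],
        correlation = stats::cor(pooled[[i]], pooled[[j]], method = method),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Quality-control report for a set of samples
#'
#' @param rtsc named list of samples (named lists of count vectors).
#' @param sequences named character vector of sequences.
#' @param end_n segment count for the 5' end coverage score.
#' @return List with `samples` (data.frame: per-sample specificity,
#'   base composition, ligation-bias deviation, total stops) and
#'   `transcripts` (data.frame: per sample x transcript coverage and 5'
#'   end coverage scores).
#' @export
qc_report <- function(rtsc, sequences, end_n = 10) {
  srows <- lapply(names(rtsc), function(s) {
    tracks <- rtsc[[s]]
    total <- sum(vapply(tracks, sum, numeric(1)))
    agg <- setNames(numeric(4), c("A", "C", "G", "T"))
    for (id in names(tracks)) {
      ch <- seq_chars(sequences[[id]])
      for (b in names(agg)) agg[b] <- agg[b] + sum(tracks[[id]][ch == b])
    }
    comp <- if (total > 0) agg / total else agg * NA
    lb <- tryCatch(ligation_bias(tracks, sequences)$max_deviation,
                   error = function(e) NA_real_)
    data.frame(sample = s, total_stops = total,
               frac_A = comp[["A"]], frac_C = comp[["C"]],
               frac_G = comp[["G"]], frac_T = comp[["T"]],
               specificity = comp[["A"]] + comp[["C"]],
               ligation_max_deviation = lb,
               stringsAsFactors = FALSE)
  })
  trows <- lapply(names(rtsc), function(s) {
    tracks <- rtsc[[s]]
    data.frame(
      sample = s,
      transcript_id = names(tracks),
      coverage = vapply(names(tracks), function(id) {
        coverage_score(tracks[[id]], sequences[[id]])
      }, numeric(1)),
      end_coverage = vapply(names(tracks), function(id) {
        end_coverage_score(tracks[[id]], n = end_n)
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  list(samples = do.call(rbind, srows), transcripts = do.call(rbind, trows))
}
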