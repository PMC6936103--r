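.MOTIFS <- c(GGC4 = "GGCGGCGGCGGC", GCC4 = "GCCGCCGCCGCC")

#' Find (GGC)4 / (GCC)4 motif occurrences in a 5'UTR
#'
#' All exact, possibly overlapping, occurrences of the 12-nt motif fully
#' inside the 5'UTR span.  (GGC)4 has G-quadruplex-forming potential; its
#' reverse complement (GCC)4 is the non-quadruplex control.
#'
#' @param sequence transcript sequence.
#' @param utr5_end 0-based half-open 5'UTR boundary.
#' @param motif `"GGC4"` or `"GCC4"`.
#' @return data.frame: `motif`, `start`, `end` (0-based half-open,
#'   transcript coordinates).
#' @export
find_motif_hits <- function(sequence, utr5_end, motif = c("GGC4", "GCC4")) {
  motif <- match.arg(motif)
  pat <- .MOTIFS[[motif]]
  k <- nchar(pat)
  utr <- substr(sequence, 1, utr5_end)
  starts <- integer(0)
  if (nchar(utr) >= k) {
    for (s in 1:(nchar(utr) - k + 1)) {
      if (substr(utr, s, s + k - 1) == pat) starts <- c(starts, s - 1L)
    }
  }
  data.frame(motif = rep(motif, length(starts)),
             start = starts, end = starts + k,
             stringsAsFactors = FALSE)
}

#' Motif hits across a transcript set, one random hit per 5'UTR
#'
#' Scans every transcript for a motif and keeps at most one occurrence per
#' 5'UTR, selected uniformly at random under a fixed seed.
#'
#' @param sequences named character vector.
#' @param transcripts annotation data.frame.
#' @param motif `"GGC4"` or `"GCC4"`.
#' @param seed integer seed for the per-UTR selection.
#' @return data.frame: `transcript_id`, `motif`, `start`, `end`,
#'   `n_hits` (occurrences the selection was made from).
#' @export
motif_hits_set <- function(sequences, transcripts, motif = c("GGC4", "GCC4"),
                           seed = 1) {
  motif <- match.arg(motif)
  rows <- list()
  for (id in names(sequences)) {
    a <- transcripts[match(id, transcripts$transcript_id), ]
    if (is.na(a$transcript_id)) next
    hits <- find_motif_hits(sequences[[id]], a$utr5_end, motif)
    if (nrow(hits) == 0) next
    pick <- with_seed(substream_seed(seed, 7L, match(id, names(sequences))),
                      sample.int(nrow(hits), 1))
    h <- hits[pick, ]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = id, motif = motif, start = h$start, end = h$end,
      n_hits = nrow(hits), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      n_hits = integer(0)))
  }
  do.call(rbind, rows)
}

#' UTR-normalized motif (delta) reactivity
#'
#' Mean (delta) reactivity over the motif's defined positions minus the
#' mean over the whole 5'UTR's defined positions.  For GGC/GCC repeats the
#' defined positions are the cytosines (DMS does not report on G), so a
#' (GGC)4 value rests on 4 C's and a (GCC)4 value on 8 C's per hit.
#' Invariant to adding a constant to the whole profile.
#'
#' @param profile reactivity or delta vector.
#' @param start,end motif interval (0-based half-open).
#' @param utr5_end 0-based half-open 5'UTR boundary.
#' @return Normalized value, or `NA` when the motif (or UTR) has no
#'   defined position.
#' @export
normalized_motif_stat <- function(profile, start, end, utr5_end) {
  motif_vals <- profile[(start + 1L):end]
  utr_vals <- profile[seq_len(utr5_end)]
  if (all(is.na(motif_vals)) || all(is.na(utr_vals))) return(NA_real_)
  mean(motif_vals, na.rm = TRUE) - mean(utr_vals, na.rm = TRUE)
}

#' Normalized motif reactivity table for both motifs
#'
#' Combines motif discovery, per-UTR random selection and UTR-normalized
#' reactivity / delta reactivity into the per-motif table used for group
#' comparisons (unpaired two-sided Wilcoxon tests between motifs or
#' between dependency groups).
#'
#' @param sequences named character vector.
#' @param transcripts annotation data.frame.
#' @param reactivity named list of (treated-condition) reactivity vectors.
#' @param delta named list of delta vectors.
#' @param seed selection seed.
#' @return data.frame: `transcript_id`, `motif`, `start`, `end`,
#'   `normalized_react`, `normalized_delta`.
#' @export
motif_table <- function(sequences, transcripts, reactivity, delta,
                        seed = 1) {
  rows <- list()
  for (m in names(.MOTIFS)) {
    hits <- motif_hits_set(sequences, transcripts, m, seed)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      a <- transcripts[match(h$transcript_id, transcripts$transcript_id), ]
      pr <- reactivity[[h$transcript_id]]
      dl <- delta[[h$transcript_id]]
      nr <- if (!is.null(pr)) {
        normalized_motif_stat(pr, h$start, h$end, a$utr5_end)
      } else NA_real_
      nd <- if (!is.null(dl)) {
        normalized_motif_stat(dl, h$start, h$end, a$utr5_end)
      } else NA_real_
      if (is.na(nr) && is.na(nd)) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = h$transcript_id, motif = m,
        start = h$start, end = h$end,
        normalized_react = nr, normalized_delta = nd,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      normalized_react = numeric(0),
                      normalized_delta = numeric(0)))
  }
  do.call(rbind, rows)
}
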