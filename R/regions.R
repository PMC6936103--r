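#' Region span within a transcript
#'
#' Returns the 1-based inclusive index range of a region, respecting the
#' 3' trim (the trimmed tail of the 3'UTR is excluded; the remaining part
#' is the analyzed 3' region).  The three regions partition the
#' untrimmed transcript exactly.
#'
#' @param utr5_end,cds_end 0-based half-open region boundaries.
#' @param length transcript length.
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @param trim_nt 3' trim (applies to the 3'UTR only; default 125).
#' @return Integer `c(start, end)` (1-based inclusive) or `NULL` when the
#'   region is empty after trimming.
#' @export
region_span <- function(utr5_end, cds_end, length, region, trim_nt = 125) {
  span <- switch(region,
    utr5 = c(1L, utr5_end),
    cds  = c(utr5_end + 1L, cds_end),
    utr3 = c(cds_end + 1L, length - trim_nt),
    stop("unknown region: ", region, call. = FALSE)
  )
  if (span[2] < span[1]) return(NULL)
  as.integer(span)
}

#' Select the most abundant transcript per gene
#'
#' Downstream analysis is carried out at the gene level on the most
#' abundant transcript; ties break to the lexicographically smallest
#' transcript id.  Transcripts without an abundance are excluded (with a
#' message).
#'
#' @param transcripts data.frame with `transcript_id`, `gene_id`,
#'   `abundance`.
#' @return The input restricted to one row per gene.
#' @export
select_representative <- function(transcripts) {
  has <- !is.na(transcripts$abundance)
  if (any(!has)) {
    message("excluding ", sum(!has), " transcripts without abundance")
    transcripts <- transcripts[has, ]
  }
  ord <- order(transcripts$gene_id, -transcripts$abundance,
               transcripts$transcript_id)
  x <- transcripts[ord, ]
  x[!duplicated(x$gene_id), , drop = FALSE]
}

#' Mean (delta) reactivity of a region
#'
#' Arithmetic mean over defined positions within the region span.
#'
#' @param profile reactivity or delta vector (NA = undefined).
#' @param span 1-based inclusive `c(start, end)` from [region_span()].
#' @return Mean, or `NA` when the region has no defined position.
#' @export
region_average <- function(profile, span) {
  if (is.null(span)) return(NA_real_)
  v <- profile[span[1]:span[2]]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Gini coefficient of reactivity dispersion
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))` over defined values.  Zero
#' indicates perfectly even reactivity; one indicates reactivity
#' concentrated on a vanishing fraction of positions.  Undefined positions
#' are excluded, not zero-filled (zero-filling would inflate inequality as
#' a function of GC content).
#'
#' @param x nonnegative values (NA dropped).
#' @return Gini coefficient in `[0, 1]`, or `NA` for singleton/all-zero
#'   input.
#' @export
gini <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || all(x == 0)) return(NA_real_)
  if (any(x < 0)) stop("gini requires nonnegative values", call. = FALSE)
  n <- length(x)
  s <- sort(x)
  # identical to the mean-absolute-difference definition, O(n log n)
  (2 * sum(seq_len(n) * s) / (n * sum(s))) - (n + 1) / n
}

#' Map a 0-based region offset to a 0-based bin index
#'
#' Position `p` in a region of length `L` maps to bin `floor(p * B / L)`;
#' bins never span region boundaries.
#'
#' @param p 0-based offset(s) within the region.
#' @param n_bins number of bins `B`.
#' @param region_length region length `L`.
#' @return Integer bin index in `[0, B)`.
#' @export
bin_index <- function(p, n_bins, region_length) {
  as.integer(floor(p * n_bins / region_length))
}

bin_one_profile <- function(profile, utr5_end, cds_end, length,
                            scheme = c(25, 50, 25), trim_nt = 125) {
  regions <- c("utr5", "cds", "utr3")
  out <- rep(NA_real_, sum(scheme))
  offset <- 0L
  for (k in seq_along(regions)) {
    span <- region_span(utr5_end, cds_end, length, regions[k], trim_nt)
    if (!is.null(span)) {
      v <- profile[span[1]:span[2]]
      Lr <- span[2] - span[1] + 1L
      bins <- bin_index(seq_len(Lr) - 1L, scheme[k], Lr)
      for (b in unique(bins)) {
        vals <- v[bins == b]
        if (!all(is.na(vals))) out[offset + b + 1L] <- mean(vals, na.rm = TRUE)
      }
    }
    offset <- offset + scheme[k]
  }
  out
}

#' Per-transcript binned profiles
#'
#' Rescales every transcript's regions to a fixed bin scheme (default 25
#' 5'UTR + 50 CDS + 25 3'UTR bins); each bin holds the mean over its
#' defined positions.  Transcripts whose analyzed 5'UTR, CDS or 3' region
#' is shorter than `min_region_len` are excluded.
#'
#' @param profiles named list of (delta) reactivity vectors.
#' @param transcripts annotation data.frame (`transcript_id`, `utr5_end`,
#'   `cds_end`, `length`).
#' @param scheme bins per region.
#' @param min_region_len minimal analyzed region length (default 100).
#' @param trim_nt 3' trim.
#' @return Matrix (transcripts x bins) with attributes `region` and `bin`
#'   (0-based bin index within its region) describing the columns.
#' @export
bin_profiles <- function(profiles, transcripts, scheme = c(25, 50, 25),
                         min_region_len = 100, trim_nt = 125) {
  ann <- transcripts[match(names(profiles), transcripts$transcript_id), ]
  keep <- vapply(seq_along(profiles), function(i) {
    a <- ann[i, ]
    if (is.na(a$transcript_id)) return(FALSE)
    all(vapply(c("utr5", "cds", "utr3"), function(r) {
      span <- region_span(a$utr5_end, a$cds_end, a$length, r, trim_nt)
      !is.null(span) && (span[2] - span[1] + 1L) >= min_region_len
    }, logical(1)))
  }, logical(1))
  ids <- names(profiles)[keep]
  if (length(ids) == 0) stop("no transcripts satisfy min_region_len", call. = FALSE)
  m <- t(vapply(ids, function(id) {
    a <- ann[match(id, ann$transcript_id), ]
    bin_one_profile(profiles[[id]], a$utr5_end, a$cds_end, a$length,
                    scheme, trim_nt)
  }, numeric(sum(scheme))))
  rownames(m) <- ids
  attr(m, "region") <- rep(c("utr5", "cds", "utr3"), scheme)
  attr(m, "bin") <- unlist(lapply(scheme, function(b) 0:(b - 1)))
  m
}

bin_ci <- function(est, se, df, level = 0.95) {
  half <- stats::qt(1 - (1 - level) / 2, df) * se
  cbind(lo = est - half, hi = est + half)
}

#' Paired binned meta-profile of two conditions
#'
#' Group means per bin (each transcript weighted equally), the per-bin
#' delta (treated minus control) and its 95% confidence limits from a
#' paired two-sided t test across transcripts.
#'
#' @param control_profiles,treated_profiles named lists of averaged
#'   reactivity vectors (same transcripts).
#' @param transcripts annotation data.frame.
#' @inheritParams bin_profiles
#' @param conf_level confidence level for the per-bin interval.
#' @return data.frame: `region`, `bin` (0-based), `mean_control`,
#'   `mean_treated`, `delta`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
metaprofile_paired <- function(control_profiles, treated_profiles,
                               transcripts, scheme = c(25, 50, 25),
                               min_region_len = 100, trim_nt = 125,
                               conf_level = 0.95) {
  ids <- intersect(names(control_profiles), names(treated_profiles))
  mc <- bin_profiles(control_profiles[ids], transcripts, scheme,
                     min_region_len, trim_nt)
  mt <- bin_profiles(treated_profiles[ids], transcripts, scheme,
                     min_region_len, trim_nt)
  stopifnot(identical(rownames(mc), rownames(mt)))
  nb <- ncol(mc)
  res <- lapply(seq_len(nb), function(j) {
    d <- mt[, j] - mc[, j]
    ok <- !is.na(d)
    n <- sum(ok)
    est <- mean(d[ok])
    if (n >= 2 && stats::sd(d[ok]) > 0) {
      tt <- stats::t.test(mt[ok, j], mc[ok, j], paired = TRUE,
                          conf.level = conf_level)
      c(est = est, lo = tt$conf.int[1], hi = tt$conf.int[2],
        p = tt$p.value, n = n)
    } else {
      c(est = est, lo = est, hi = est, p = NA_real_, n = n)
    }
  })
  res <- do.call(rbind, res)
  data.frame(region = attr(mc, "region"), bin = attr(mc, "bin"),
             mean_control = colMeans(mc, na.rm = TRUE),
             mean_treated = colMeans(mt, na.rm = TRUE),
             delta = res[, "est"], ci_lo = res[, "lo"], ci_hi = res[, "hi"],
             p = res[, "p"], n = as.integer(res[, "n"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group binned meta-profile
#'
#' Compares two transcript groups (for example helicase-dependent versus
#' independent, or high versus low translational efficiency) on the same
#' kind of profile; per-bin confidence limits come from an unpaired
#' two-sided t test.
#'
#' @param profiles named list of (delta) reactivity vectors covering both
#'   groups.
#' @param group_a,group_b transcript ids of the two groups.
#' @param transcripts annotation data.frame.
#' @inheritParams metaprofile_paired
#' @return data.frame: `region`, `bin`, `mean_a`, `mean_b`, `diff`
#'   (a minus b), `ci_lo`, `ci_hi`, `p`, `n_a`, `n_b`.
#' @export
metaprofile_groups <- function(profiles, group_a, group_b, transcripts,
                               scheme = c(25, 50, 25), min_region_len = 100,
                               trim_nt = 125, conf_level = 0.95) {
  ma <- bin_profiles(profiles[intersect(group_a, names(profiles))],
                     transcripts, scheme, min_region_len, trim_nt)
  mb <- bin_profiles(profiles[intersect(group_b, names(profiles))],
                     transcripts, scheme, min_region_len, trim_nt)
  nb <- ncol(ma)
  res <- lapply(seq_len(nb), function(j) {
    a <- ma[, j][!is.na(ma[, j])]
    b <- mb[, j][!is.na(mb[, j])]
    est <- mean(a) - mean(b)
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b, conf.level = conf_level)
      c(est = est, lo = tt$conf.int[1], hi = tt$conf.int[2], p = tt$p.value,
        na = length(a), nb = length(b))
    } else {
      c(est = est, lo = est, hi = est, p = NA_real_,
        na = length(a), nb = length(b))
    }
  })
  res <- do.call(rbind, res)
  data.frame(region = attr(ma, "region"), bin = attr(ma, "bin"),
             mean_a = colMeans(ma, na.rm = TRUE),
             mean_b = colMeans(mb, na.rm = TRUE),
             diff = res[, "est"], ci_lo = res[, "lo"], ci_hi = res[, "hi"],
             p = res[, "p"], n_a = as.integer(res[, "na"]),
             n_b = as.integer(res[, "nb"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Terminal positionwise profile of a region
#'
#' Mean (delta) reactivity per offset over the first or last `span`
#' nucleotides of a region, across transcripts.  Transcripts whose region
#' is shorter than `span` are skipped.
#'
#' @param profiles named list of profile vectors.
#' @param transcripts annotation data.frame.
#' @param region `"utr5"`, `"cds"` or `"utr3"`.
#' @param end `"first"` or `"last"`.
#' @param span number of terminal nucleotides (60 for end profiles, 20 for
#'   the short start-codon-proximal contrast).
#' @param trim_nt 3' trim.
#' @return data.frame: `offset` (0-based from the region end chosen),
#'   `mean`, `n` (defining transcripts per offset).
#' @export
terminal_profile <- function(profiles, transcripts, region = "utr5",
                             end = c("last", "first"), span = 60,
                             trim_nt = 125) {
  end <- match.arg(end)
  ann <- transcripts
  rows <- matrix(NA_real_, nrow = 0, ncol = span)
  for (id in names(profiles)) {
    a <- ann[match(id, ann$transcript_id), ]
    if (is.na(a$transcript_id)) next
    sp <- region_span(a$utr5_end, a$cds_end, a$length, region, trim_nt)
    if (is.null(sp) || (sp[2] - sp[1] + 1L) < span) next
    idx <- if (end == "first") sp[1]:(sp[1] + span - 1L) else (sp[2] - span + 1L):sp[2]
    rows <- rbind(rows, profiles[[id]][idx])
  }
  if (nrow(rows) == 0) {
    return(data.frame(offset = integer(0), mean = numeric(0), n = integer(0)))
  }
  data.frame(offset = 0:(span - 1L),
             mean = colMeans(rows, na.rm = TRUE),
             n = colSums(!is.na(rows)),
             stringsAsFactors = FALSE)
}
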