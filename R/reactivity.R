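#' Derive a normalized DMS reactivity profile
#'
#' Implements the canonical Structure-seq normalization of paired
#' DMS(-)/DMS(+) stop tracks.  At every defined position (A or C inside
#' the analyzable, untrimmed span) the raw signal is
#' `max(0, P_i - M_i)` where `P` and `M` are `ln(count + 1)` values, each
#' channel normalized to unit sum over the defined positions.  The raw
#' values are divided by a per-transcript scale - the mean of the
#' descending-sorted 2-8% quantile band of the raw values - and capped.
#' When a scale is supplied (the shared-scale workflow, in which the scale
#' generated for one reference replicate is reused for every other sample)
#' it is used verbatim.
#'
#' @param minus,plus integer stop-count vectors, DMS(-) and DMS(+).
#' @param sequence transcript sequence (same length).
#' @param scale optional externally supplied positive scale factor.
#' @param trim_nt nucleotides masked at the 3' end (default 125); masked
#'   positions take no part in sums, the scale, or the cap.
#' @param cap maximum reported reactivity (default 7).
#' @param norm_band quantile band (fractions of the descending sort) whose
#'   mean defines the scale; default `c(0.02, 0.08)`.
#' @return List with `reactivity` (numeric vector, `NA` at undefined
#'   positions) and `scale`, or `NULL` when the transcript is unscorable
#'   (no defined DMS(+) signal, or a nonpositive generated scale).
#' @export
derive_reactivity <- function(minus, plus, sequence, scale = NULL,
                              trim_nt = 125, cap = 7,
                              norm_band = c(0.02, 0.08)) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (length(minus) != L || length(plus) != L) {
    stop("track and sequence lengths differ", call. = FALSE)
  }
  span <- analyzable_span(L, trim_nt)
  if (is.na(span)) return(NULL)
  defined <- ch %in% c("A", "C") & seq_len(L) <= span
  if (!any(defined)) return(NULL)

  lp <- log(plus[defined] + 1)
  lm <- log(minus[defined] + 1)
  if (sum(lp) == 0) return(NULL)          # all-zero DMS(+): unscorable
  pn <- lp / sum(lp)
  mn <- if (sum(lm) > 0) lm / sum(lm) else rep(0, length(lm))
  raw <- pmax(0, pn - mn)

  if (is.null(scale)) {
    scale <- reactivity_scale(raw, norm_band)
    if (is.na(scale) || scale <= 0) return(NULL)
  }
  out <- rep(NA_real_, L)
  out[defined] <- pmin(cap, raw / scale)
  list(reactivity = out, scale = scale)
}

#' Scale factor from the 2-8% band of raw reactivities
#'
#' Mean of the values ranked within the `norm_band` quantile band of the
#' descending sort (at least the single top-ranked value).  Dividing by
#' this scale sets the band mean to 1.
#'
#' @param raw nonnegative raw reactivity values at defined positions.
#' @param norm_band lower/upper band fractions.
#' @return Positive scale, or `NA` when the band mean is nonpositive.
#' @export
reactivity_scale <- function(raw, norm_band = c(0.02, 0.08)) {
  n <- length(raw)
  if (n == 0) return(NA_real_)
  s <- sort(raw, decreasing = TRUE)
  lo <- floor(norm_band[1] * n) + 1
  hi <- max(lo, floor(norm_band[2] * n))
  m <- mean(s[lo:hi])
  if (!is.finite(m) || m <= 0) NA_real_ else m
}

#' Average reactivity profiles across replicates
#'
#' Positionwise arithmetic mean; a position is defined in the average only
#' where every replicate defines it.
#'
#' @param profiles list of numeric vectors of equal length (NA =
#'   undefined).
#' @return Numeric vector.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 1) stop("no profiles to average", call. = FALSE)
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("profiles have different lengths", call. = FALSE)
  }
  m <- do.call(cbind, profiles)
  out <- rowMeans(m)
  out[apply(m, 1, anyNA)] <- NA_real_
  out
}

#' Average a set of per-sample profiles per transcript
#'
#' @param profile_sets list of samples, each a named list of profiles;
#'   every sample must cover the same transcripts.
#' @return Named list of averaged profiles.
#' @export
average_replicates <- function(profile_sets) {
  ids <- Reduce(intersect, lapply(profile_sets, names))
  if (length(ids) == 0) stop("no shared transcripts across replicates", call. = FALSE)
  setNames(lapply(ids, function(id) {
    average_profiles(lapply(profile_sets, `[[`, id))
  }), ids)
}

#' Delta reactivity (treated minus control)
#'
#' `delta_i = treated_i - control_i` where both are defined.  A negative
#' value indicates decreased reactivity and therefore increased structure
#' under treatment; this sign convention is preserved in all downstream
#' outputs.
#'
#' @param treated,control averaged reactivity vectors for one transcript.
#' @return Numeric delta vector (NA where either input is undefined).
#' @export
delta_reactivity <- function(treated, control) {
  if (length(treated) != length(control)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  treated - control
}

#' Derive reactivities for all transcripts of all replicates
#'
#' Convenience wrapper for the shared-scale workflow: scales are generated
#' from `scale_from` (default the first control replicate) and reused for
#' every other sample, so all samples share one per-transcript scale.
#'
#' @param rtsc named list of samples (named lists of count vectors); the
#'   minus/plus pairing uses names `<condition>_minus_<r>` /
#'   `<condition>_plus_<r>`.
#' @param sequences named character vector.
#' @param ids transcripts to score (default all in the reference sample).
#' @param conditions condition prefixes (default control/hipp).
#' @param n_replicates replicates per condition.
#' @param scale_from sample pair used to generate the shared scale,
#'   `c(condition, replicate)`.
#' @inheritParams derive_reactivity
#' @return List with `profiles` (nested list:
#'   `profiles[[condition]][[replicate]][[transcript]]`), `scales` (named
#'   vector) and `unscorable` (ids dropped).
#' @export
derive_reactivity_set <- function(rtsc, sequences, ids = NULL,
                                  conditions = c("control", "hipp"),
                                  n_replicates = 3,
                                  scale_from = c("control", 1),
                                  trim_nt = 125, cap = 7,
                                  norm_band = c(0.02, 0.08)) {
  ref_minus <- rtsc[[sprintf("%s_minus_%s", scale_from[1], scale_from[2])]]
  ref_plus <- rtsc[[sprintf("%s_plus_%s", scale_from[1], scale_from[2])]]
  if (is.null(ref_minus) || is.null(ref_plus)) {
    stop("reference sample for the shared scale not found", call. = FALSE)
  }
  if (is.null(ids)) ids <- names(ref_plus)

  scales <- setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    r <- derive_reactivity(ref_minus[[id]], ref_plus[[id]], sequences[[id]],
                           trim_nt = trim_nt, cap = cap, norm_band = norm_band)
    if (!is.null(r)) scales[[id]] <- r$scale
  }
  scorable <- names(scales)[!is.na(scales)]
  unscorable <- setdiff(ids, scorable)

  profiles <- lapply(conditions, function(cond) {
    lapply(seq_len(n_replicates), function(r) {
      minus <- rtsc[[sprintf("%s_minus_%d", cond, r)]]
      plus <- rtsc[[sprintf("%s_plus_%d", cond, r)]]
      out <- setNames(vector("list", length(scorable)), scorable)
      drop <- character(0)
      for (id in scorable) {
        pr <- derive_reactivity(minus[[id]], plus[[id]], sequences[[id]],
                                scale = scales[[id]], trim_nt = trim_nt,
                                cap = cap, norm_band = norm_band)
        if (is.null(pr)) drop <- c(drop, id) else out[[id]] <- pr$reactivity
      }
      out[setdiff(scorable, drop)]
    })
  })
  names(profiles) <- conditions
  list(profiles = profiles, scales = scales[scorable], unscorable = unscorable)
}
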