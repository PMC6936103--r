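#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data
#' generator.  Defaults describe a DMS probing experiment of the
#' Structure-seq2 type on a transcriptome in which a subset of transcripts
#' depends on helicase activity for translation: three biological
#' replicates, single-hit DMS chemistry concentrated at A/C, a 5'-high GC
#' gradient within 5'UTRs, and treatment-induced localized loss of
#' accessibility (structure gain) near the 3' end of the 5'UTR in the
#' dependent subset, with a compensatory gain of accessibility elsewhere in
#' the same 5'UTR.
#'
#' Length distributions are named lists, e.g.
#' `list(dist = "lnorm", meanlog = log(200), sdlog = 0.6, min = 100, max = 3000)`;
#' supported `dist` values are `"lnorm"`, `"unif"` and `"fixed"` (which
#' takes a single `value`).  Draws are rounded and clipped into
#' `[min, max]`; region minima must be at least 100 nt.
#'
#' @param n_transcripts number of transcripts (one per gene).
#' @param seed integer master seed; fully determines all generator output.
#' @param utr5_length_dist,cds_length_dist,utr3_length_dist region length
#'   distributions (nt).  CDS lengths are rounded down to multiples of 3.
#' @param gc_utr5 GC fraction of the 5'UTR at its relative midpoint.
#' @param gc_gradient_slope linear decrease of 5'UTR GC fraction from the
#'   cap (relative position 0) to the CDS (relative position 1); the GC
#'   probability at relative position `r` is
#'   `gc_utr5 + gc_gradient_slope * (0.5 - r)`, clipped to `[0.2, 0.8]`.
#' @param gc_body GC fraction of CDS and 3'UTR.
#' @param frac_dep,frac_antidep fractions of transcripts labeled
#'   helicase-dependent and antidependent; the rest are independent.
#' @param remodel_width width (nt) of the injected accessibility-loss
#'   window.
#' @param remodel_depth accessibility units subtracted over the loss window
#'   (clipped at 0).
#' @param remodel_position_bias relative position in `[0, 1]` of the loss
#'   window midpoint within the 5'UTR for dependent transcripts (0.9 = near
#'   the CDS); independent and antidependent transcripts place their window
#'   uniformly at random.
#' @param remodel_position_jitter half-width of the uniform jitter applied
#'   to the dependent-window midpoint (relative units).
#' @param compensation_width_factor the compensatory accessibility-gain
#'   window is this many times `remodel_width` wide.
#' @param stops_per_transcript_mean mean total DMS(+) RT stops per
#'   transcript at unit abundance.
#' @param minus_depth_frac DMS(-) total stops as a fraction of the DMS(+)
#'   mean.
#' @param background_rate relative weight of a DMS-independent stop per
#'   nucleotide in the DMS(+) channel (accessibility contributes weight
#'   `accessibility` at A/C positions on top of this).
#' @param end_spike_frac fraction of DMS(-) stops concentrated at the first
#'   transcript position, emulating full-length cDNA stops at annotated 5'
#'   ends; this is what gives well-annotated transcripts a high 5' end
#'   coverage score.
#' @param abundance_sdlog sdlog of the mean-normalized lognormal transcript
#'   abundance; sequencing depth per transcript scales with abundance.
#' @param n_replicates biological replicates per sample.
#' @param te_shift log-units by which treatment shifts polysomal versus
#'   sub-polysomal expression in dependent genes (opposite sign for
#'   antidependent genes).
#' @param dispersion negative-binomial dispersion of expression counts
#'   (variance = mu + dispersion * mu^2).
#' @param polysome_mean,polysome_mean_sdlog lognormal parameters of the
#'   per-gene baseline expression.
#' @param poly_fraction fraction of a gene's RNA in the polysomal fraction
#'   under control conditions.
#' @param utis_mix proportion of genes with upstream translation
#'   initiation.
#' @param utis_upstream_frac expected fraction of TIS reads at upstream
#'   sites for genes with upstream initiation.
#' @param tis_reads_mean mean total TIS reads per gene.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_transcripts = 200,
                       seed = 1,
                       utr5_length_dist = list(dist = "lnorm", meanlog = log(200),
                                               sdlog = 0.6, min = 100, max = 3000),
                       cds_length_dist = list(dist = "lnorm", meanlog = log(900),
                                              sdlog = 0.4, min = 102, max = 9000),
                       utr3_length_dist = list(dist = "lnorm", meanlog = log(400),
                                               sdlog = 0.3, min = 250, max = 3000),
                       gc_utr5 = 0.55,
                       gc_gradient_slope = 0.2,
                       gc_body = 0.45,
                       frac_dep = 0.3,
                       frac_antidep = 0.05,
                       remodel_width = 20,
                       remodel_depth = 0.5,
                       remodel_position_bias = 0.9,
                       remodel_position_jitter = 0.1,
                       compensation_width_factor = 2,
                       stops_per_transcript_mean = 2000,
                       minus_depth_frac = 0.3,
                       background_rate = 0.02,
                       end_spike_frac = 0.2,
                       abundance_sdlog = 1.2,
                       n_replicates = 3,
                       te_shift = 1,
                       dispersion = 0.05,
                       polysome_mean = 500,
                       polysome_mean_sdlog = 1,
                       poly_fraction = 0.6,
                       utis_mix = 0.3,
                       utis_upstream_frac = 0.3,
                       tis_reads_mean = 2000) {
  cfg <- list(
    n_transcripts = n_transcripts, seed = seed,
    utr5_length_dist = utr5_length_dist, cds_length_dist = cds_length_dist,
    utr3_length_dist = utr3_length_dist,
    gc_utr5 = gc_utr5, gc_gradient_slope = gc_gradient_slope, gc_body = gc_body,
    frac_dep = frac_dep, frac_antidep = frac_antidep,
    remodel_width = remodel_width, remodel_depth = remodel_depth,
    remodel_position_bias = remodel_position_bias,
    remodel_position_jitter = remodel_position_jitter,
    compensation_width_factor = compensation_width_factor,
    stops_per_transcript_mean = stops_per_transcript_mean,
    minus_depth_frac = minus_depth_frac,
    background_rate = background_rate, end_spike_frac = end_spike_frac,
    abundance_sdlog = abundance_sdlog, n_replicates = n_replicates,
    te_shift = te_shift, dispersion = dispersion,
    polysome_mean = polysome_mean, polysome_mean_sdlog = polysome_mean_sdlog,
    poly_fraction = poly_fraction,
    utis_mix = utis_mix, utis_upstream_frac = utis_upstream_frac,
    tis_reads_mean = tis_reads_mean
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (!is.numeric(cfg$n_transcripts) || cfg$n_transcripts < 1) {
    stop_cfg("n_transcripts must be a positive count")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop_cfg("seed must be a single integer")
  }
  props <- c("frac_dep", "frac_antidep", "remodel_position_bias",
             "utis_mix", "utis_upstream_frac", "end_spike_frac",
             "poly_fraction", "minus_depth_frac")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) stop_cfg(paste(p, "must lie in [0, 1]"))
  }
  if (cfg$frac_dep + cfg$frac_antidep > 1) {
    stop_cfg("frac_dep + frac_antidep must not exceed 1")
  }
  for (d in c("utr5_length_dist", "cds_length_dist", "utr3_length_dist")) {
    spec <- cfg[[d]]
    if (!is.list(spec) || is.null(spec$dist)) stop_cfg(paste(d, "must name a distribution"))
    if (!spec$dist %in% c("lnorm", "unif", "fixed")) {
      stop_cfg(paste0(d, ": unknown distribution '", spec$dist, "'"))
    }
    if (spec$dist == "lnorm" && (is.null(spec$meanlog) || is.null(spec$sdlog) ||
                                 !is.finite(spec$meanlog) || spec$sdlog < 0)) {
      stop_cfg(paste(d, "lnorm needs finite meanlog and sdlog >= 0"))
    }
    if (spec$dist == "unif" && (is.null(spec$min) || is.null(spec$max) ||
                                spec$min > spec$max)) {
      stop_cfg(paste(d, "unif needs min <= max"))
    }
    if (spec$dist == "fixed" && is.null(spec$value)) {
      stop_cfg(paste(d, "fixed needs a value"))
    }
    min_len <- if (!is.null(spec$min)) spec$min else if (spec$dist == "fixed") spec$value else NA
    if (!is.na(min_len) && min_len < 100) {
      stop_cfg(paste(d, "region minimum length must be at least 100 nt"))
    }
  }
  if (cfg$n_replicates < 1) stop_cfg("n_replicates must be at least 1")
  if (cfg$remodel_width < 1) stop_cfg("remodel_width must be at least 1 nt")
  if (cfg$remodel_depth < 0) stop_cfg("remodel_depth must be nonnegative")
  if (cfg$dispersion < 0) stop_cfg("dispersion must be nonnegative")
  if (cfg$background_rate < 0) stop_cfg("background_rate must be nonnegative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts, seed", x$seed, "\n")
  cat("  labels: dep", x$frac_dep, "| antidep", x$frac_antidep,
      "| indep", 1 - x$frac_dep - x$frac_antidep, "\n")
  cat("  remodeling: width", x$remodel_width, "nt, depth", x$remodel_depth,
      ", dep position bias", x$remodel_position_bias, "\n")
  cat("  depth:", x$stops_per_transcript_mean, "DMS(+) stops/transcript,",
      x$n_replicates, "replicates\n")
  invisible(x)
}

draw_lengths <- function(n, spec) {
  x <- switch(spec$dist,
    lnorm = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    unif  = stats::runif(n, spec$min, spec$max),
    fixed = rep(spec$value, n)
  )
  x <- round(x)
  if (!is.null(spec$min)) x <- pmax(x, spec$min)
  if (!is.null(spec$max)) x <- pmin(x, spec$max)
  as.integer(x)
}
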