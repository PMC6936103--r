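#' Analysis parameters for the end-to-end pipeline
#'
#' Collects every tunable threshold of the analysis in one place, with the
#' standard values as defaults: coverage >= 1 in every DMS(+) replicate,
#' 5' end coverage >= 1.5 (n = 10) in the DMS(-) samples of both
#' conditions, 125-nt 3' trim, 25/50/25 meta-profile bins with a 100-nt
#' minimum region length, 20-nt extreme windows, reactivity cap 7 with the
#' 2-8% scaling band, and the dependency classifier's 0.1 prior with
#' 0.25/0.02 posterior thresholds.
#'
#' @param coverage_threshold minimum coverage per DMS(+) replicate.
#' @param end_coverage_threshold minimum 5' end coverage score.
#' @param end_n segment count of the 5' end coverage score.
#' @param trim_nt 3' trim (nt).
#' @param cap reactivity cap.
#' @param norm_band scaling quantile band.
#' @param scheme meta-profile bins per region.
#' @param min_region_len minimum analyzed region length for meta-profiles.
#' @param window_width extreme-window width (nt).
#' @param window_step window step (nt).
#' @param min_defined minimum defined positions per window.
#' @param prior_alt,post_threshold,indep_threshold classifier settings.
#' @param pseudocount TE / classifier pseudocount.
#' @return List of class `"pipeline_params"`.
#' @export
pipeline_params <- function(coverage_threshold = 1,
                            end_coverage_threshold = 1.5,
                            end_n = 10,
                            trim_nt = 125,
                            cap = 7,
                            norm_band = c(0.02, 0.08),
                            scheme = c(25, 50, 25),
                            min_region_len = 100,
                            window_width = 20,
                            window_step = 1,
                            min_defined = 3,
                            prior_alt = 0.1,
                            post_threshold = 0.25,
                            indep_threshold = 0.02,
                            pseudocount = 0.5) {
  p <- as.list(environment())
  class(p) <- "pipeline_params"
  p
}

#' Run the full differential-reactivity analysis
#'
#' Orchestrates the pipeline end to end: simulate (or read) the inputs,
#' apply the coverage and 5' end coverage filters, derive shared-scale
#' reactivities, average replicates, compute delta reactivity, and write
#' every figure-style output (meta-profile, extreme windows, motif table,
#' region statistics, dependency classification, QC report) plus a run
#' manifest.  Identical config and seed produce byte-identical outputs.
#'
#' @param config a [sim_config()] (ignored when `input_dir` is given).
#' @param outdir output directory.
#' @param params a [pipeline_params()].
#' @param input_dir optional directory of previously written inputs (as
#'   produced by [write_simulation()]); when given, inputs are read from
#'   disk instead of simulated in memory.
#' @return Invisibly, a list with the main result tables and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         params = pipeline_params(), input_dir = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(input_dir)) {
    sim <- simulate_structure_seq(config)
    input_dir <- file.path(outdir, "inputs")
    write_simulation(sim, input_dir)
  }
  ann_path <- file.path(input_dir, "annotation.tsv")
  fasta_path <- file.path(input_dir, "transcripts.fasta")
  transcripts <- read_annotation(ann_path)
  sequences <- read_transcript_fasta(fasta_path)
  rtsc_paths <- list.files(input_dir, pattern = "\\.rtsc$", full.names = TRUE)
  rtsc <- lapply(rtsc_paths, read_rtsc,
                 lengths = setNames(transcripts$length,
                                    transcripts$transcript_id))
  names(rtsc) <- sub("\\.rtsc$", "", basename(rtsc_paths))
  expression <- read_expression_csv(file.path(input_dir, "polysome.csv"))
  tis <- read_tis_csv(file.path(input_dir, "tis.csv"))

  n_rep <- length(grep("^control_plus_", names(rtsc)))
  plus_samples <- grep("_plus_", names(rtsc), value = TRUE)
  minus_samples <- grep("_minus_", names(rtsc), value = TRUE)

  counts <- c(input = nrow(transcripts))

  transcripts <- select_representative(transcripts)
  counts["representative"] <- nrow(transcripts)

  long_enough <- transcripts$length > params$trim_nt
  if (any(!long_enough)) {
    message("excluding ", sum(!long_enough),
            " transcripts not longer than the 3' trim")
  }
  transcripts <- transcripts[long_enough, ]
  counts["after_trim"] <- nrow(transcripts)

  restrict <- function(sample_set, ids) {
    lapply(sample_set, function(s) s[ids])
  }
  rtsc <- restrict(rtsc, transcripts$transcript_id)

  pass_cov <- filter_by_coverage(rtsc, sequences, plus_samples,
                                 params$coverage_threshold)
  counts["coverage_filter"] <- length(pass_cov)
  rtsc <- restrict(rtsc, pass_cov)

  pass_end <- filter_by_end_coverage(rtsc, minus_samples,
                                     params$end_coverage_threshold,
                                     params$end_n)
  counts["end_coverage_filter"] <- length(pass_end)
  rtsc <- restrict(rtsc, pass_end)

  rset <- derive_reactivity_set(
    rtsc, sequences, ids = pass_end,
    conditions = c("control", "hipp"), n_replicates = n_rep,
    scale_from = c("control", 1), trim_nt = params$trim_nt,
    cap = params$cap, norm_band = params$norm_band)
  counts["scorable"] <- length(rset$scales)

  avg_control <- average_replicates(rset$profiles$control)
  avg_hipp <- average_replicates(rset$profiles$hipp)
  ids <- intersect(names(avg_control), names(avg_hipp))
  delta <- setNames(lapply(ids, function(id) {
    delta_reactivity(avg_hipp[[id]], avg_control[[id]])
  }), ids)
  counts["averaged"] <- length(ids)

  write_scale(rset$scales, file.path(outdir, "shared.scale"))
  write_react(avg_control, file.path(outdir, "control_avg.react"))
  write_react(avg_hipp, file.path(outdir, "hipp_avg.react"))
  write_react(delta, file.path(outdir, "delta.react"))

  qc <- qc_report(rtsc, sequences, end_n = params$end_n)
  utils::write.csv(qc$samples, file.path(outdir, "qc_samples.csv"),
                   row.names = FALSE)
  utils::write.csv(qc$transcripts, file.path(outdir, "qc_transcripts.csv"),
                   row.names = FALSE)

  meta <- tryCatch(
    metaprofile_paired(avg_control[ids], avg_hipp[ids], transcripts,
                       params$scheme, params$min_region_len, params$trim_nt),
    error = function(e) {
      stop("metaprofile stage failed: ", conditionMessage(e), call. = FALSE)
    })
  utils::write.csv(meta, file.path(outdir, "metaprofile.csv"),
                   row.names = FALSE)

  windows <- extreme_windows_set(delta, transcripts,
                                 width = params$window_width,
                                 step = params$window_step,
                                 min_defined = params$min_defined,
                                 trim_nt = params$trim_nt)
  utils::write.csv(windows, file.path(outdir, "windows.csv"),
                   row.names = FALSE)

  regions_tab <- do.call(rbind, lapply(ids, function(id) {
    a <- transcripts[match(id, transcripts$transcript_id), ]
    do.call(rbind, lapply(c("utr5", "cds", "utr3"), function(r) {
      sp <- region_span(a$utr5_end, a$cds_end, a$length, r, params$trim_nt)
      data.frame(transcript_id = id, region = r,
                 mean_control = region_average(avg_control[[id]], sp),
                 mean_hipp = region_average(avg_hipp[[id]], sp),
                 mean_delta = region_average(delta[[id]], sp),
                 gini_control = if (is.null(sp)) NA_real_ else
                   gini(avg_control[[id]][sp[1]:sp[2]]),
                 gini_hipp = if (is.null(sp)) NA_real_ else
                   gini(avg_hipp[[id]][sp[1]:sp[2]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(regions_tab, file.path(outdir, "regions.csv"),
                   row.names = FALSE)

  motifs <- motif_table(sequences[ids], transcripts, avg_hipp, delta,
                        seed = if (is.null(config)) 1 else config$seed)
  utils::write.csv(motifs, file.path(outdir, "motifs.csv"),
                   row.names = FALSE)

  te <- compute_te(expression, params$pseudocount)
  cls <- classify_dod(expression, prior_alt = params$prior_alt,
                      post_threshold = params$post_threshold,
                      indep_threshold = params$indep_threshold,
                      pseudocount = params$pseudocount)
  te_wide <- merge(
    setNames(te[te$condition == "control", c("gene_id", "te")],
             c("gene_id", "te_control")),
    setNames(te[te$condition != "control", c("gene_id", "te")],
             c("gene_id", "te_hipp")),
    by = "gene_id")
  cls <- merge(cls, te_wide, by = "gene_id", sort = TRUE)
  tis$utis <- utis_score(tis$upstream_reads, tis$atis_reads)
  cls <- merge(cls, tis[, c("gene_id", "utis")], by = "gene_id",
               all.x = TRUE, sort = TRUE)
  utils::write.csv(cls, file.path(outdir, "classification.csv"),
                   row.names = FALSE)

  input_files <- sort(list.files(input_dir, full.names = TRUE))
  input_hashes <- tools::md5sum(input_files)
  names(input_hashes) <- basename(input_files)
  manifest <- list(
    tool = "dmsdiff",
    version = as.character(utils::packageVersion("dmsdiff")),
    seed = if (is.null(config)) NA else config$seed,
    config = if (is.null(config)) NULL else unclass(config),
    params = unclass(params),
    input_hashes = as.list(input_hashes),
    stage_counts = as.list(counts),
    unscorable = rset$unscorable
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  invisible(list(transcripts = transcripts, metaprofile = meta,
                 windows = windows, regions = regions_tab, motifs = motifs,
                 classification = cls, qc = qc, manifest = manifest,
                 reactivity = list(control = avg_control, hipp = avg_hipp,
                                   delta = delta)))
}
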