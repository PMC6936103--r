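# File formats (all plain text, documented here and in the vignette):
#   .rtsc   : one line per transcript, "<id>\t<c1,c2,...,cL>", integer counts
#   .react  : one line per transcript, "<id>\t<v1,v2,...,vL>", "NA" undefined
#   .scale  : "<id>\t<positive float>"
#   annotation TSV: transcript_id gene_id utr5_end cds_end length abundance
#                   (utr5_end / cds_end are 0-based half-open boundaries)
#   expression CSV: gene_id, fraction, condition, replicate, count
#   TIS CSV       : gene_id, upstream_reads, atis_reads

#' Read an RT-stop count (.rtsc) file
#'
#' @param path file path.
#' @param lengths optional named integer vector of annotated transcript
#'   lengths; tracks whose length disagrees raise an error naming the
#'   transcript.
#' @return Named list of integer count vectors.
#' @export
read_rtsc <- function(path, lengths = NULL) {
  if (!file.exists(path)) stop("rtsc file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(parts[1])) {
      stop("malformed rtsc line ", i, " in ", path, call. = FALSE)
    }
    counts <- suppressWarnings(as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(counts)) {
      stop("non-numeric count on rtsc line ", i, " (", parts[1], ")", call. = FALSE)
    }
    if (any(counts < 0)) {
      stop("negative count on rtsc line ", i, " (", parts[1], ")", call. = FALSE)
    }
    if (any(counts != floor(counts))) {
      stop("non-integer count on rtsc line ", i, " (", parts[1], ")", call. = FALSE)
    }
    ids[i] <- parts[1]
    out[[i]] <- as.integer(counts)
  }
  names(out) <- ids
  if (!is.null(lengths)) {
    for (id in ids) {
      if (!id %in% names(lengths)) next
      if (length(out[[id]]) != lengths[[id]]) {
        stop("track length ", length(out[[id]]), " for transcript ", id,
             " does not match annotated length ", lengths[[id]], call. = FALSE)
      }
    }
  }
  out
}

#' Write an RT-stop count (.rtsc) file
#'
#' Round-trips byte-identically through [read_rtsc()].
#'
#' @param tracks named list of integer count vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rtsc <- function(tracks, path) {
  lines <- vapply(names(tracks), function(id) {
    paste0(id, "\t", paste(tracks[[id]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write reactivity (.react) files
#'
#' Undefined positions (non-A/C, trimmed, or otherwise unscored) are
#' written as `NA`.
#'
#' @param path file path.
#' @return Named list of numeric vectors with `NA` at undefined positions.
#' @export
read_react <- function(path) {
  if (!file.exists(path)) stop("react file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed react line ", i, call. = FALSE)
    ids[i] <- parts[1]
    out[[i]] <- suppressWarnings(as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
  }
  names(out) <- ids
  out
}

#' @rdname read_react
#' @param profiles named list of numeric vectors (NA = undefined).
#' @export
write_react <- function(profiles, path) {
  lines <- vapply(names(profiles), function(id) {
    v <- profiles[[id]]
    s <- ifelse(is.na(v), "NA", formatC(v, digits = 8, format = "g"))
    paste0(id, "\t", paste(s, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write per-transcript scale (.scale) tables
#'
#' @param path file path.
#' @return Named numeric vector of positive scale factors.
#' @export
read_scale <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("transcript_id", "scale"),
                          stringsAsFactors = FALSE)
  setNames(df$scale, df$transcript_id)
}

#' @rdname read_scale
#' @param scales named numeric vector.
#' @export
write_scale <- function(scales, path) {
  lines <- paste0(names(scales), "\t", formatC(scales, digits = 10, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the transcript annotation table
#'
#' Tab-delimited with columns `transcript_id`, `gene_id`, `utr5_end`,
#' `cds_end`, `length`, `abundance`; region boundaries are 0-based
#' half-open (the 5'UTR is `[0, utr5_end)`, the CDS `[utr5_end, cds_end)`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("transcript_id", "utr5_end", "cds_end", "length")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- with(df, !(utr5_end > 0 & cds_end > utr5_end & length > cds_end))
  if (any(bad)) {
    stop("invalid region boundaries for: ",
         paste(df$transcript_id[bad], collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_annotation
#' @param transcripts transcript table (sequence column is dropped).
#' @export
write_annotation <- function(transcripts, path) {
  keep <- intersect(c("transcript_id", "gene_id", "utr5_end", "cds_end",
                      "length", "abundance", "label"), names(transcripts))
  utils::write.table(transcripts[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write transcript sequences as FASTA
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_transcript_fasta
#' @param sequences named character vector of sequences.
#' @export
write_transcript_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read polysome expression and TIS count tables
#'
#' @param path file path.
#' @return data.frame in the long expression layout (`gene_id`, `fraction`,
#'   `condition`, `replicate`, `count`).
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "fraction", "condition", "replicate", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("expression table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_expression_csv
#' @export
read_tis_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "upstream_reads", "atis_reads")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("TIS table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write all inputs of a simulated experiment to a directory
#'
#' Writes `transcripts.fasta`, `annotation.tsv`, one `.rtsc` file per
#' sample, `polysome.csv`, `tis.csv` and `truth.json`.
#'
#' @param sim result of [simulate_structure_seq()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "transcripts.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    polysome = file.path(dir, "polysome.csv"),
    tis = file.path(dir, "tis.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_transcript_fasta(setNames(sim$transcripts$sequence,
                                  sim$transcripts$transcript_id),
                         paths[["fasta"]])
  write_annotation(sim$transcripts, paths[["annotation"]])
  utils::write.csv(sim$polysome, paths[["polysome"]], row.names = FALSE)
  utils::write.csv(sim$tis, paths[["tis"]], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA, na = "null")
  for (s in names(sim$rtsc)) {
    p <- file.path(dir, paste0(s, ".rtsc"))
    write_rtsc(sim$rtsc[[s]], p)
    paths[[s]] <- p
  }
  invisible(paths)
}
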