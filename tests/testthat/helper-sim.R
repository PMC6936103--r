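# Shared fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# default study conditions, moderate size
cached_default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_structure_seq(
      sim_config(n_transcripts = 150, seed = 1))
  }
  .sim_cache$default
}

# filters + shared-scale reactivity + replicate averages + delta
cached_default_analysis <- function() {
  if (is.null(.sim_cache$analysis)) {
    sim <- cached_default_sim()
    seqs <- setNames(sim$transcripts$sequence, sim$transcripts$transcript_id)
    plus <- grep("_plus_", names(sim$rtsc), value = TRUE)
    minus <- grep("_minus_", names(sim$rtsc), value = TRUE)
    pass <- filter_by_coverage(sim$rtsc, seqs, plus)
    pass <- intersect(pass, filter_by_end_coverage(sim$rtsc, minus))
    rset <- derive_reactivity_set(sim$rtsc, seqs, ids = pass,
                                  n_replicates = 3)
    avg_control <- average_replicates(rset$profiles$control)
    avg_hipp <- average_replicates(rset$profiles$hipp)
    ids <- intersect(names(avg_control), names(avg_hipp))
    delta <- setNames(lapply(ids, function(id) {
      delta_reactivity(avg_hipp[[id]], avg_control[[id]])
    }), ids)
    .sim_cache$analysis <- list(sim = sim, seqs = seqs, pass = pass,
                                rset = rset, avg_control = avg_control,
                                avg_hipp = avg_hipp, delta = delta,
                                ids = ids)
  }
  .sim_cache$analysis
}

# brute-force pairwise-difference Gini, the independent oracle
brute_gini <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# brute-force window enumeration, the independent oracle
brute_windows <- function(v, width, step = 1, min_defined = 3) {
  starts <- as.integer(seq.int(0L, length(v) - width, by = step))
  rows <- lapply(starts, function(s) {
    w <- v[(s + 1):(s + width)]
    nd <- sum(!is.na(w))
    if (nd < min_defined) return(NULL)
    data.frame(start = s, delta_mean = mean(w, na.rm = TRUE),
               n_defined = as.integer(nd))
  })
  do.call(rbind, rows)
}

# minimal gene table for the expression-only simulators
fake_genes <- function(n, label = "indep") {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             transcript_id = sprintf("g%04d.t1", seq_len(n)),
             label = label, stringsAsFactors = FALSE)
}
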