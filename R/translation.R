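#' Translational efficiency per gene and condition
#'
#' TE is the ratio of polysomal to sub-polysomal expression (replicate
#' means), with a pseudocount added to both to keep the ratio finite:
#' `TE = (poly + eps) / (sub + eps)`.  Natural-log TE is reported
#' alongside.
#'
#' @param expression long data.frame (`gene_id`, `fraction`, `condition`,
#'   `replicate`, `count`) with fractions `sub` and `poly`.
#' @param pseudocount `eps` (default 0.5 expression units).
#' @return data.frame: `gene_id`, `condition`, `poly`, `sub`, `te`,
#'   `log_te`.
#' @export
compute_te <- function(expression, pseudocount = 0.5) {
  x <- expression[expression$fraction %in% c("sub", "poly"), ]
  agg <- stats::aggregate(count ~ gene_id + condition + fraction, data = x,
                          FUN = mean)
  wide <- merge(agg[agg$fraction == "poly", c("gene_id", "condition", "count")],
                agg[agg$fraction == "sub", c("gene_id", "condition", "count")],
                by = c("gene_id", "condition"), suffixes = c("_poly", "_sub"))
  te <- (wide$count_poly + pseudocount) / (wide$count_sub + pseudocount)
  out <- data.frame(gene_id = wide$gene_id, condition = wide$condition,
                    poly = wide$count_poly, sub = wide$count_sub,
                    te = te, log_te = log(te), stringsAsFactors = FALSE)
  out[order(out$condition, out$gene_id), ]
}

#' Top and bottom TE tertiles
#'
#' Splits genes ranked by TE into the top (high TE) and bottom (low TE)
#' thirds, each of size `floor(n/3)`; ties resolve by stable gene-id
#' order.
#'
#' @param te named numeric vector of TE values (names = gene ids).
#' @return List with character vectors `high` and `low`.
#' @export
te_tertiles <- function(te) {
  n <- length(te)
  if (n < 3) stop("need at least 3 genes", call. = FALSE)
  k <- floor(n / 3)
  ord <- order(-te, names(te))
  list(high = names(te)[ord[seq_len(k)]],
       low = names(te)[ord[(n - k + 1):n]])
}

#' Upstream translation-initiation-site score
#'
#' `uTIS = upstream / (upstream + annotated)`.  Zero indicates no upstream
#' initiation; one indicates initiation only at upstream sites.
#'
#' @param upstream_reads,atis_reads nonnegative read counts (vectorized).
#' @return Score in `[0, 1]`; `NA` where both counts are zero.
#' @export
utis_score <- function(upstream_reads, atis_reads) {
  total <- upstream_reads + atis_reads
  ifelse(total > 0, upstream_reads / total, NA_real_)
}

# log-density of a zero-mean bivariate normal with covariance
# [[v1, c], [c, v2]]
ldbvnorm <- function(y1, y2, v1, v2, c) {
  det <- v1 * v2 - c^2
  q <- (v2 * y1^2 - 2 * c * y1 * y2 + v1 * y2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Bayesian difference-of-differences dependency classification
#'
#' Compares, per gene, a baseline model in which the treatment log-fold
#' change is shared between the sub-polysomal and polysomal fractions
#' against an alternate model in which the two fractions have their own
#' log-fold changes.  The observed per-fraction LFCs (differences of
#' replicate-mean log expressions, natural log with pseudocount) are given
#' normal likelihoods whose variance is the gene's pooled replicate
#' variance, shrunk toward the across-gene median with `shrink_k`
#' pseudo-replicates; the fraction LFC parameters carry conjugate `N(0,
#' sigma0^2)` priors, so both marginal likelihoods are closed-form
#' (bivariate) normals.
#'
#' A gene is labeled dependent when the posterior probability of the
#' alternate model exceeds `post_threshold` and `polyLFC - subLFC` is
#' negative (expression moved out of polysomes under treatment),
#' antidependent when the sign is positive, independent when the posterior
#' falls below `indep_threshold`, and unassigned otherwise.
#'
#' @param expression long data.frame with fractions `sub` and `poly` and
#'   conditions `control` and the treatment.
#' @param treatment name of the treated condition (default `"hipp"`).
#' @param prior_alt prior probability of the alternate model (default
#'   0.1).
#' @param post_threshold posterior above which a gene is declared
#'   dependent/antidependent (default 0.25).
#' @param indep_threshold posterior below which a gene is declared
#'   independent (default 0.02).
#' @param sigma0 prior standard deviation of the LFC parameters (natural
#'   log units).  The default of 2 is weakly informative; with only two
#'   observed fraction LFCs per gene, a much tighter prior caps the
#'   attainable evidence for the shared-change model below the
#'   independence threshold at realistic replicate noise.
#' @param shrink_k pseudo-replicates of shrinkage toward the across-gene
#'   median replicate variance.
#' @param pseudocount added before taking logs.
#' @return data.frame: `gene_id`, `sub_lfc`, `poly_lfc`, `dod`
#'   (`poly_lfc - sub_lfc`), `posterior_alt`, `label` in
#'   dep/antidep/indep/unassigned.
#' @export
classify_dod <- function(expression, treatment = "hipp", prior_alt = 0.1,
                         post_threshold = 0.25, indep_threshold = 0.02,
                         sigma0 = 2, shrink_k = 5, pseudocount = 0.5) {
  x <- expression[expression$fraction %in% c("sub", "poly") &
                    expression$condition %in% c("control", treatment), ]
  x$logx <- log(x$count + pseudocount)
  genes <- sort(unique(x$gene_id))

  stats_of <- function(v) c(m = mean(v), ss = sum((v - mean(v))^2),
                            df = length(v) - 1, n = length(v))
  per_gene <- lapply(genes, function(g) {
    gg <- x[x$gene_id == g, ]
    out <- list()
    for (fr in c("sub", "poly")) {
      for (cond in c("control", treatment)) {
        v <- gg$logx[gg$fraction == fr & gg$condition == cond]
        out[[paste(fr, cond, sep = ".")]] <- stats_of(v)
      }
    }
    out
  })
  names(per_gene) <- genes

  pooled_var <- vapply(per_gene, function(st) {
    ss <- sum(vapply(st, `[[`, numeric(1), "ss"))
    df <- sum(vapply(st, `[[`, numeric(1), "df"))
    if (df > 0) ss / df else NA_real_
  }, numeric(1))
  s0_sq <- stats::median(pooled_var, na.rm = TRUE)
  if (!is.finite(s0_sq)) s0_sq <- 0

  rows <- lapply(genes, function(g) {
    st <- per_gene[[g]]
    df <- sum(vapply(st, `[[`, numeric(1), "df"))
    y_sub <- st[[paste0("sub.", treatment)]][["m"]] - st[["sub.control"]][["m"]]
    y_poly <- st[[paste0("poly.", treatment)]][["m"]] - st[["poly.control"]][["m"]]
    if (df == 0 && s0_sq == 0) {
      return(data.frame(gene_id = g, sub_lfc = y_sub, poly_lfc = y_poly,
                        dod = y_poly - y_sub, posterior_alt = NA_real_,
                        label = "unassigned", stringsAsFactors = FALSE))
    }
    s2 <- (df * ifelse(is.na(pooled_var[[g]]), 0, pooled_var[[g]]) +
             shrink_k * s0_sq) / (df + shrink_k)
    inv_n <- function(key) 1 / st[[key]][["n"]]
    v_sub <- max(s2 * (inv_n("sub.control") + inv_n(paste0("sub.", treatment))),
                 1e-8)
    v_poly <- max(s2 * (inv_n("poly.control") + inv_n(paste0("poly.", treatment))),
                  1e-8)
    # alternate: independent N(0, sigma0^2) priors per fraction
    l1 <- stats::dnorm(y_sub, 0, sqrt(sigma0^2 + v_sub), log = TRUE) +
      stats::dnorm(y_poly, 0, sqrt(sigma0^2 + v_poly), log = TRUE)
    # baseline: shared delta ~ N(0, sigma0^2) induces covariance sigma0^2
    l0 <- ldbvnorm(y_sub, y_poly, sigma0^2 + v_sub, sigma0^2 + v_poly,
                   sigma0^2)
    if (prior_alt <= 0) {
      post <- 0
    } else if (prior_alt >= 1) {
      post <- 1
    } else {
      log_odds <- log(prior_alt) - log(1 - prior_alt) + l1 - l0
      post <- 1 / (1 + exp(-log_odds))
    }
    dod <- y_poly - y_sub
    label <- if (is.na(post)) {
      "unassigned"
    } else if (post > post_threshold) {
      if (dod < 0) "dep" else "antidep"
    } else if (post < indep_threshold) {
      "indep"
    } else {
      "unassigned"
    }
    data.frame(gene_id = g, sub_lfc = y_sub, poly_lfc = y_poly, dod = dod,
               posterior_alt = post, label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
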