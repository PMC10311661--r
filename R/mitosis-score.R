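#' Derive an anchor-correlated, tumor-elevated gene signature
#'
#' Builds an "active mitosis" style signature: from a candidate gene set
#' (e.g. a cell-cycle/mitotic pathway), keep the genes that are
#' (i) positively correlated with the anchor gene across tumor samples at
#' a Benjamini-Hochberg adjusted one-sided p <= `fdr_cut`, and
#' (ii) elevated in tumors versus matched normals by a one-sided paired
#' Wilcoxon signed-rank test at BH-adjusted p <= `elevation_fdr`.
#' The anchor itself is never a member of the returned signature.
#'
#' @param cohort An `expression_cohort` with at least 3 tumor/normal pairs.
#' @param anchor Anchor gene id (must be in the cohort).
#' @param candidate_set Character vector of candidate gene ids; must
#'   intersect the cohort's genes.
#' @param corr_method `"spearman"` (default, robust to the unknown
#'   normalisation of real cohorts) or `"pearson"`.
#' @param fdr_cut BH-adjusted p cutoff for the correlation filter.
#' @param elevation_fdr BH-adjusted p cutoff for the elevation filter.
#' @param corr_samples Correlate over `"tumor"` samples only (default) or
#'   `"all"` samples.
#' @return A `gene_signature`: list with `genes` and a `derivation` record
#'   (anchor, method, cutoffs, per-filter survivor counts).
#' @export
derive_signature <- function(cohort, anchor, candidate_set,
                             corr_method = c("spearman", "pearson"),
                             fdr_cut = 0.05, elevation_fdr = 0.05,
                             corr_samples = c("tumor", "all")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  corr_method <- match.arg(corr_method)
  corr_samples <- match.arg(corr_samples)
  if (!anchor %in% cohort$genes) {
    stop("anchor gene not present in cohort", call. = FALSE)
  }
  candidates <- setdiff(intersect(unique(candidate_set), cohort$genes),
                        anchor)
  if (length(candidates) == 0) {
    stop("candidate_set does not intersect the cohort's genes",
         call. = FALSE)
  }
  if (nrow(cohort$pairing) < 3) {
    stop("need at least 3 tumor/normal pairs", call. = FALSE)
  }

  tumor <- cohort_matrix(cohort, "tumor")
  normal <- cohort_matrix(cohort, "normal")
  corr_mat <- if (corr_samples == "tumor") tumor else
    cohort$values[, cohort$samples, drop = FALSE]
  anchor_expr <- corr_mat[anchor, ]

  corr_p <- vapply(candidates, function(g) {
    ct <- suppressWarnings(
      stats::cor.test(corr_mat[g, ], anchor_expr, method = corr_method,
                      alternative = "greater", exact = FALSE))
    ct$p.value
  }, numeric(1))
  elev_p <- vapply(candidates, function(g) {
    wt <- suppressWarnings(
      stats::wilcox.test(tumor[g, ], normal[g, ], paired = TRUE,
                         alternative = "greater", exact = FALSE))
    wt$p.value
  }, numeric(1))

  pass_corr <- stats::p.adjust(corr_p, method = "BH") <= fdr_cut
  pass_elev <- stats::p.adjust(elev_p, method = "BH") <= elevation_fdr
  keep <- candidates[pass_corr & pass_elev]

  if (length(keep) == 0) {
    stop(sprintf(paste0("empty signature: %d candidates, %d passed the ",
                        "correlation filter, %d the elevation filter, ",
                        "0 passed both"),
                 length(candidates), sum(pass_corr), sum(pass_elev)),
         call. = FALSE)
  }
  structure(
    list(genes = sort(keep),
         derivation = list(anchor = anchor,
                           corr_method = corr_method,
                           corr_samples = corr_samples,
                           fdr_cut = fdr_cut,
                           elevation_fdr = elevation_fdr,
                           n_candidates = length(candidates),
                           n_pass_corr = sum(pass_corr),
                           n_pass_elev = sum(pass_elev))),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  d <- x$derivation
  cat(sprintf("gene_signature: %d genes (anchor %s, %s correlation)\n",
              length(x$genes), d$anchor %||% "?", d$corr_method %||% "?"))
  invisible(x)
}

as_signature_genes <- function(signature) {
  if (inherits(signature, "gene_signature")) signature$genes
  else as.character(signature)
}

#' Single-sample GSEA enrichment score
#'
#' Barbie-style integral statistic for one sample against one gene set.
#' Genes are ranked by descending expression within the sample (ties
#' broken by gene id); walking down the list, the in-set empirical
#' distribution steps by the rank weight `(N - position + 1)^tau`
#' normalised over in-set genes, the out-of-set distribution steps
#' uniformly, and the score is the sum over all positions of their
#' difference (an integrated, not maximum, deviation). With `tau = 0` the
#' statistic depends only on the ranks.
#'
#' @param sample_expression Named numeric vector: expression of every gene
#'   in one sample.
#' @param signature A `gene_signature` or character vector of gene ids;
#'   must share at least one gene with the sample's universe and not cover
#'   it entirely.
#' @param tau Rank-weight exponent, >= 0 (0 = unweighted ranks).
#' @return A single enrichment score (unnormalised, sample-level).
#' @export
ssgsea_score <- function(sample_expression, signature, tau = 0.25) {
  stop_if_not_scalar_number(tau, "tau", nonnegative = TRUE)
  genes <- names(sample_expression)
  if (is.null(genes)) {
    stop("`sample_expression` must be a named vector", call. = FALSE)
  }
  sig <- as_signature_genes(signature)
  hit <- genes %in% sig
  n <- length(genes)
  k <- sum(hit)
  if (k == 0) stop("signature does not overlap the sample's genes",
                   call. = FALSE)
  if (k == n) stop("signature covers the whole gene universe",
                   call. = FALSE)
  ord <- order(-as.numeric(sample_expression), genes)
  hit <- hit[ord]
  w <- (n - seq_len(n) + 1)^tau
  p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  p_out <- cumsum(!hit) / (n - k)
  sum(p_in - p_out)
}

#' Active-mitosis signature enrichment scores (AMSES) for a cohort
#'
#' Scores every sample of the cohort against the signature by
#' [ssgsea_score()] and range-normalises the raw scores to `[0, 1]`
#' across the scored cohort. When the cohort carries planted truth, the
#' Spearman correlation between tumor-sample scores and the latent
#' activity is attached as a diagnostic.
#'
#' @param cohort An `expression_cohort`.
#' @param signature A `gene_signature` or character vector of gene ids.
#' @param tau Rank-weight exponent passed to [ssgsea_score()].
#' @return A `score_vector`: data frame `(sample, patient, condition, raw,
#'   normalized)` with attributes `normalization` (`"range"` or `"raw"`)
#'   and, when available, `truth_correlation`.
#' @export
amses <- function(cohort, signature, tau = 0.25) {
  stopifnot(inherits(cohort, "expression_cohort"))
  raw <- vapply(cohort$samples, function(s) {
    ssgsea_score(stats::setNames(cohort$values[, s], cohort$genes),
                 signature, tau = tau)
  }, numeric(1))
  rng <- range(raw)
  if (length(raw) < 2 || rng[1] == rng[2]) {
    warning("cannot range-normalize (<2 distinct raw scores); ",
            "returning raw scores", call. = FALSE)
    normalized <- raw
    normalization <- "raw"
  } else {
    normalized <- (raw - rng[1]) / (rng[2] - rng[1])
    normalization <- "range"
  }
  out <- data.frame(sample = cohort$samples,
                    patient = unname(cohort$patient[cohort$samples]),
                    condition = unname(cohort$condition[cohort$samples]),
                    raw = unname(raw),
                    normalized = unname(normalized),
                    stringsAsFactors = FALSE)
  attr(out, "normalization") <- normalization
  if (!is.null(cohort$truth$activity)) {
    tum <- out[out$condition == "tumor", ]
    act <- cohort$truth$activity[tum$patient]
    attr(out, "truth_correlation") <-
      suppressWarnings(stats::cor(tum$raw, act, method = "spearman"))
  }
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Ordered trend test of scores across cancer stages
#'
#' Jonckheere-Terpstra style test for a monotone increase of scores across
#' ordered groups: the statistic is the sum over all ordered group pairs
#' of Mann-Whitney counts (ties count 1/2), and the p-value comes from a
#' seeded permutation of group labels, one-sided for an increasing trend
#' by default (`alternative = "two.sided"` uses the deviation from the
#' permutation mean).
#'
#' @param scores Numeric vector of per-sample scores.
#' @param stages Group labels; order taken from factor levels (or sorted
#'   unique values), each group needing >= 2 samples.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed.
#' @param alternative `"increasing"` or `"two.sided"`.
#' @return List with `statistic`, `p_value`, `n_permutations`.
#' @export
score_vs_stage <- function(scores, stages, n_permutations = 1000L,
                           seed = 1L, alternative = c("increasing",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  stages <- as.factor(stages)
  if (nlevels(stages) < 2) stop("need at least 2 stage groups",
                                call. = FALSE)
  if (any(table(stages) < 2)) {
    stop("every stage group needs at least 2 samples", call. = FALSE)
  }
  if (length(scores) != length(stages)) {
    stop("`scores` and `stages` lengths differ", call. = FALSE)
  }

  jt_stat <- function(x, g) {
    lev <- levels(g)
    total <- 0
    for (i in seq_len(length(lev) - 1)) {
      for (j in seq(i + 1, length(lev))) {
        xi <- x[g == lev[i]]
        xj <- x[g == lev[j]]
        cmp <- outer(xi, xj, "<") + 0.5 * outer(xi, xj, "==")
        total <- total + sum(cmp)
      }
    }
    total
  }

  obs <- jt_stat(scores, stages)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      jt_stat(scores, sample(stages))
    }, numeric(1))
  })
  p <- if (alternative == "increasing") {
    (1 + sum(perm >= obs)) / (1 + n_permutations)
  } else {
    mu <- mean(perm)
    (1 + sum(abs(perm - mu) >= abs(obs - mu))) / (1 + n_permutations)
  }
  list(statistic = obs, p_value = p,
       n_permutations = as.integer(n_permutations))
}
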