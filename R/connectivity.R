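#' Ranked expression profile
#'
#' A profile of per-gene signed scores ordered from most up-regulated to
#' most down-regulated. Ties in score are broken by gene id (lexicographic)
#' so the ordering is bit-reproducible.
#'
#' @param genes Character vector of unique gene ids.
#' @param scores Numeric signed statistic per gene (same length/order as
#'   `genes`, or a named vector over `genes`).
#' @param id Optional compound / profile identifier.
#' @return A `ranked_profile`: data frame with columns `gene`, `score`,
#'   sorted by decreasing score.
#' @export
ranked_profile <- function(genes, scores, id = NULL) {
  if (anyDuplicated(genes)) stop("gene ids must be unique", call. = FALSE)
  if (!is.null(names(scores))) scores <- scores[genes]
  if (length(scores) != length(genes) || any(!is.finite(scores))) {
    stop("`scores` must be finite and match `genes`", call. = FALSE)
  }
  ord <- order(-scores, genes)
  structure(data.frame(gene = genes[ord], score = as.numeric(scores)[ord],
                       stringsAsFactors = FALSE),
            id = id, class = c("ranked_profile", "data.frame"))
}

#' Up/down query signature
#'
#' @param up,down Disjoint, nonempty character vectors of gene ids
#'   expected up- and down-regulated by the query perturbation.
#' @return A `query_signature` list.
#' @export
query_signature <- function(up, down) {
  if (length(up) == 0 || length(down) == 0) {
    stop("both `up` and `down` must be nonempty", call. = FALSE)
  }
  if (length(intersect(up, down)) > 0) {
    stop("`up` and `down` must be disjoint", call. = FALSE)
  }
  structure(list(up = unique(up), down = unique(down)),
            class = "query_signature")
}

#' Binary molecular fingerprint
#'
#' @param id Molecule identifier.
#' @param bits Integer vector of set-bit positions (1-based), all
#'   `<= n_bits`.
#' @param n_bits Total fingerprint length.
#' @return A `fingerprint` list.
#' @export
fingerprint <- function(id, bits, n_bits) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > n_bits)) {
    stop("bit positions must lie in [1, n_bits]", call. = FALSE)
  }
  structure(list(id = id, bits = bits, n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The GSEA running-sum statistic: walking down the ranked profile, a gene
#' in `gene_set` ("hit") increments the sum by its weight
#' `|score|^weight_exponent` normalised over all hits, a miss decrements by
#' `1/(N - k)`. The enrichment score is the signed maximum deviation of the
#' running sum from zero (ties resolved to the earliest position).
#'
#' @param profile A [ranked_profile()].
#' @param gene_set Character vector of gene ids; must intersect the
#'   profile but not cover it entirely.
#' @param weight_exponent Non-negative weight on `|score|`; `0` gives the
#'   classic unweighted KS statistic, `1` the connectivity-map convention.
#' @return A single enrichment score in `[-1, 1]`.
#' @examples
#' prof <- ranked_profile(letters[1:10], 10:1)
#' weighted_ks_es(prof, c("a", "b", "c"), weight_exponent = 0)
#' @export
weighted_ks_es <- function(profile, gene_set, weight_exponent = 1) {
  stopifnot(inherits(profile, "ranked_profile"))
  stop_if_not_scalar_number(weight_exponent, "weight_exponent",
                            nonnegative = TRUE)
  hit <- profile$gene %in% gene_set
  k <- sum(hit)
  n <- length(hit)
  if (k == 0) stop("gene set does not intersect the profile", call. = FALSE)
  if (k == n) {
    stop("gene set covers the whole profile (miss step undefined)",
         call. = FALSE)
  }
  w <- abs(profile$score)^weight_exponent
  w_hit_total <- sum(w[hit])
  if (w_hit_total == 0) {
    # all-hit weights zero (e.g. zero scores at positive exponent):
    # fall back to uniform hit steps, the weight-exponent-0 limit
    step_hit <- rep(1 / k, n)
  } else {
    step_hit <- w / w_hit_total
  }
  steps <- ifelse(hit, step_hit, -1 / (n - k))
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Weighted two-sided connectivity score (wtcs)
#'
#' Connectivity-map style score of a reference profile against an up/down
#' query signature: enrichment scores of the up and the down set are
#' combined as `(ES_up - ES_down) / 2` when their signs differ and set to
#' 0 otherwise (a same-sign pattern is not connectivity).
#'
#' @param profile A [ranked_profile()].
#' @param query A [query_signature()].
#' @param weight_exponent Passed to [weighted_ks_es()].
#' @return A connectivity score in `[-1, 1]`; positive means the profile
#'   mimics the query perturbation, negative that it reverses it.
#' @export
wtcs <- function(profile, query, weight_exponent = 1) {
  stopifnot(inherits(query, "query_signature"))
  es_up <- weighted_ks_es(profile, query$up, weight_exponent)
  es_down <- weighted_ks_es(profile, query$down, weight_exponent)
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Preranked GSEA with a gene-label permutation p-value
#'
#' Computes the enrichment score of `gene_set` on `profile` and a
#' permutation p-value obtained by shuffling gene labels (equivalently,
#' redrawing the hit positions uniformly) `n_permutations` times with the
#' given seed. The add-one estimator
#' `p = (1 + #\{|ES*| >= |ES|\}) / (1 + n_permutations)` is used, so p is
#' bounded below by `1/(n_permutations + 1)`.
#'
#' @inheritParams weighted_ks_es
#' @param n_permutations Number of label permutations, >= 100.
#' @param seed Integer seed for the permutation stream.
#' @return A list with `es`, `p_value`, `n_permutations`.
#' @export
preranked_gsea <- function(profile, gene_set, weight_exponent = 1,
                           n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100) {
    stop("`n_permutations` must be at least 100", call. = FALSE)
  }
  es <- weighted_ks_es(profile, gene_set, weight_exponent)
  hit <- profile$gene %in% gene_set
  k <- sum(hit)
  n <- length(hit)
  w <- abs(profile$score)^weight_exponent
  miss_step <- -1 / (n - k)
  perm_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, k)
      h <- logical(n)
      h[idx] <- TRUE
      wt <- sum(w[h])
      steps <- if (wt == 0) ifelse(h, 1 / k, miss_step) else
        ifelse(h, w / wt, miss_step)
      running <- cumsum(steps)
      running[which.max(abs(running))]
    }, numeric(1))
  })
  list(es = es,
       p_value = (1 + sum(abs(perm_es) >= abs(es))) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations))
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. Undefined (error)
#' when both fingerprints are empty; fingerprints must have equal length.
#'
#' @param a,b [fingerprint()] objects with equal `n_bits`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint lengths differ", call. = FALSE)
  }
  union_size <- length(union(a$bits, b$bits))
  if (union_size == 0) {
    stop("Tanimoto undefined for two empty fingerprints", call. = FALSE)
  }
  length(intersect(a$bits, b$bits)) / union_size
}

#' Rank candidate compounds by connectivity, annotated with Tanimoto
#'
#' Scores every reference profile against the query signature by [wtcs()]
#' and, when fingerprints are supplied, annotates each compound with its
#' Tanimoto similarity to the query compound's fingerprint. Compounds
#' without a fingerprint get `NA` similarity rather than an error.
#'
#' @param profiles Named list of [ranked_profile()]s (names or profile
#'   `id` attributes are the compound ids).
#' @param query A [query_signature()].
#' @param fingerprints Optional list of [fingerprint()]s.
#' @param query_fp Optional [fingerprint()] of the query compound (or the
#'   id of one of `fingerprints`).
#' @param weight_exponent Passed to [wtcs()].
#' @return Data frame `(compound, wtcs, tanimoto)` sorted by decreasing
#'   `wtcs`, ties broken by compound id.
#' @export
rank_candidates <- function(profiles, query, fingerprints = NULL,
                            query_fp = NULL, weight_exponent = 1) {
  if (length(profiles) == 0) stop("no profiles supplied", call. = FALSE)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) attr(p, "id") %||% NA_character_,
                  character(1))
  }
  if (anyNA(ids)) stop("profiles must carry compound ids", call. = FALSE)

  fp_by_id <- list()
  if (!is.null(fingerprints)) {
    fp_by_id <- stats::setNames(fingerprints,
                                vapply(fingerprints, `[[`, character(1), "id"))
  }
  if (is.character(query_fp)) {
    query_fp <- fp_by_id[[query_fp]]
    if (is.null(query_fp)) stop("query_fp id not found", call. = FALSE)
  }

  scores <- vapply(profiles, wtcs, numeric(1), query = query,
                   weight_exponent = weight_exponent)
  tani <- rep(NA_real_, length(profiles))
  if (!is.null(query_fp)) {
    for (i in seq_along(ids)) {
      fp <- fp_by_id[[ids[i]]]
      if (!is.null(fp)) tani[i] <- tanimoto(fp, query_fp)
    }
  }
  out <- data.frame(compound = ids, wtcs = as.numeric(scores),
                    tanimoto = tani, stringsAsFactors = FALSE)
  out[order(-out$wtcs, out$compound), , drop = FALSE]
}
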