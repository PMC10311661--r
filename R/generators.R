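#' Generate a synthetic kinome competition-binding profile
#'
#' Emulates a scanMAX-style table of percent-of-control (%Ctrl) binding
#' values: low %Ctrl means strong competition, i.e. strong binding of the
#' probe compound to that kinase. Exactly `n_hits` nonmutant kinases are
#' placed strictly below `threshold` and all other nonmutant kinases at or
#' above it, so the downstream selectivity score at that threshold is
#' `n_hits / (n_kinases - n_mutant)` by construction.
#'
#' @param n_kinases Total kinases assayed.
#' @param n_mutant Number of mutant-kinase entries (excluded from
#'   selectivity scoring).
#' @param n_hits Number of nonmutant kinases planted strictly below
#'   `threshold`; must not exceed `n_kinases - n_mutant`.
#' @param threshold %Ctrl hit threshold used when planting.
#' @param seed Integer seed.
#' @return A `kinome_profile` object (see [kinome_profile()]).
#' @examples
#' prof <- generate_kinome_profile(403, n_mutant = 0, n_hits = 17,
#'                                 threshold = 10, seed = 1)
#' s_score(prof, 10)
#' @export
generate_kinome_profile <- function(n_kinases, n_mutant = 0L, n_hits,
                                    threshold = 10, seed = 1L) {
  stop_if_not_scalar_number(n_kinases, "n_kinases", positive = TRUE)
  stop_if_not_scalar_number(n_mutant, "n_mutant", nonnegative = TRUE)
  stop_if_not_scalar_number(n_hits, "n_hits", nonnegative = TRUE)
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  n_kinases <- as.integer(n_kinases)
  n_mutant <- as.integer(n_mutant)
  n_hits <- as.integer(n_hits)
  if (n_hits > n_kinases - n_mutant) {
    stop("`n_hits` cannot exceed the number of nonmutant kinases",
         call. = FALSE)
  }
  with_seed(seed, {
    ids <- make_ids("KIN", n_kinases)
    is_mutant <- rep(FALSE, n_kinases)
    if (n_mutant > 0) {
      is_mutant[sample.int(n_kinases, n_mutant)] <- TRUE
    }
    nonmutant_idx <- which(!is_mutant)
    hit_idx <- if (n_hits > 0) {
      nonmutant_idx[sample.int(length(nonmutant_idx), n_hits)]
    } else integer(0)
    pct <- stats::runif(n_kinases, min = threshold, max = 100)
    if (n_hits > 0) {
      pct[hit_idx] <- stats::runif(n_hits, min = 0, max = threshold * 0.999)
    }
    if (n_mutant > 0) {
      pct[is_mutant] <- stats::runif(n_mutant, min = 0, max = 100)
    }
    kinome_profile(data.frame(kinase = ids, pct_ctrl = pct,
                              is_mutant = is_mutant,
                              stringsAsFactors = FALSE))
  })
}

#' Median-effect dose-response parameters
#'
#' Parameters of the median-effect (Chou) model
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)` used by [generate_dose_response()] and
#' [generate_combination()].
#'
#' @param m Sigmoidicity (median-effect slope), > 0.
#' @param Dm Median-effect dose (dose giving 50% effect), > 0.
#' @param doses Vector of doses, all > 0.
#' @param noise_sd Gaussian noise standard deviation applied on the logit
#'   scale of the fraction affected (0 = noiseless).
#' @param seed Integer seed.
#' @return A `dose_response_params` object.
#' @export
dose_response_params <- function(m, Dm, doses, noise_sd = 0, seed = 1L) {
  stop_if_not_scalar_number(m, "m", positive = TRUE)
  stop_if_not_scalar_number(Dm, "Dm", positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.numeric(doses) || length(doses) == 0 || any(!is.finite(doses)) ||
      any(doses <= 0)) {
    stop("`doses` must be a vector of positive finite doses", call. = FALSE)
  }
  structure(list(m = m, Dm = Dm, doses = as.numeric(doses),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dose_response_params")
}

#' Generate a single-agent dose-response table from the median-effect model
#'
#' The fraction affected at dose `D` is
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`; with `noise_sd > 0`, gaussian noise is
#' added on the logit scale and mapped back, so noisy values stay strictly
#' inside (0, 1). `noise_sd = 0` gives the exact model values, making the
#' generator exactly invertible by [median_effect_fit()].
#'
#' @param params A [dose_response_params()] object.
#' @param drug Drug identifier stored in the table.
#' @return A `dose_response` object: data frame with columns `drug`,
#'   `dose1`, `dose2` (`NA` for single agents), `fa`, `flag`.
#' @examples
#' dr <- generate_dose_response(dose_response_params(m = 2, Dm = 10,
#'                                                   doses = c(2, 5, 10, 20)))
#' dr
#' @export
generate_dose_response <- function(params, drug = "drug1") {
  stopifnot(inherits(params, "dose_response_params"))
  fa <- with(params, (doses / Dm)^m / (1 + (doses / Dm)^m))
  if (params$noise_sd > 0) {
    fa <- with_seed(params$seed, {
      inv_logit(logit(fa) + stats::rnorm(length(fa), sd = params$noise_sd))
    })
  }
  dose_response(data.frame(drug = drug, dose1 = params$doses, dose2 = NA_real_,
                           fa = fa, flag = NA_character_,
                           stringsAsFactors = FALSE))
}

#' Generate a fixed-ratio drug-combination dose-response table
#'
#' For each total dose, the pair doses are split according to `ratio` and
#' the fraction affected solves the Loewe-type interaction equation
#' `d1/Dx1(fa) + d2/Dx2(fa) = combo_alpha`, where `Dx` is the
#' median-effect dose-for-effect of each single agent. `combo_alpha = 1`
#' plants exact Loewe additivity; `combo_alpha < 1` plants synergy and
#' `> 1` antagonism, and the combination index recomputed from the true
#' single-agent parameters equals `combo_alpha` at every noiseless point.
#' Rows whose equation has no solution in (0, 1) are flagged rather than
#' clamped.
#'
#' @param params_drug1,params_drug2 [dose_response_params()] for the two
#'   single agents (their `m`, `Dm` are used; doses come from `doses`).
#' @param combo_alpha Loewe-interaction multiplier, > 0.
#' @param ratio Length-2 positive vector: `d1:d2` mixing ratio.
#' @param doses Total doses of the fixed-ratio mixture, all > 0.
#' @param noise_sd Gaussian logit-scale noise on the generated `fa`.
#' @param seed Integer seed.
#' @return A `dose_response` object with both `dose1` and `dose2` set.
#' @examples
#' p1 <- dose_response_params(m = 1, Dm = 1, doses = 1)
#' p2 <- dose_response_params(m = 2, Dm = 10, doses = 1)
#' generate_combination(p1, p2, combo_alpha = 0.5, ratio = c(1, 1),
#'                      doses = c(1, 2, 4))
#' @export
generate_combination <- function(params_drug1, params_drug2,
                                 combo_alpha = 1, ratio = c(1, 1),
                                 doses, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params_drug1, "dose_response_params"),
            inherits(params_drug2, "dose_response_params"))
  stop_if_not_scalar_number(combo_alpha, "combo_alpha", positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop("`ratio` must be two positive numbers (d1:d2)", call. = FALSE)
  }
  if (any(doses <= 0)) stop("`doses` must be positive", call. = FALSE)

  d1 <- doses * ratio[1] / sum(ratio)
  d2 <- doses * ratio[2] / sum(ratio)
  dx1 <- function(fa) params_drug1$Dm * (fa / (1 - fa))^(1 / params_drug1$m)
  dx2 <- function(fa) params_drug2$Dm * (fa / (1 - fa))^(1 / params_drug2$m)

  fa <- numeric(length(doses))
  flag <- rep(NA_character_, length(doses))
  for (i in seq_along(doses)) {
    # g is strictly decreasing in fa: +Inf as fa -> 0+, -> -alpha as fa -> 1-
    g <- function(x) d1[i] / dx1(x) + d2[i] / dx2(x) - combo_alpha
    root <- tryCatch(
      stats::uniroot(function(z) g(inv_logit(z)), lower = -40, upper = 40,
                     tol = .Machine$double.eps^0.75),
      error = function(e) NULL)
    if (is.null(root)) {
      fa[i] <- NA_real_
      flag[i] <- "no-solution"
    } else {
      fa[i] <- inv_logit(root$root)
    }
  }
  if (noise_sd > 0) {
    ok <- is.na(flag)
    fa[ok] <- with_seed(seed, {
      inv_logit(logit(fa[ok]) + stats::rnorm(sum(ok), sd = noise_sd))
    })
  }
  dose_response(data.frame(
    drug = paste(attr(params_drug1, "drug") %||% "drug1",
                 attr(params_drug2, "drug") %||% "drug2", sep = "+"),
    dose1 = d1, dose2 = d2, fa = fa, flag = flag,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate families of binary molecular fingerprints
#'
#' Molecules are organised into families. Each family has a random
#' prototype bit pattern (bits set independently with probability
#' `bit_density`); every molecule copies each prototype bit with
#' probability `family_overlap` and otherwise redraws it fresh, so
#' `family_overlap = 1` gives identical fingerprints within a family and
#' `family_overlap = 0` gives independent molecules. With
#' `disjoint_families = TRUE` the bit space is partitioned between
#' families so cross-family Tanimoto similarity is exactly zero.
#'
#' @param n_molecules Total molecules (split as evenly as possible across
#'   families).
#' @param n_bits Fingerprint length, > 0.
#' @param family_overlap Probability of inheriting each prototype bit, in
#'   `[0, 1]`.
#' @param n_families Number of families.
#' @param bit_density Marginal probability that a bit is set.
#' @param disjoint_families Give each family a private slice of bit space.
#' @param seed Integer seed.
#' @return A list of [fingerprint()] objects; each carries a `family`
#'   attribute.
#' @export
generate_fingerprints <- function(n_molecules, n_bits = 1024,
                                  family_overlap = 0.5, n_families = 1L,
                                  bit_density = 0.1,
                                  disjoint_families = FALSE, seed = 1L) {
  stop_if_not_scalar_number(n_molecules, "n_molecules", positive = TRUE)
  stop_if_not_scalar_number(n_bits, "n_bits", positive = TRUE)
  stop_if_not_scalar_number(family_overlap, "family_overlap",
                            nonnegative = TRUE)
  if (family_overlap > 1) {
    stop("`family_overlap` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(bit_density, "bit_density", positive = TRUE)
  n_molecules <- as.integer(n_molecules)
  n_families <- as.integer(n_families)
  n_bits <- as.integer(n_bits)

  with_seed(seed, {
    family_of <- rep(seq_len(n_families), length.out = n_molecules)
    family_of <- sort(family_of)
    regions <- if (disjoint_families) {
      split(seq_len(n_bits), cut(seq_len(n_bits), n_families, labels = FALSE))
    } else {
      rep(list(seq_len(n_bits)), n_families)
    }
    prototypes <- lapply(regions, function(r) {
      stats::runif(length(r)) < bit_density
    })
    out <- vector("list", n_molecules)
    counter <- integer(n_families)
    for (i in seq_len(n_molecules)) {
      fam <- family_of[i]
      counter[fam] <- counter[fam] + 1L
      region <- regions[[fam]]
      proto <- prototypes[[fam]]
      inherit <- stats::runif(length(region)) < family_overlap
      fresh <- stats::runif(length(region)) < bit_density
      bits_local <- ifelse(inherit, proto, fresh)
      fp <- fingerprint(id = sprintf("FAM%d-M%03d", fam, counter[fam]),
                        bits = region[bits_local], n_bits = n_bits)
      attr(fp, "family") <- fam
      out[[i]] <- fp
    }
    out
  })
}

#' Generate reference ranked expression profiles with a planted match
#'
#' Builds a collection of compound-perturbation profiles (one ranked gene
#' list per compound) for connectivity scoring. Decoy compounds get
#' i.i.d. standard-normal gene scores; the planted compound additionally
#' shifts the query's up-genes by `+signal` and down-genes by `-signal`,
#' so it is concordant with the query signature.
#'
#' @param universe Character vector of gene ids shared by all profiles.
#' @param query A [query_signature()]; its sets must be subsets of
#'   `universe`.
#' @param n_profiles Number of profiles (compounds) to generate.
#' @param planted_id Compound id of the planted concordant profile, or
#'   `NULL` for decoys only. Remaining compounds are named `CPD...`.
#' @param signal Mean score shift applied to query genes in the planted
#'   profile.
#' @param seed Integer seed.
#' @return A named list of `ranked_profile` objects.
#' @export
generate_ranked_profiles <- function(universe, query, n_profiles,
                                     planted_id = NULL, signal = 3,
                                     seed = 1L) {
  stopifnot(inherits(query, "query_signature"))
  if (!all(c(query$up, query$down) %in% universe)) {
    stop("query genes must belong to `universe`", call. = FALSE)
  }
  with_seed(seed, {
    ids <- make_ids("CPD", n_profiles)
    planted_idx <- 0L
    if (!is.null(planted_id)) {
      planted_idx <- sample.int(n_profiles, 1L)
      ids[planted_idx] <- planted_id
    }
    out <- lapply(seq_len(n_profiles), function(i) {
      scores <- stats::rnorm(length(universe))
      names(scores) <- universe
      if (i == planted_idx) {
        scores[query$up] <- scores[query$up] + signal
        scores[query$down] <- scores[query$down] - signal
      }
      ranked_profile(universe, scores, id = ids[i])
    })
    stats::setNames(out, ids)
  })
}
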