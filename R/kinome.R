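#' Kinome competition-binding profile
#'
#' Container for a percent-of-control (%Ctrl) kinome panel: one row per
#' kinase with its %Ctrl readout (low = strong binding) and a mutant flag.
#' Mutant-kinase entries are carried but excluded from selectivity scoring.
#'
#' @param entries Data frame with columns `kinase` (unique ids),
#'   `pct_ctrl` (>= 0) and `is_mutant` (logical).
#' @return A `kinome_profile` object.
#' @export
kinome_profile <- function(entries) {
  req <- c("kinase", "pct_ctrl", "is_mutant")
  if (!is.data.frame(entries) || !all(req %in% names(entries))) {
    stop("`entries` must have columns kinase, pct_ctrl, is_mutant",
         call. = FALSE)
  }
  if (anyDuplicated(entries$kinase)) {
    stop("kinase ids must be unique", call. = FALSE)
  }
  if (any(!is.finite(entries$pct_ctrl)) || any(entries$pct_ctrl < 0)) {
    stop("pct_ctrl must be finite and >= 0", call. = FALSE)
  }
  entries$is_mutant <- as.logical(entries$is_mutant)
  structure(entries[req], class = c("kinome_profile", "data.frame"))
}

#' Kinome selectivity score S(x)
#'
#' Fraction of nonmutant kinases bound below `x`% of control:
#' `S(x) = #\{nonmutant kinases with %Ctrl < x\} / #\{nonmutant kinases\}`.
#' The inequality is strict, so kinases exactly at the threshold are
#' non-hits, and mutant entries are excluded from both numerator and
#' denominator. The conventional report is S(10).
#'
#' @param profile A [kinome_profile()] with at least one nonmutant entry.
#' @param threshold %Ctrl threshold `x` (> 0).
#' @return A `selectivity_score` list: `score` (exact fraction),
#'   `score_3dp` (rounded to three decimals, the conventional printout),
#'   `n_hits`, `n_nonmutant`, `threshold`.
#' @examples
#' prof <- generate_kinome_profile(403, n_mutant = 0, n_hits = 17,
#'                                 threshold = 10, seed = 1)
#' s_score(prof, 10)  # 17/403 = 0.042
#' @export
s_score <- function(profile, threshold = 10) {
  stopifnot(inherits(profile, "kinome_profile"))
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  nonmutant <- profile[!profile$is_mutant, , drop = FALSE]
  if (nrow(nonmutant) == 0) {
    stop("selectivity score needs at least one nonmutant kinase",
         call. = FALSE)
  }
  n_hits <- sum(nonmutant$pct_ctrl < threshold)
  score <- n_hits / nrow(nonmutant)
  structure(list(score = score,
                 score_3dp = round(score, 3),
                 n_hits = n_hits,
                 n_nonmutant = nrow(nonmutant),
                 threshold = threshold),
            class = "selectivity_score")
}

#' @export
print.selectivity_score <- function(x, ...) {
  cat(sprintf("S(%g) = %d/%d = %.3f\n", x$threshold, x$n_hits,
              x$n_nonmutant, x$score))
  invisible(x)
}

#' Call kinase hits below a %Ctrl threshold
#'
#' Nonmutant kinases with `pct_ctrl` strictly below `threshold`, sorted by
#' ascending %Ctrl (strongest binders first) with ties broken by kinase id.
#'
#' @inheritParams s_score
#' @return Data frame `(kinase, pct_ctrl)` of hits (possibly empty).
#' @export
call_hits <- function(profile, threshold = 10) {
  stopifnot(inherits(profile, "kinome_profile"))
  stop_if_not_scalar_number(threshold, "threshold", nonnegative = TRUE)
  nonmutant <- profile[!profile$is_mutant, , drop = FALSE]
  if (nrow(nonmutant) == 0) {
    stop("hit calling needs at least one nonmutant kinase", call. = FALSE)
  }
  hits <- nonmutant[nonmutant$pct_ctrl < threshold, c("kinase", "pct_ctrl"),
                    drop = FALSE]
  hits <- hits[order(hits$pct_ctrl, hits$kinase), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Selectivity curve S(x) over a grid of thresholds
#'
#' @inheritParams s_score
#' @param thresholds Positive thresholds in strictly ascending order.
#' @return Data frame `(threshold, s_score)`; the score column is
#'   nondecreasing in the threshold.
#' @export
selectivity_curve <- function(profile, thresholds) {
  if (length(thresholds) == 0 || any(thresholds <= 0)) {
    stop("`thresholds` must be positive", call. = FALSE)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly ascending", call. = FALSE)
  }
  data.frame(threshold = thresholds,
             s_score = vapply(thresholds,
                              function(t) s_score(profile, t)$score,
                              numeric(1)))
}
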