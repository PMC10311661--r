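#' Dose-response table
#'
#' Container for single-agent or fixed-ratio combination viability data:
#' one row per measurement with dose(s) and the fraction affected. Rows
#' violating the validity window are flagged (with a reason) rather than
#' silently dropped or clamped; flagged rows are excluded from fits.
#'
#' @param rows Data frame with columns `drug`, `dose1`, `dose2` (`NA` for
#'   single agents), `fa`, and optionally `flag`.
#' @return A `dose_response` object.
#' @export
dose_response <- function(rows) {
  req <- c("drug", "dose1", "dose2", "fa")
  if (!is.data.frame(rows) || !all(req %in% names(rows))) {
    stop("`rows` must have columns drug, dose1, dose2, fa", call. = FALSE)
  }
  if (is.null(rows$flag)) rows$flag <- NA_character_
  bad_dose <- !is.na(rows$dose1) & rows$dose1 <= 0 |
    (!is.na(rows$dose2) & rows$dose2 <= 0)
  if (any(bad_dose, na.rm = TRUE)) {
    stop("doses must be positive", call. = FALSE)
  }
  structure(rows[c(req, "flag")],
            class = c("dose_response", "data.frame"))
}

#' Fit the median-effect (Chou) model to a single-agent dose response
#'
#' Linearises the median-effect equation `fa/(1-fa) = (D/Dm)^m` as
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)` and fits it by unweighted
#' least squares. Measurements with `fa` outside the clipping window are
#' flagged and excluded (the logit blows up at the boundaries), as are
#' pre-flagged rows. A nonpositive fitted slope violates the model's
#' monotonicity and yields a flagged fit.
#'
#' @param dr A single-agent [dose_response()] (or data frame with columns
#'   `dose1`, `fa`).
#' @param fa_window Valid `fa` range for fitting, default `c(0.01, 0.99)`.
#' @return A `median_effect_fit`: list with `m`, `Dm`, `r_squared`,
#'   `n_points`, `flagged`, `drug`.
#' @examples
#' dr <- generate_dose_response(dose_response_params(m = 2, Dm = 10,
#'                                                   doses = c(2, 5, 10, 20)))
#' median_effect_fit(dr)
#' @export
median_effect_fit <- function(dr, fa_window = c(0.01, 0.99)) {
  if (!all(c("dose1", "fa") %in% names(dr))) {
    stop("`dr` must have columns dose1 and fa", call. = FALSE)
  }
  flag <- dr$flag %||% rep(NA_character_, nrow(dr))
  ok <- is.na(flag) & is.finite(dr$fa) & is.finite(dr$dose1) &
    dr$dose1 > 0 & dr$fa >= fa_window[1] & dr$fa <= fa_window[2]
  d <- dr[ok, , drop = FALSE]
  if (length(unique(d$dose1)) < 2) {
    stop("median-effect fit needs at least 2 distinct valid doses",
         call. = FALSE)
  }
  x <- log10(d$dose1)
  y <- log10(d$fa / (1 - d$fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(y) == 0) NA_real_ else
    suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  flagged <- !is.finite(m) || m <= 0
  structure(list(m = m,
                 Dm = if (flagged) NA_real_ else 10^(-b0 / m),
                 r_squared = r2,
                 n_points = nrow(d),
                 flagged = flagged,
                 drug = if (!is.null(d$drug)) d$drug[1] else NA_character_),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit (%s): m = %.4g, Dm = %.4g, r2 = %.4f (%d points)%s\n",
              x$drug, x$m, x$Dm, x$r_squared, x$n_points,
              if (x$flagged) " [FLAGGED: nonpositive slope]" else ""))
  invisible(x)
}

#' Dose required for a given effect under a median-effect fit
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`: the dose at which the single agent
#' alone produces fraction affected `fa`. Strictly increasing in `fa`;
#' `dx(0.5)` equals `Dm`.
#'
#' @param fa Fraction affected, strictly inside (0, 1) (vectorised).
#' @param fit A valid (unflagged) [median_effect_fit()].
#' @return Dose(s) on the same concentration scale as the fit.
#' @export
dx <- function(fa, fit) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (fit$flagged) stop("cannot invert a flagged median-effect fit",
                        call. = FALSE)
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("`fa` must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' Mutually exclusive (Loewe-type, two-term) combination index at an
#' observed combination effect: `CI = d1/Dx1(fa) + d2/Dx2(fa)`, where
#' `Dx_i(fa)` is the dose of drug i alone producing the same effect.
#' `CI < 1` indicates synergy, `CI = 1` additivity, `CI > 1` antagonism.
#'
#' @param d1,d2 Doses of the two drugs in the combination (>= 0;
#'   vectorised).
#' @param fa Measured fraction affected of the combination, in (0, 1).
#' @param fit1,fit2 Single-agent [median_effect_fit()]s.
#' @return Combination index value(s).
#' @export
combination_index <- function(d1, d2, fa, fit1, fit2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("doses must be >= 0", call. = FALSE)
  d1 / dx(fa, fit1) + d2 / dx(fa, fit2)
}

#' Fa-CI table for a drug combination
#'
#' Fits the median-effect model to both single agents, then computes the
#' combination index at every combination measurement using its measured
#' fraction affected (not a model prediction). Combination rows whose `fa`
#' falls outside the clipping window, or that arrived pre-flagged, are
#' kept in the table with `ci = NA` and a flag reason. Rows are sorted by
#' increasing `fa`.
#'
#' @param single1,single2 Single-agent [dose_response()] tables.
#' @param combo Combination [dose_response()] table (`dose1`, `dose2` both
#'   set).
#' @param fa_window Valid `fa` window for fitting and CI rows.
#' @return A `fa_ci_table`: data frame `(d1, d2, fa, ci, flag)` with the
#'   two fits and the exclusivity assumption in attributes.
#' @export
fa_ci_table <- function(single1, single2, combo,
                        fa_window = c(0.01, 0.99)) {
  fit1 <- tryCatch(median_effect_fit(single1, fa_window),
                   error = function(e) {
                     stop("invalid single-agent fit for drug 1 (",
                          single1$drug[1], "): ", conditionMessage(e),
                          call. = FALSE)
                   })
  fit2 <- tryCatch(median_effect_fit(single2, fa_window),
                   error = function(e) {
                     stop("invalid single-agent fit for drug 2 (",
                          single2$drug[1], "): ", conditionMessage(e),
                          call. = FALSE)
                   })
  for (f in list(fit1, fit2)) {
    if (f$flagged) {
      stop("invalid single-agent fit for drug ", f$drug,
           ": nonpositive median-effect slope", call. = FALSE)
    }
  }
  if (!all(c("dose1", "dose2", "fa") %in% names(combo))) {
    stop("`combo` must have dose1, dose2 and fa columns", call. = FALSE)
  }
  flag <- combo$flag %||% rep(NA_character_, nrow(combo))
  in_window <- is.finite(combo$fa) & combo$fa >= fa_window[1] &
    combo$fa <= fa_window[2]
  flag[is.na(flag) & !in_window] <- "fa outside clipping window"
  ok <- is.na(flag)
  ci <- rep(NA_real_, nrow(combo))
  ci[ok] <- combination_index(combo$dose1[ok], combo$dose2[ok],
                              combo$fa[ok], fit1, fit2)
  out <- data.frame(d1 = combo$dose1, d2 = combo$dose2, fa = combo$fa,
                    ci = ci, flag = flag, stringsAsFactors = FALSE)
  out <- out[order(out$fa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- list(drug1 = fit1, drug2 = fit2)
  attr(out, "exclusivity") <- "mutually-exclusive"
  class(out) <- c("fa_ci_table", "data.frame")
  out
}
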