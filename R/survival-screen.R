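#' Kaplan-Meier product-limit survival estimate
#'
#' @param records Data frame with columns `time` (days, > 0) and `event`
#'   (1 = death, 0 = censored).
#' @return Data frame `(time, n_risk, n_event, n_censor, surv)` — the
#'   right-continuous step function, starting from S(0) = 1 (rows are the
#'   distinct observed times).
#' @examples
#' km_estimate(data.frame(time = 1:4, event = 1))
#' @export
km_estimate <- function(records) {
  records <- validate_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

validate_records <- function(records, arg = "records") {
  if (!is.data.frame(records) ||
      !all(c("time", "event") %in% names(records))) {
    stop(sprintf("`%s` must have columns time and event", arg),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  records
}

#' Two-group log-rank test
#'
#' @param records_a,records_b Survival record data frames (see
#'   [km_estimate()]); at least one event in total.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank <- function(records_a, records_b) {
  a <- validate_records(records_a, "records_a")
  b <- validate_records(records_b, "records_b")
  if (sum(a$event) + sum(b$event) == 0) {
    stop("log-rank needs at least one event", call. = FALSE)
  }
  d <- rbind(a[c("time", "event")], b[c("time", "event")])
  d$group <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards estimate
#'
#' Fits `Surv(time, event) ~ covariate` with Efron tie handling and
#' reports the hazard ratio with a Wald 95% confidence interval. A
#' non-converging or separated fit (monotone likelihood) is reported with
#' `indeterminate = TRUE` instead of an error.
#'
#' @param covariate Numeric (binary or continuous) per-patient covariate,
#'   non-constant.
#' @param records Survival record data frame aligned with `covariate`.
#' @return List: `hr`, `ci95` (length 2), `p_value`, `coef`, `se`, `n`,
#'   `n_event`, `indeterminate`.
#' @export
cox_hr <- function(covariate, records) {
  records <- validate_records(records)
  if (length(covariate) != nrow(records)) {
    stop("`covariate` length must match `records`", call. = FALSE)
  }
  if (length(unique(covariate)) < 2) {
    stop("`covariate` is constant", call. = FALSE)
  }
  if (sum(records$event) == 0) {
    stop("Cox model needs at least one event", call. = FALSE)
  }
  d <- data.frame(time = records$time, event = records$event, x = covariate)
  warned <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, data = d,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge|singular", conditionMessage(w),
                  ignore.case = TRUE)) {
          warned <<- TRUE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(list(hr = NA_real_, ci95 = c(NA_real_, NA_real_),
                p_value = NA_real_, coef = NA_real_, se = NA_real_,
                n = nrow(d), n_event = sum(d$event), indeterminate = TRUE))
  }
  coef <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  indeterminate <- warned || !is.finite(coef) || !is.finite(se) ||
    abs(coef) > 15 || se > 100
  z <- stats::qnorm(0.975)
  list(hr = exp(coef),
       ci95 = exp(c(coef - z * se, coef + z * se)),
       p_value = 2 * stats::pnorm(-abs(coef / se)),
       coef = coef, se = se, n = nrow(d), n_event = sum(d$event),
       indeterminate = indeterminate)
}

#' Anchor-stratified synthetic-lethal survival screen
#'
#' Splits the cohort's patients into anchor-low and anchor-high strata at
#' the median tumor expression of the anchor gene (ties assigned to low).
#' Within each stratum, every candidate gene is dichotomised at its
#' within-stratum median into a LOW-expression indicator (1 = expression at
#' or below the stratum median), and a univariate Cox model estimates the
#' hazard ratio of the candidate-low group versus candidate-high. A
#' candidate is classified a synthetic-lethal (`"SL-partner"`) of the
#' anchor when low expression carries a significant hazard in the
#' anchor-low stratum (95% CI lower bound of HR_low above 1) while showing
#' no such significant hazard in the anchor-high stratum — the pattern
#' expected when simultaneous loss of both genes, and only that, is
#' deleterious. A stratum without events, or a non-converging fit, makes
#' the candidate `"indeterminate"` with the reason recorded.
#'
#' @param cohort An `expression_cohort` with survival records.
#' @param anchor Anchor gene id (non-constant across tumors).
#' @param candidates Character vector of candidate gene ids in the cohort.
#' @param candidate_covariate `"low-indicator"` (default, dichotomised) or
#'   `"continuous"` (the expression value itself; HR then per unit
#'   *decrease* so the SL direction reads the same way).
#' @param split Anchor split rule: `"median"`, `"tertile"` or `"quartile"`
#'   (the latter two drop the middle patients and compare outer groups).
#' @return An `sl_screen` data frame: one row per candidate with
#'   `hr_low`, `hr_low_lo`, `hr_low_hi`, `p_low`, the `_high` analogues,
#'   `classification` in `{SL-partner, not-partner, indeterminate}` and
#'   `reason` for indeterminate rows.
#' @export
stratified_sl_screen <- function(cohort, anchor, candidates,
                                 candidate_covariate = c("low-indicator",
                                                         "continuous"),
                                 split = c("median", "tertile",
                                           "quartile")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  candidate_covariate <- match.arg(candidate_covariate)
  split <- match.arg(split)
  if (!anchor %in% cohort$genes) {
    stop("anchor gene not present in cohort", call. = FALSE)
  }
  missing_cand <- setdiff(candidates, cohort$genes)
  if (length(missing_cand)) {
    stop("candidates not in cohort: ",
         paste(utils::head(missing_cand, 5), collapse = ", "),
         call. = FALSE)
  }
  tumor <- cohort_matrix(cohort, "tumor")
  anchor_expr <- tumor[anchor, ]
  if (length(unique(anchor_expr)) < 2) {
    stop("anchor expression is constant across patients", call. = FALSE)
  }
  surv <- cohort$survival
  rownames(surv) <- surv$patient
  surv <- surv[colnames(tumor), ]

  q <- switch(split,
              median = 0.5,
              tertile = 1 / 3,
              quartile = 0.25)
  lo_cut <- stats::quantile(anchor_expr, q, names = FALSE)
  hi_cut <- stats::quantile(anchor_expr, 1 - q, names = FALSE)
  strata <- list(low = which(anchor_expr <= lo_cut),
                 high = which(anchor_expr > hi_cut))

  one_stratum <- function(gene, idx) {
    x <- tumor[gene, idx]
    rec <- surv[idx, c("time", "event")]
    if (sum(rec$event) == 0) {
      return(list(hr = NA_real_, ci95 = c(NA_real_, NA_real_),
                  p_value = NA_real_, indeterminate = TRUE,
                  reason = "no events in stratum"))
    }
    covar <- if (candidate_covariate == "low-indicator") {
      as.numeric(x <= stats::median(x))
    } else {
      -x  # per-unit decrease, so HR > 1 still reads "low is hazardous"
    }
    if (length(unique(covar)) < 2) {
      return(list(hr = NA_real_, ci95 = c(NA_real_, NA_real_),
                  p_value = NA_real_, indeterminate = TRUE,
                  reason = "constant covariate in stratum"))
    }
    res <- cox_hr(covar, rec)
    res$reason <- if (res$indeterminate) "non-converging fit" else NA_character_
    res
  }

  rows <- lapply(sort(unique(candidates)), function(gene) {
    lo <- one_stratum(gene, strata$low)
    hi <- one_stratum(gene, strata$high)
    classification <- if (lo$indeterminate || hi$indeterminate) {
      "indeterminate"
    } else if (lo$ci95[1] > 1 && !(hi$ci95[1] > 1)) {
      "SL-partner"
    } else {
      "not-partner"
    }
    data.frame(gene = gene,
               hr_low = lo$hr, hr_low_lo = lo$ci95[1],
               hr_low_hi = lo$ci95[2], p_low = lo$p_value,
               hr_high = hi$hr, hr_high_lo = hi$ci95[1],
               hr_high_hi = hi$ci95[2], p_high = hi$p_value,
               classification = classification,
               reason = if (classification == "indeterminate") {
                 paste(stats::na.omit(c(lo$reason, hi$reason)),
                       collapse = "; ")
               } else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sl_screen", "data.frame")
  out
}
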