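#' Parameters for the synthetic paired tumor/normal cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The cohort
#' emulates a pan-cancer style paired design: each patient contributes one
#' tumor and one matched normal sample, tumors carry a latent
#' mitotic-activity factor that loads on a set of signature genes (and on
#' the anchor kinase gene), and overall survival depends on that activity
#' through a proportional-hazards model. Optionally a synthetic-lethal
#' partner gene is planted: patients whose tumor expression of both the
#' anchor and the partner falls at or below the cohort median receive an
#' extra additive term on the log hazard.
#'
#' @param n_patients Number of patients (each with a tumor and a matched
#'   normal sample).
#' @param n_genes Total number of genes in the expression matrix (must
#'   exceed `n_signature_genes` plus the anchor and any partner gene).
#' @param n_signature_genes Number of planted active-mitosis signature
#'   genes (loading on the latent factor and shifted up in tumors).
#' @param anchor_gene Gene id used for the anchor mitotic kinase (the role
#'   GSG2/HASPIN plays in the real analysis).
#' @param factor_loading Loading of signature genes (and the anchor) on the
#'   latent per-patient activity factor; `0` removes the shared factor.
#' @param tumor_shift Mean elevation of signature genes (and anchor) in
#'   tumor relative to matched normal, on the same arbitrary log-like scale
#'   as the noise.
#' @param hazard_beta Log-hazard increase per unit latent activity.
#' @param sl_partner_gene Optional gene id of a planted synthetic-lethal
#'   partner (`NULL` for none). The partner is a background gene unless the
#'   id names a signature gene explicitly.
#' @param sl_interaction_beta Extra log-hazard applied only to patients
#'   with both anchor and partner tumor expression at or below the cohort
#'   median ("both low").
#' @param censor_rate Fraction of patients administratively censored, in
#'   `[0, 1]`.
#' @param noise_sd Standard deviation of the gaussian expression noise
#'   (must be > 0).
#' @param baseline_hazard Baseline event rate per day of the exponential
#'   survival model. The default (1/1000) gives a median survival of about
#'   two years for a patient at zero activity.
#' @param seed Integer seed; all random substreams derive from it.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_patients,
                          n_genes,
                          n_signature_genes,
                          anchor_gene = "GSG2",
                          factor_loading = 1,
                          tumor_shift = 1,
                          hazard_beta = 0.5,
                          sl_partner_gene = NULL,
                          sl_interaction_beta = 0,
                          censor_rate = 0.2,
                          noise_sd = 0.5,
                          baseline_hazard = 1 / 1000,
                          seed = 1L) {
  stop_if_not_scalar_number(n_patients, "n_patients", positive = TRUE)
  stop_if_not_scalar_number(n_genes, "n_genes", positive = TRUE)
  stop_if_not_scalar_number(n_signature_genes, "n_signature_genes",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(factor_loading, "factor_loading",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(tumor_shift, "tumor_shift")
  stop_if_not_scalar_number(hazard_beta, "hazard_beta")
  stop_if_not_scalar_number(sl_interaction_beta, "sl_interaction_beta")
  stop_if_not_scalar_number(censor_rate, "censor_rate", nonnegative = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  stop_if_not_scalar_number(baseline_hazard, "baseline_hazard",
                            positive = TRUE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (censor_rate > 1) stop("`censor_rate` must lie in [0, 1]", call. = FALSE)
  if (n_signature_genes >= n_genes) {
    stop("`n_signature_genes` must be smaller than `n_genes`", call. = FALSE)
  }
  n_special <- 1L + (!is.null(sl_partner_gene))
  if (n_signature_genes + n_special > n_genes) {
    stop("`n_genes` too small for signature + anchor (+ partner) genes",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_genes = as.integer(n_genes),
         n_signature_genes = as.integer(n_signature_genes),
         anchor_gene = anchor_gene,
         factor_loading = factor_loading,
         tumor_shift = tumor_shift,
         hazard_beta = hazard_beta,
         sl_partner_gene = sl_partner_gene,
         sl_interaction_beta = sl_interaction_beta,
         censor_rate = censor_rate,
         noise_sd = noise_sd,
         baseline_hazard = baseline_hazard,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Generate a synthetic paired tumor/normal expression cohort
#'
#' Simulates the statistical structure the downstream analyses assume:
#'
#' * each tumor sample `i` carries a latent mitotic activity
#'   `a_i ~ N(0, 1)`;
#' * signature genes and the anchor gene are
#'   `factor_loading * a_i + tumor_shift + noise` in tumors and pure noise
#'   in matched normals; background genes are pure noise everywhere;
#' * overall survival is exponential with hazard
#'   `baseline_hazard * exp(hazard_beta * a_i + sl_interaction_beta * I_i)`
#'   where `I_i` indicates that tumor expression of both the anchor and the
#'   planted partner is at or below the cohort median;
#' * with probability `censor_rate` a patient is administratively censored
#'   at a uniform fraction of the latent event time.
#'
#' The planted truth (signature gene ids, per-patient activity, the
#' both-low indicator) is stored in `$truth` for recovery tests.
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `expression_cohort`: a list with elements
#'   `genes`, `samples`, `values` (gene-by-sample matrix), `condition`
#'   (per-sample `"tumor"`/`"normal"`), `patient` (per-sample patient id),
#'   `pairing` (data frame of matched normal/tumor sample ids),
#'   `survival` (data frame `patient`, `time`, `event`), `truth`, and the
#'   generating `params`.
#' @examples
#' co <- generate_cohort(cohort_params(n_patients = 40, n_genes = 50,
#'                                     n_signature_genes = 10, seed = 7))
#' dim(co$values)
#' head(co$survival)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_seed(p$seed, {
    patients <- make_ids("PT", p$n_patients)
    tumor_samples <- paste0(patients, "-T")
    normal_samples <- paste0(patients, "-N")
    samples <- c(tumor_samples, normal_samples)
    condition <- rep(c("tumor", "normal"), each = p$n_patients)

    sig_genes <- make_ids("MSIG", p$n_signature_genes)
    n_background <- p$n_genes - p$n_signature_genes - 1L
    background <- make_ids("BG", max(n_background, 0L))
    genes <- c(p$anchor_gene, sig_genes, background)
    if (!is.null(p$sl_partner_gene) && !(p$sl_partner_gene %in% genes)) {
      # partner takes the place of the last background gene
      genes[length(genes)] <- p$sl_partner_gene
    }

    activity <- stats::rnorm(p$n_patients)
    values <- matrix(stats::rnorm(length(genes) * length(samples),
                                  sd = p$noise_sd),
                     nrow = length(genes), ncol = length(samples),
                     dimnames = list(genes, samples))
    loaded <- c(p$anchor_gene, sig_genes)
    loaded <- loaded[loaded %in% genes]
    signal <- p$factor_loading * activity + p$tumor_shift
    values[loaded, tumor_samples] <-
      values[loaded, tumor_samples] +
      matrix(signal, nrow = length(loaded), ncol = p$n_patients, byrow = TRUE)

    anchor_tumor <- values[p$anchor_gene, tumor_samples]
    anchor_low <- anchor_tumor <= stats::median(anchor_tumor)
    if (!is.null(p$sl_partner_gene)) {
      partner_tumor <- values[p$sl_partner_gene, tumor_samples]
      partner_low <- partner_tumor <= stats::median(partner_tumor)
      both_low <- anchor_low & partner_low
    } else {
      partner_low <- rep(NA, p$n_patients)
      both_low <- rep(FALSE, p$n_patients)
    }

    log_hazard <- p$hazard_beta * activity +
      p$sl_interaction_beta * as.numeric(both_low)
    event_time <- stats::rexp(p$n_patients,
                              rate = p$baseline_hazard * exp(log_hazard))
    censored <- stats::runif(p$n_patients) < p$censor_rate
    obs_time <- ifelse(censored,
                       pmax(event_time * stats::runif(p$n_patients), 1e-6),
                       event_time)
    survival <- data.frame(patient = patients,
                           time = obs_time,
                           event = as.integer(!censored),
                           stringsAsFactors = FALSE)

    structure(
      list(genes = genes,
           samples = samples,
           values = values,
           condition = stats::setNames(condition, samples),
           patient = stats::setNames(rep(patients, 2L), samples),
           pairing = data.frame(patient = patients,
                                normal = normal_samples,
                                tumor = tumor_samples,
                                stringsAsFactors = FALSE),
           survival = survival,
           truth = list(signature_genes = sig_genes,
                        activity = stats::setNames(activity, patients),
                        anchor_low = stats::setNames(anchor_low, patients),
                        partner_low = stats::setNames(partner_low, patients),
                        sl_partner_gene = p$sl_partner_gene),
           params = p),
      class = "expression_cohort"
    )
  })
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf(
    "expression_cohort: %d genes x %d samples (%d paired patients)\n",
    length(x$genes), length(x$samples), nrow(x$pairing)))
  cat(sprintf("  anchor gene: %s; planted signature genes: %d\n",
              x$params$anchor_gene, length(x$truth$signature_genes)))
  cat(sprintf("  events: %d / %d patients\n",
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Tumor (or normal) sub-matrix of a cohort, columns ordered by patient
#'
#' @param cohort An `expression_cohort`.
#' @param condition `"tumor"` or `"normal"`.
#' @return A gene-by-patient matrix; column order follows
#'   `cohort$pairing$patient` so tumor and normal matrices are aligned.
#' @export
cohort_matrix <- function(cohort, condition = c("tumor", "normal")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  condition <- match.arg(condition)
  cols <- if (condition == "tumor") cohort$pairing$tumor else
    cohort$pairing$normal
  m <- cohort$values[, cols, drop = FALSE]
  colnames(m) <- cohort$pairing$patient
  m
}
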