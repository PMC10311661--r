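# Independent brute-force oracles used to freeze expected values.
# Each is a direct, position-by-position enumeration, deliberately naive
# and unrelated to the package's vectorised implementations.

# Weighted-KS running sum by explicit loop over ranked positions.
oracle_ks_es <- function(scores_desc, hit_positions, w_exp) {
  n <- length(scores_desc)
  hits <- seq_len(n) %in% hit_positions
  weights <- abs(scores_desc)^w_exp
  hit_total <- sum(weights[hits])
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      running <- running + weights[i] / hit_total
    } else {
      running <- running - 1 / (n - length(hit_positions))
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# ssGSEA integral accumulation by explicit loop.
oracle_ssgsea <- function(n, hit_positions, tau) {
  hits <- seq_len(n) %in% hit_positions
  w <- (n - seq_len(n) + 1)^tau
  in_total <- sum(w[hits])
  cum_in <- 0
  cum_out <- 0
  score <- 0
  for (i in seq_len(n)) {
    if (hits[i]) cum_in <- cum_in + w[i] / in_total
    else cum_out <- cum_out + 1 / (n - length(hit_positions))
    score <- score + (cum_in - cum_out)
  }
  score
}

# Product-limit table built row by row.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  surv <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    deaths <- sum(time == times[i] & event == 1)
    surv <- surv * (1 - deaths / at_risk)
    out$surv[i] <- surv
  }
  out
}

# Two-group log-rank chi-square by observed-minus-expected accumulation
# at each distinct event time (hypergeometric variance).
oracle_logrank <- function(time, event, group) {
  event_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    n_tot <- sum(time >= t)
    n_a <- sum(time >= t & group == "a")
    d_tot <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & group == "a")
    e_a <- d_tot * n_a / n_tot
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n_tot > 1) {
      v <- v + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  (o_minus_e)^2 / v
}

# Mann-Whitney U by exhaustive pair counting (ties count 1/2).
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi < yj) + 0.5 * (xi == yj)
  }
  u
}

# Expected within-family Tanimoto by direct pair simulation under the
# fingerprint generative model (prototype bits inherited with prob q,
# otherwise redrawn at density d).
oracle_tanimoto_expectation <- function(q, d, n_bits, n_pairs, seed) {
  set.seed(seed)
  sims <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    proto <- runif(n_bits) < d
    mk <- function() {
      inherit <- runif(n_bits) < q
      ifelse(inherit, proto, runif(n_bits) < d)
    }
    a <- mk(); b <- mk()
    sims[i] <- sum(a & b) / sum(a | b)
  }
  mean(sims)
}

# Small paired cohort fixture shared by several tests.
small_cohort <- function(n_patients = 60, n_genes = 100, seed = 42, ...) {
  generate_cohort(cohort_params(n_patients = n_patients, n_genes = n_genes,
                                n_signature_genes = 20, seed = seed, ...))
}
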