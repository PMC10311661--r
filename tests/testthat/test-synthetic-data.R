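test_that("cohort generation is deterministic and validates parameters", {
  p <- cohort_params(n_patients = 30, n_genes = 50, n_signature_genes = 10,
                     seed = 5)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$values, b$values)
  expect_identical(a$survival, b$survival)

  expect_error(cohort_params(n_patients = 10, n_genes = 10,
                             n_signature_genes = 10, seed = 1),
               "n_signature_genes")
  expect_error(cohort_params(n_patients = 10, n_genes = 20,
                             n_signature_genes = 5, noise_sd = 0),
               "noise_sd")
  expect_error(cohort_params(n_patients = 10, n_genes = 20,
                             n_signature_genes = 5, censor_rate = 1.5),
               "censor_rate")
})

test_that("cohort structure satisfies its invariants", {
  co <- small_cohort(n_patients = 40, sl_partner_gene = "BG001")
  expect_equal(dim(co$values), c(100, 80))
  expect_false(anyNA(co$values))
  expect_true(all(co$survival$time > 0))
  expect_true(all(co$pairing$tumor %in% co$samples))
  expect_true(all(co$pairing$normal %in% co$samples))
  expect_identical(unname(co$condition[co$pairing$tumor]),
                   rep("tumor", 40))
  expect_identical(unname(co$condition[co$pairing$normal]),
                   rep("normal", 40))
  expect_length(co$truth$signature_genes, 20)
  expect_true(all(co$truth$signature_genes %in% co$genes))
})

test_that("no shared factor means no anchor-signature correlation", {
  co <- generate_cohort(cohort_params(
    n_patients = 500, n_genes = 60, n_signature_genes = 20,
    factor_loading = 0, tumor_shift = 0, seed = 9))
  tum <- cohort_matrix(co, "tumor")
  r <- vapply(co$truth$signature_genes,
              function(g) cor(tum["GSG2", ], tum[g, ]), numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("anchor-signature correlation matches the one-factor closed form", {
  # two variables sharing one factor: cor = L^2 / (L^2 + sigma^2)
  L <- 1; sigma <- 0.5
  expected <- L^2 / (L^2 + sigma^2)
  co <- generate_cohort(cohort_params(
    n_patients = 500, n_genes = 60, n_signature_genes = 20,
    factor_loading = L, noise_sd = sigma, seed = 13))
  tum <- cohort_matrix(co, "tumor")
  r <- vapply(co$truth$signature_genes,
              function(g) cor(tum["GSG2", ], tum[g, ], method = "spearman"),
              numeric(1))
  expect_lt(abs(mean(r) - expected), 0.1)
})

test_that("kinome generator plants exactly the requested hit structure", {
  prof <- generate_kinome_profile(403, 0, 17, threshold = 10, seed = 1)
  expect_s3_class(prof, "kinome_profile")
  expect_equal(sum(prof$pct_ctrl < 10), 17)
  expect_equal(s_score(prof, 10)$score, 17 / 403)

  expect_equal(s_score(generate_kinome_profile(50, 0, 0, 10, seed = 2),
                       10)$score, 0)
  expect_equal(s_score(generate_kinome_profile(50, 0, 50, 10, seed = 3),
                       10)$score, 1)
  expect_error(generate_kinome_profile(10, 5, 6, 10, seed = 1), "nonmutant")

  with_mut <- generate_kinome_profile(100, 20, 10, 10, seed = 4)
  expect_equal(sum(with_mut$is_mutant), 20)
  expect_equal(s_score(with_mut, 10)$score, 10 / 80)
})

test_that("dose-response generator reproduces the median-effect equation", {
  # D = Dm gives half effect by definition
  expect_equal(generate_dose_response(
    dose_response_params(m = 3, Dm = 7, doses = 7))$fa, 0.5)
  # m=1, Dm=1, D=3: 3/(1+3)
  expect_equal(generate_dose_response(
    dose_response_params(m = 1, Dm = 1, doses = 3))$fa, 0.75)
  # m=2, Dm=10, D=5: 0.25/1.25
  expect_equal(generate_dose_response(
    dose_response_params(m = 2, Dm = 10, doses = 5))$fa, 0.2)
  expect_error(dose_response_params(m = 1, Dm = 1, doses = c(1, -2)),
               "positive")
})

test_that("noiseless combinations carry CI equal to combo_alpha", {
  p1 <- dose_response_params(m = 0.8, Dm = 2, doses = 1)
  p2 <- dose_response_params(m = 2, Dm = 30, doses = 1)
  f1 <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 0.8, Dm = 2, doses = c(0.5, 1, 2, 4, 8))))
  f2 <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 2, Dm = 30, doses = c(10, 20, 40, 80))))
  for (alpha in c(0.25, 0.5, 1, 2)) {
    combo <- generate_combination(p1, p2, combo_alpha = alpha,
                                  ratio = c(1, 3), doses = c(1, 5, 20, 60))
    ci <- combination_index(combo$dose1, combo$dose2, combo$fa, f1, f2)
    expect_equal(ci, rep(alpha, 4), tolerance = 1e-6)
  }
})

test_that("fingerprint families honour the overlap parameter", {
  identical_fam <- generate_fingerprints(6, n_bits = 256,
                                         family_overlap = 1, seed = 1)
  expect_equal(tanimoto(identical_fam[[1]], identical_fam[[2]]), 1)

  disjoint <- generate_fingerprints(8, n_bits = 256, family_overlap = 1,
                                    n_families = 2,
                                    disjoint_families = TRUE, seed = 2)
  fams <- vapply(disjoint, attr, numeric(1), "family")
  a <- disjoint[[which(fams == 1)[1]]]
  b <- disjoint[[which(fams == 2)[1]]]
  expect_equal(tanimoto(a, b), 0)

  expect_error(generate_fingerprints(4, family_overlap = 1.2), "0, 1")
})

test_that("mean within-family Tanimoto matches a Monte-Carlo expectation", {
  q <- 0.5; d <- 0.1; n_bits <- 1024
  expected <- oracle_tanimoto_expectation(q, d, n_bits, n_pairs = 2000,
                                          seed = 99)
  fps <- generate_fingerprints(50, n_bits = n_bits, family_overlap = q,
                               bit_density = d, seed = 7)
  pairs <- combn(50, 2)
  observed <- mean(apply(pairs, 2,
                         function(ij) tanimoto(fps[[ij[1]]], fps[[ij[2]]])))
  expect_lt(abs(observed - expected), 0.05)
})

test_that("generators restore the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_kinome_profile(20, 0, 3, 10, seed = 77))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("null survival simulation gives calibrated log-rank rejections", {
  # hazard_beta = 0 and no SL interaction: splitting on any expression
  # stratum must give uniform log-rank p-values
  n_rep <- 400
  reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(cohort_params(
      n_patients = 40, n_genes = 10, n_signature_genes = 3,
      hazard_beta = 0, sl_interaction_beta = 0, censor_rate = 0.2,
      seed = 5000 + i))
    tum <- cohort_matrix(co, "tumor")
    split_gene <- tum["BG001", ]
    low <- split_gene <= median(split_gene)
    surv <- co$survival
    p <- logrank(surv[low, ], surv[!low, ])$p_value
    reject[i] <- p < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})
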