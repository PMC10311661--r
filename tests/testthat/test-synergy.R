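test_that("noiseless median-effect curves are inverted exactly", {
  for (m in c(0.5, 1, 2)) {
    for (Dm in c(1, 10)) {
      dr <- generate_dose_response(
        dose_response_params(m = m, Dm = Dm,
                             doses = Dm * c(0.2, 0.5, 1, 2, 5)))
      fit <- median_effect_fit(dr)
      expect_equal(fit$m, m, tolerance = 1e-10)
      expect_equal(fit$Dm, Dm, tolerance = 1e-10)
      expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    }
  }
  # two exact points suffice
  two <- dose_response(data.frame(drug = "d", dose1 = c(0.5, 2),
                                  dose2 = NA, fa = c(1 / 3, 2 / 3)))
  fit2 <- median_effect_fit(two)
  expect_equal(fit2$m, 1, tolerance = 1e-10)
  expect_equal(fit2$Dm, 1, tolerance = 1e-10)
})

test_that("median-effect fitting flags or rejects degenerate input", {
  one <- dose_response(data.frame(drug = "d", dose1 = 5, dose2 = NA,
                                  fa = 0.4))
  expect_error(median_effect_fit(one), "2 distinct")
  # decreasing effect with dose: nonpositive slope is flagged
  dec <- dose_response(data.frame(drug = "d", dose1 = c(1, 2, 4),
                                  dose2 = NA, fa = c(0.8, 0.5, 0.2)))
  expect_true(median_effect_fit(dec)$flagged)
  # out-of-window points are excluded from the fit
  wide <- dose_response(data.frame(drug = "d", dose1 = c(0.01, 1, 2, 500),
                                   dose2 = NA,
                                   fa = c(0.0001, 0.5, 2 / 3, 0.9999)))
  fit <- median_effect_fit(wide)
  expect_equal(fit$n_points, 2)
  expect_equal(fit$m, 1, tolerance = 1e-10)
})

test_that("noisy median-effect recovery stays within 10% median error", {
  m <- 1.5; Dm <- 10
  rel_err <- vapply(seq_len(200), function(i) {
    dr <- generate_dose_response(
      dose_response_params(m = m, Dm = Dm,
                           doses = Dm * 2^seq(-3.5, 3.5, length.out = 8),
                           noise_sd = 0.1, seed = 2200 + i))
    abs(median_effect_fit(dr)$m - m) / m
  }, numeric(1))
  expect_lte(median(rel_err), 0.1)
})

test_that("dose-for-effect inversion follows the median-effect identities", {
  fit <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 2, Dm = 10, doses = c(2, 5, 10, 20))))
  expect_equal(dx(0.5, fit), 10, tolerance = 1e-10)
  expect_equal(dx(0.2, fit), 5, tolerance = 1e-10)
  fit1 <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 1, Dm = 1, doses = c(0.5, 1, 2))))
  expect_equal(dx(0.75, fit1), 3, tolerance = 1e-10)
  # strictly increasing in fa
  fas <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dx(fas, fit)) > 0))
  expect_error(dx(1.2, fit), "inside")
})

test_that("combination index identities hold", {
  fit1 <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 1, Dm = 2, doses = c(0.5, 2, 8))))
  fit2 <- median_effect_fit(generate_dose_response(
    dose_response_params(m = 2, Dm = 30, doses = c(10, 30, 90))))
  fa <- 0.6
  # half-isobole sum: each drug at half its own Dx
  expect_equal(combination_index(dx(fa, fit1) / 2, dx(fa, fit2) / 2, fa,
                                 fit1, fit2), 1, tolerance = 1e-12)
  # degenerate single-agent case
  expect_equal(combination_index(dx(fa, fit1), 0, fa, fit1, fit2), 1,
               tolerance = 1e-12)
  # linear in joint dose scaling at fixed fa
  ci1 <- combination_index(1, 4, fa, fit1, fit2)
  ci3 <- combination_index(3, 12, fa, fit1, fit2)
  expect_equal(ci3, 3 * ci1, tolerance = 1e-12)
})

test_that("round-trip CI through refitted curves equals planted alpha", {
  p1 <- dose_response_params(m = 1, Dm = 2, doses = c(0.25, 1, 4, 16))
  p2 <- dose_response_params(m = 2, Dm = 30, doses = c(5, 15, 45, 135))
  fit1 <- median_effect_fit(generate_dose_response(p1))
  fit2 <- median_effect_fit(generate_dose_response(p2))
  for (alpha in c(0.5, 1, 2)) {
    combo <- generate_combination(p1, p2, combo_alpha = alpha,
                                  ratio = c(1, 10),
                                  doses = c(2, 10, 40, 100))
    ci <- combination_index(combo$dose1, combo$dose2, combo$fa, fit1, fit2)
    expect_equal(ci, rep(alpha, 4), tolerance = 1e-6)
  }
})

test_that("a 2 x 3 dose grid yields a six-row Fa-CI table", {
  p1 <- dose_response_params(m = 1.2, Dm = 300,
                             doses = c(50, 150, 300, 600, 1200))
  p2 <- dose_response_params(m = 1.5, Dm = 3, doses = c(0.5, 1.5, 3, 6, 12))
  s1 <- generate_dose_response(p1, "drugA")
  s2 <- generate_dose_response(p2, "drugB")
  # two doses of drug A crossed with three doses of drug B
  grid <- expand.grid(dose1 = c(250, 500), dose2 = c(1, 3, 5))
  fa <- vapply(seq_len(6), function(i) {
    cmb <- generate_combination(p1, p2, combo_alpha = 0.5,
                                ratio = c(grid$dose1[i], grid$dose2[i]),
                                doses = grid$dose1[i] + grid$dose2[i])
    cmb$fa
  }, numeric(1))
  combo <- dose_response(data.frame(drug = "A+B", dose1 = grid$dose1,
                                    dose2 = grid$dose2, fa = fa))
  tab <- fa_ci_table(s1, s2, combo)
  expect_s3_class(tab, "fa_ci_table")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$ci, rep(0.5, 6), tolerance = 1e-6)
  expect_true(all(diff(tab$fa) >= 0))
})

test_that("synergy detection and additivity calibration hold under noise", {
  p1 <- dose_response_params(m = 1, Dm = 2, doses = c(0.25, 1, 4, 16))
  p2 <- dose_response_params(m = 2, Dm = 30, doses = c(5, 15, 45, 135))
  run_once <- function(alpha, seed) {
    s1 <- generate_dose_response(
      dose_response_params(m = 1, Dm = 2, doses = p1$doses,
                           noise_sd = 0.05, seed = seed))
    s2 <- generate_dose_response(
      dose_response_params(m = 2, Dm = 30, doses = p2$doses,
                           noise_sd = 0.05, seed = seed + 1))
    combo <- generate_combination(p1, p2, combo_alpha = alpha,
                                  ratio = c(1, 10),
                                  doses = c(2, 10, 40, 100),
                                  noise_sd = 0.05, seed = seed + 2)
    fa_ci_table(s1, s2, combo)$ci
  }
  synergy_all <- vapply(seq_len(50), function(i) {
    all(run_once(0.5, 3000 + 10 * i) < 1)
  }, logical(1))
  expect_gte(mean(synergy_all), 0.9)

  additive_mean <- vapply(seq_len(50), function(i) {
    mean(run_once(1, 4000 + 10 * i))
  }, numeric(1))
  expect_gte(mean(additive_mean), 0.9)
  expect_lte(mean(additive_mean), 1.1)
})

test_that("fa_ci_table flags out-of-window rows and names bad drugs", {
  p1 <- dose_response_params(m = 1, Dm = 1, doses = c(0.5, 1, 2))
  s1 <- generate_dose_response(p1, "good")
  combo <- dose_response(data.frame(drug = "c", dose1 = c(1, 1),
                                    dose2 = c(1, 1), fa = c(0.5, 0.999)))
  tab <- fa_ci_table(s1, s1, combo)
  expect_equal(sum(!is.na(tab$ci)), 1)
  expect_match(tab$flag[is.na(tab$ci)], "window")

  bad <- dose_response(data.frame(drug = "shrinker", dose1 = c(1, 2, 4),
                                  dose2 = NA, fa = c(0.8, 0.5, 0.2)))
  expect_error(fa_ci_table(bad, s1, combo), "shrinker")
})
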