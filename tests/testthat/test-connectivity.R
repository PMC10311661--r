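test_that("extreme arrangements reach the KS enrichment bounds", {
  prof <- ranked_profile(letters[1:10], 10:1)
  expect_equal(weighted_ks_es(prof, c("a", "b", "c"), 0), 1)
  expect_equal(weighted_ks_es(prof, c("h", "i", "j"), 0), -1)
  expect_error(weighted_ks_es(prof, c("zz"), 0), "intersect")
  expect_error(weighted_ks_es(prof, letters[1:10], 0), "whole profile")
})

test_that("weighted KS matches brute-force enumeration on 10 positions", {
  scores <- c(5, 4, 3, 2.5, 2, 1.5, 1, -1, -2, -4)
  genes <- paste0("g", 1:10)
  prof <- ranked_profile(genes, scores)
  for (w in c(0, 1)) {
    for (set_pos in list(c(2, 5, 8), c(1, 10), c(3, 4, 5, 6))) {
      expect_equal(weighted_ks_es(prof, genes[set_pos], w),
                   oracle_ks_es(scores, set_pos, w),
                   info = sprintf("w=%g set={%s}", w,
                                  paste(set_pos, collapse = ",")))
    }
  }
})

test_that("rank-only KS is invariant under monotone score transforms", {
  set.seed(1)
  scores <- sort(rnorm(40), decreasing = TRUE)
  genes <- paste0("g", 1:40)
  prof <- ranked_profile(genes, scores)
  prof2 <- ranked_profile(genes, 2 * scores + 10)    # strictly monotone
  prof3 <- ranked_profile(genes, rank(scores))
  set <- genes[c(3, 7, 20, 33)]
  expect_equal(weighted_ks_es(prof2, set, 0), weighted_ks_es(prof, set, 0))
  expect_equal(weighted_ks_es(prof3, set, 0), weighted_ks_es(prof, set, 0))
})

test_that("enrichment scores agree with the fgsea reference implementation", {
  set.seed(2)
  stats <- sort(rnorm(60), decreasing = TRUE)
  names(stats) <- paste0("g", 1:60)
  prof <- ranked_profile(names(stats), stats)
  for (sel in list(c(3L, 10L, 25L, 40L, 59L), 1:6, 55:60)) {
    for (w in c(0, 1)) {
      expect_equal(weighted_ks_es(prof, names(stats)[sel], w),
                   fgsea::calcGseaStat(stats, sel, gseaParam = w),
                   tolerance = 1e-12,
                   info = sprintf("w=%g", w))
    }
  }
})

test_that("wtcs combines up and down enrichment with the sign rule", {
  prof <- ranked_profile(letters[1:10], 10:1)
  q <- query_signature(c("a", "b"), c("i", "j"))
  expect_equal(wtcs(prof, q, 0), 1)
  # swapping up and down negates the score
  q_swap <- query_signature(c("i", "j"), c("a", "b"))
  expect_equal(wtcs(prof, q_swap, 0), -1)
  # both sets at the top: same-sign ES pair scores 0
  q_same <- query_signature(c("a", "b"), c("c", "d"))
  es_up <- weighted_ks_es(prof, c("a", "b"), 0)
  es_down <- weighted_ks_es(prof, c("c", "d"), 0)
  expect_true(sign(es_up) == sign(es_down))
  expect_equal(wtcs(prof, q_same, 0), 0)
  # |wtcs| bounded by the larger |ES|
  set.seed(4)
  for (i in 1:20) {
    genes <- paste0("g", 1:30)
    prof_r <- ranked_profile(genes, rnorm(30))
    picks <- sample(genes, 8)
    qr <- query_signature(picks[1:4], picks[5:8])
    w <- wtcs(prof_r, qr, 1)
    bound <- max(abs(weighted_ks_es(prof_r, qr$up, 1)),
                 abs(weighted_ks_es(prof_r, qr$down, 1)))
    expect_lte(abs(w), bound + 1e-12)
    expect_lte(bound, 1)
  }
})

test_that("preranked GSEA p-values obey the add-one floor and match ES", {
  prof <- ranked_profile(paste0("g", 1:50), 50:1)
  res <- preranked_gsea(prof, paste0("g", 1:5), weight_exponent = 0,
                        n_permutations = 999, seed = 3)
  expect_equal(res$es, weighted_ks_es(prof, paste0("g", 1:5), 0))
  expect_equal(res$p_value, 1 / 1000)  # top-ranked set, no permutation ties
  expect_error(preranked_gsea(prof, paste0("g", 1:5), 0,
                              n_permutations = 50), "100")
})

test_that("tanimoto satisfies its identities and error contract", {
  a <- fingerprint("a", c(1, 2, 3), 16)
  b <- fingerprint("b", c(2, 3, 4), 16)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(b, a), tanimoto(a, b))
  expect_equal(tanimoto(a, fingerprint("c", c(5, 6), 16)), 0)
  expect_error(tanimoto(a, fingerprint("d", 1, 32)), "lengths")
  expect_error(tanimoto(fingerprint("e", integer(0), 16),
                        fingerprint("f", integer(0), 16)), "empty")
  # 1 - tanimoto triangle inequality on random triples
  set.seed(8)
  for (i in 1:25) {
    fps <- lapply(1:3, function(j) {
      fingerprint(paste0("x", j), which(runif(64) < 0.3), 64)
    })
    d12 <- 1 - tanimoto(fps[[1]], fps[[2]])
    d13 <- 1 - tanimoto(fps[[1]], fps[[3]])
    d23 <- 1 - tanimoto(fps[[2]], fps[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("rank_candidates retrieves a self-derived reference first", {
  genes <- paste0("g", 1:100)
  q <- query_signature(genes[1:10], genes[91:100])
  profiles <- generate_ranked_profiles(genes, q, n_profiles = 10,
                                       planted_id = "SELF", signal = 5,
                                       seed = 21)
  tab <- rank_candidates(profiles, q)
  expect_equal(tab$compound[1], "SELF")
  expect_true(all(is.na(tab$tanimoto)))

  single <- rank_candidates(profiles["SELF"], q)
  expect_equal(nrow(single), 1)
})

test_that("a planted concordant compound tops the ranking consistently", {
  genes <- paste0("g", 1:150)
  q <- query_signature(genes[1:15], genes[131:150])
  hits <- 0
  n_sim <- 100
  for (i in seq_len(n_sim)) {
    profiles <- generate_ranked_profiles(genes, q, n_profiles = 21,
                                         planted_id = "HIT", signal = 3,
                                         seed = 300 + i)
    tab <- rank_candidates(profiles, q)
    hits <- hits + (tab$compound[1] == "HIT")
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("compounds without fingerprints get NA similarity, not errors", {
  genes <- paste0("g", 1:40)
  q <- query_signature(genes[1:5], genes[36:40])
  profiles <- generate_ranked_profiles(genes, q, 3, seed = 5)
  fps <- generate_fingerprints(2, n_bits = 64, seed = 6)
  fps[[1]]$id <- names(profiles)[1]
  fps[[2]]$id <- "QUERY"
  tab <- rank_candidates(profiles, q, fingerprints = fps,
                         query_fp = "QUERY")
  expect_equal(sum(is.na(tab$tanimoto)), 2)
  expect_equal(sum(!is.na(tab$tanimoto)), 1)
})
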