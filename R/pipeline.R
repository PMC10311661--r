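#' Default discovery-pipeline configuration
#'
#' Returns the full default configuration of [run_discovery()] as a nested
#' list; every parameter a user can set in the YAML config appears here
#' explicitly (no hidden defaults). The demo scale is small enough to run
#' the whole chain in well under five minutes on one CPU.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out = "mitoscreen-run",
    stages = list(simulate = TRUE, connect = TRUE, kinome = TRUE,
                  amses = TRUE, slscreen = TRUE, synergy = TRUE),
    cohort = list(n_patients = 150L, n_genes = 400L,
                  n_signature_genes = 40L, anchor_gene = "GSG2",
                  factor_loading = 1, tumor_shift = 1, hazard_beta = 0.5,
                  sl_partner_gene = "BG001", sl_interaction_beta = 0.9,
                  censor_rate = 0.2, noise_sd = 0.5),
    connect = list(n_profiles = 21L, planted_id = "CPD-PLANTED",
                   signal = 3, n_query_up = 25L, n_query_down = 25L,
                   weight_exponent = 1),
    fingerprints = list(n_bits = 512L, family_overlap = 0.8,
                        n_families = 3L, bit_density = 0.1),
    kinome = list(n_kinases = 403L, n_mutant = 0L, n_hits = 17L,
                  threshold = 10),
    amses = list(tau = 0.25, fdr_cut = 0.05, elevation_fdr = 0.05,
                 n_decoy_candidates = 60L, corr_method = "spearman"),
    slscreen = list(n_decoys = 30L, split = "median",
                    candidate_covariate = "low-indicator"),
    synergy = list(drug1 = list(m = 1.2, Dm = 300),
                   drug2 = list(m = 1.5, Dm = 3),
                   combo_alpha = 0.5, ratio = c(100, 1),
                   single_doses1 = c(50, 100, 200, 400, 800, 1600),
                   single_doses2 = c(0.5, 1, 2, 4, 8, 16),
                   combo_doses = c(100, 200, 400, 600, 800, 1200),
                   noise_sd = 0.05, fa_window = c(0.01, 0.99))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the in-silico discovery chain end to end
#'
#' Executes, as toggled in the config: synthetic-data simulation,
#' connectivity + Tanimoto candidate ranking, kinome selectivity scoring,
#' signature derivation + per-sample AMSES, the anchor-stratified
#' synthetic-lethal survival screen, and Fa-CI synergy analysis. Every
#' stage writes plain-text outputs under `out/` and the run ends with a
#' `manifest.json` recording the configuration, seed, package version,
#' per-file MD5 hashes and per-stage summaries, so identical config + seed
#' reproduce identical hashes. A stage failure halts the run with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config Path to a YAML config file, or a nested list; merged over
#'   [default_config()].
#' @param out Optional output directory (overrides the config).
#' @param seed Optional integer seed (overrides the config).
#' @return Invisibly, the manifest list.
#' @export
run_discovery <- function(config = list(), out = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "mitoscreen",
                   version = as.character(utils::packageVersion("mitoscreen")),
                   seed = cfg$seed, config = cfg, stages = list(),
                   outputs = list())
  log_stage <- function(stage, msg) {
    message(sprintf("[mitoscreen:%s] %s", stage, msg))
  }
  run_stage <- function(stage, fun) {
    if (!isTRUE(cfg$stages[[stage]])) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- res
  }
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    cc <- cfg$cohort
    state$cohort <- generate_cohort(cohort_params(
      n_patients = cc$n_patients, n_genes = cc$n_genes,
      n_signature_genes = cc$n_signature_genes,
      anchor_gene = cc$anchor_gene, factor_loading = cc$factor_loading,
      tumor_shift = cc$tumor_shift, hazard_beta = cc$hazard_beta,
      sl_partner_gene = cc$sl_partner_gene,
      sl_interaction_beta = cc$sl_interaction_beta,
      censor_rate = cc$censor_rate, noise_sd = cc$noise_sd,
      seed = child_seed(cfg$seed, 101L)))
    write_cohort(state$cohort, file.path(cfg$out, "cohort"))
    state$kinome <- generate_kinome_profile(
      cfg$kinome$n_kinases, cfg$kinome$n_mutant, cfg$kinome$n_hits,
      cfg$kinome$threshold, seed = child_seed(cfg$seed, 102L))
    write_kinome_csv(state$kinome, file.path(cfg$out, "kinome.csv"))
    log_stage("simulate", sprintf("cohort %d patients, %d genes; kinome %d",
                                  cc$n_patients, cc$n_genes,
                                  cfg$kinome$n_kinases))
    list(n_patients = cc$n_patients, n_genes = cc$n_genes,
         n_kinases = cfg$kinome$n_kinases)
  })

  run_stage("connect", function() {
    if (is.null(state$cohort)) stop("connect requires the simulate stage")
    cn <- cfg$connect
    truth_sig <- state$cohort$truth$signature_genes
    up <- utils::head(truth_sig, cn$n_query_up)
    down <- utils::head(grep("^BG", state$cohort$genes, value = TRUE),
                        cn$n_query_down)
    query <- query_signature(up, down)
    profiles <- generate_ranked_profiles(
      state$cohort$genes, query, cn$n_profiles,
      planted_id = cn$planted_id, signal = cn$signal,
      seed = child_seed(cfg$seed, 103L))
    fps <- generate_fingerprints(
      cn$n_profiles + 1L, n_bits = cfg$fingerprints$n_bits,
      family_overlap = cfg$fingerprints$family_overlap,
      n_families = cfg$fingerprints$n_families,
      bit_density = cfg$fingerprints$bit_density,
      seed = child_seed(cfg$seed, 104L))
    # family 1 holds the query compound and the planted hit; the rest
    # are decoys in the remaining families
    ids <- c("QUERY", cn$planted_id,
             setdiff(names(profiles), cn$planted_id))
    for (i in seq_along(fps)) fps[[i]]$id <- ids[i]
    write_fingerprints(fps, file.path(cfg$out, "fingerprints.txt"))
    ranking <- rank_candidates(profiles, query, fingerprints = fps,
                               query_fp = "QUERY",
                               weight_exponent = cn$weight_exponent)
    utils::write.table(ranking, file.path(cfg$out, "connectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    planted_rank <- match(cn$planted_id, ranking$compound)
    log_stage("connect", sprintf("planted compound ranked %d of %d",
                                 planted_rank, nrow(ranking)))
    list(top_compound = ranking$compound[1], top_wtcs = ranking$wtcs[1],
         planted_id = cn$planted_id, planted_rank = planted_rank)
  })

  run_stage("kinome", function() {
    if (is.null(state$kinome)) stop("kinome requires the simulate stage")
    s <- s_score(state$kinome, cfg$kinome$threshold)
    hits <- call_hits(state$kinome, cfg$kinome$threshold)
    curve <- selectivity_curve(state$kinome, c(1, 10, 35))
    utils::write.table(hits, file.path(cfg$out, "kinome-hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(curve, file.path(cfg$out, "selectivity-curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("kinome", sprintf("S(%g) = %.3f (%d hits)", s$threshold,
                                s$score_3dp, s$n_hits))
    list(s_score = s$score, s_score_3dp = s$score_3dp, n_hits = s$n_hits,
         n_nonmutant = s$n_nonmutant)
  })

  run_stage("amses", function() {
    if (is.null(state$cohort)) stop("amses requires the simulate stage")
    am <- cfg$amses
    truth_sig <- state$cohort$truth$signature_genes
    decoys <- utils::head(grep("^BG", state$cohort$genes, value = TRUE),
                          am$n_decoy_candidates)
    candidates <- c(truth_sig, decoys)
    sig <- derive_signature(state$cohort, cfg$cohort$anchor_gene,
                            candidates, corr_method = am$corr_method,
                            fdr_cut = am$fdr_cut,
                            elevation_fdr = am$elevation_fdr)
    write_gmt(sig, file.path(cfg$out, "signature.gmt"))
    scores <- amses(state$cohort, sig, tau = am$tau)
    utils::write.table(as.data.frame(scores),
                       file.path(cfg$out, "amses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$signature <- sig
    recall <- mean(truth_sig %in% sig$genes)
    log_stage("amses", sprintf(
      "signature %d genes (recall of planted %.2f), truth cor %.2f",
      length(sig$genes), recall,
      attr(scores, "truth_correlation") %||% NA_real_))
    list(n_signature_genes = length(sig$genes), planted_recall = recall,
         truth_correlation = attr(scores, "truth_correlation"))
  })

  run_stage("slscreen", function() {
    if (is.null(state$cohort)) stop("slscreen requires the simulate stage")
    partner <- cfg$cohort$sl_partner_gene
    decoys <- setdiff(grep("^BG", state$cohort$genes, value = TRUE),
                      partner)
    candidates <- c(partner, utils::head(decoys, cfg$slscreen$n_decoys))
    screen <- stratified_sl_screen(
      state$cohort, cfg$cohort$anchor_gene, candidates,
      candidate_covariate = cfg$slscreen$candidate_covariate,
      split = cfg$slscreen$split)
    utils::write.table(as.data.frame(screen),
                       file.path(cfg$out, "sl-screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    planted_class <- screen$classification[screen$gene == partner]
    if (length(planted_class) == 0) planted_class <- NA_character_
    log_stage("slscreen", sprintf("planted partner %s classified %s",
                                  partner, planted_class))
    list(planted_partner = partner,
         planted_classification = planted_class,
         n_sl_calls = sum(screen$classification == "SL-partner"))
  })

  run_stage("synergy", function() {
    sy <- cfg$synergy
    p1 <- dose_response_params(sy$drug1$m, sy$drug1$Dm,
                               doses = sy$single_doses1,
                               noise_sd = sy$noise_sd,
                               seed = child_seed(cfg$seed, 105L))
    p2 <- dose_response_params(sy$drug2$m, sy$drug2$Dm,
                               doses = sy$single_doses2,
                               noise_sd = sy$noise_sd,
                               seed = child_seed(cfg$seed, 106L))
    s1 <- generate_dose_response(p1, drug = "drug1")
    s2 <- generate_dose_response(p2, drug = "drug2")
    combo <- generate_combination(p1, p2, combo_alpha = sy$combo_alpha,
                                  ratio = sy$ratio, doses = sy$combo_doses,
                                  noise_sd = sy$noise_sd,
                                  seed = child_seed(cfg$seed, 107L))
    write_dose_response_csv(s1, file.path(cfg$out, "dose-drug1.csv"))
    write_dose_response_csv(s2, file.path(cfg$out, "dose-drug2.csv"))
    write_dose_response_csv(combo, file.path(cfg$out, "dose-combo.csv"))
    tab <- fa_ci_table(s1, s2, combo, fa_window = sy$fa_window)
    utils::write.table(as.data.frame(tab),
                       file.path(cfg$out, "fa-ci-table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mean_ci <- mean(tab$ci, na.rm = TRUE)
    log_stage("synergy", sprintf("mean CI %.3f over %d points", mean_ci,
                                 sum(!is.na(tab$ci))))
    list(mean_ci = mean_ci, all_ci_below_1 = all(tab$ci < 1, na.rm = TRUE),
         planted_combo_alpha = sy$combo_alpha, n_rows = nrow(tab))
  })

  files <- sort(list.files(cfg$out, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  manifest$outputs <- as.list(stats::setNames(
    unname(hashes), sub(paste0("^", cfg$out, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}
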