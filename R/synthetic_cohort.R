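#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for a synthetic antenatal cohort with the
#' joint structure the analysis pipeline assumes: diploid beta-defensin copy
#' numbers on 1..8 with mode 4; per-channel PRT ratios proportional to copy
#' number with multiplicative noise; a log-linear HBD2 model positively
#' coupled to copy number and negatively to gestational age; a log-linear
#' bactericidal-activity model driven by HBD2 with a small direct
#' copy-number effect; left-censoring of the raw ELISA reading at the LOD;
#' and delivery outcomes and treatment/exclusion flags drawn at the
#' configured rates.
#'
#' The HBD2 model is
#' `log(hbd2_norm) = hbd2_mu0 + beta_cn*(cn - 4) + beta_ga*(ga - ga_ref)/7 + N(0, sigma_hbd2^2)`
#' (gestational age in days, so `beta_ga` acts per week), and the kill model
#' is
#' `log(kill_per_protein) = kill_alpha + gamma_hbd2*log(hbd2_norm) + delta_cn*(cn - 4) + N(0, sigma_kill^2)`.
#' The default coefficients were calibrated once, by simulation, so that the
#' full pipeline recovers Spearman correlations near `rho_targets` and a
#' sub-LOD fraction near `target_censor_fraction`.
#'
#' @param n_subjects Cohort size.
#' @param cn_support Integer copy-number values the generator draws from.
#' @param cn_probs Probability of each value in `cn_support` (mode at 4).
#' @param typing_failure_rate Fraction of subjects whose PRT channels are
#'   degraded so that genotyping fails (fewer than two usable assays).
#' @param channels Data frame of PRT channels (`assay`, `dye`): two dyes
#'   each for the PRT107A and HSPD21 assays plus a single-channel third
#'   assay.
#' @param ratio_slope,ratio_intercept Linear map from copy number to the
#'   expected peak-area ratio.
#' @param ratio_cv Per-channel multiplicative coefficient of variation of
#'   the ratio.
#' @param panel_cn Known copy numbers of the simulated reference panel.
#' @param ga_range_days Gestational age at sampling, drawn uniformly on this
#'   range (days).
#' @param ga_ref_days Centering constant of the HBD2 model (days).
#' @param hbd2_mu0,beta_cn,beta_ga,sigma_hbd2 HBD2 model coefficients
#'   (natural-log scale; `hbd2_norm` in pg per ug total protein).
#' @param kill_alpha,gamma_hbd2,delta_cn,sigma_kill Kill model coefficients
#'   (natural-log scale; `kill_per_protein` in %kill per ug).
#' @param protein_meanlog,protein_sdlog Log-normal total-protein
#'   concentration (ug/ml).
#' @param lod_pg_ml ELISA lower limit of detection; raw readings below it
#'   are emitted as the undetectable token.
#' @param cfu_control_cfu_ml Nominal surviving count in the buffer control.
#' @param cfu_rep_cv Replicate-level CV of the triplicate cfu readings.
#' @param preterm_prob Preterm-delivery probability among continuing
#'   pregnancies.
#' @param miscarriage_prob,termination_prob Per-subject probabilities of
#'   those outcomes.
#' @param cerclage_prob,post_progesterone_prob,pre_progesterone_prob Rates
#'   of the treatment/exclusion flags.
#' @param rho_targets Named vector of the Spearman correlations the defaults
#'   are calibrated toward (`cn_hbd2`, `ga_hbd2`, `hbd2_kill`, `cn_kill`).
#' @param target_censor_fraction Intended sub-LOD fraction of ELISA readings.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 203L,
                          cn_support = 1:8,
                          cn_probs = c(0.02, 0.08, 0.22, 0.33, 0.20, 0.10,
                                       0.04, 0.01),
                          typing_failure_rate = 0.044,
                          channels = data.frame(
                            assay = c("PRT107A", "PRT107A", "HSPD21",
                                      "HSPD21", "PRT3"),
                            dye = c("FAM", "HEX", "FAM", "HEX", "NED"),
                            stringsAsFactors = FALSE),
                          ratio_slope = 0.5,
                          ratio_intercept = 0,
                          ratio_cv = 0.05,
                          panel_cn = 2:7,
                          ga_range_days = c(61L, 192L),
                          ga_ref_days = 107,
                          hbd2_mu0 = 0.40,
                          beta_cn = 0.27,
                          beta_ga = -0.081,
                          sigma_hbd2 = 1.55,
                          kill_alpha = -3.07,
                          gamma_hbd2 = 0.285,
                          delta_cn = 0.05,
                          sigma_kill = 0.62,
                          protein_meanlog = log(100),
                          protein_sdlog = 0.5,
                          lod_pg_ml = 16,
                          cfu_control_cfu_ml = 1e5,
                          cfu_rep_cv = 0.02,
                          preterm_prob = 14 / 167,
                          miscarriage_prob = 1 / 203,
                          termination_prob = 1 / 203,
                          cerclage_prob = 20 / 203,
                          post_progesterone_prob = 2 / 203,
                          pre_progesterone_prob = 6 / 209,
                          rho_targets = c(cn_hbd2 = 0.21, ga_hbd2 = -0.25,
                                          hbd2_kill = 0.49, cn_kill = 0.17),
                          target_censor_fraction = 25 / 203) {
  stopifnot(length(cn_probs) == length(cn_support),
            abs(sum(cn_probs) - 1) < 1e-8,
            all(cn_probs >= 0),
            sigma_hbd2 > 0, sigma_kill > 0, ratio_cv >= 0,
            typing_failure_rate >= 0, typing_failure_rate <= 1)
  rates <- c(preterm_prob, miscarriage_prob, termination_prob, cerclage_prob,
             post_progesterone_prob, pre_progesterone_prob)
  stopifnot(all(rates >= 0 & rates <= 1))
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

# Fixed component ids for the decoupled random substreams: changing the
# parameters of one component never perturbs another component's draws
# under the same master seed.
.cohort_streams <- c(cn = 1L, ga = 2L, protein = 3L, hbd2 = 4L, kill = 5L,
                     panel = 6L, ratios = 7L, areas = 8L, typing = 9L,
                     outcome = 10L, flags = 11L, cfu = 12L)

#' Simulate a synthetic cohort
#'
#' Draws per-subject ground truth (copy number, gestational age, latent
#' HBD2 and kill activity) and emits the four pipeline input tables: a PRT
#' peak-area table, a reference-panel table, an assay table (with the `"ND"`
#' token for raw ELISA readings below the LOD), and a metadata table with
#' outcomes and exclusion flags. Each random component draws from its own
#' seed-derived substream, so regenerating with the same seed is
#' reproducible bit for bit, and changing one component's rate leaves the
#' other components' draws unchanged.
#'
#' Typing failures are induced by zeroing the peak areas of all but one
#' assay for the affected subjects, which leaves them below the two-assay
#' minimum of the caller. Censoring is applied by the pipeline, not here:
#' the generator emits raw values, some of which fall below the LOD.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A list of class `synthetic_cohort`: `truth`, `peaks`, `panel`,
#'   `assays`, `metadata` data frames plus the `config` and `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  stream <- function(name) set.seed(sub_seed(seed, .cohort_streams[[name]]))

  stream("cn")
  cn <- sample(config$cn_support, n, replace = TRUE, prob = config$cn_probs)

  stream("ga")
  ga <- sample(seq(config$ga_range_days[1L], config$ga_range_days[2L]),
               n, replace = TRUE)

  stream("protein")
  protein <- stats::rlnorm(n, config$protein_meanlog, config$protein_sdlog)

  stream("hbd2")
  log_hbd2 <- config$hbd2_mu0 + config$beta_cn * (cn - 4) +
    config$beta_ga * (ga - config$ga_ref_days) / 7 +
    stats::rnorm(n, 0, config$sigma_hbd2)
  hbd2_norm <- exp(log_hbd2)              # pg per ug total protein
  hbd2_raw <- hbd2_norm * protein         # pg/ml, pre-censoring

  stream("kill")
  log_kill <- config$kill_alpha + config$gamma_hbd2 * log_hbd2 +
    config$delta_cn * (cn - 4) + stats::rnorm(n, 0, config$sigma_kill)
  kill_norm <- exp(log_kill)              # %kill per ug total protein
  pct_kill <- pmin(kill_norm * protein, 99.9)

  # reference panel: one measurement per channel and known copy number
  stream("panel")
  nchan <- nrow(config$channels)
  panel_rows <- expand.grid(known_cn = config$panel_cn,
                            chan = seq_len(nchan))
  panel_ratio <- (config$ratio_slope * panel_rows$known_cn) *
    (1 + stats::rnorm(nrow(panel_rows), 0, config$ratio_cv)) +
    config$ratio_intercept
  panel_ref_area <- stats::runif(nrow(panel_rows), 8000, 12000)
  panel <- data.frame(
    sample_id = sprintf("REF%02d", match(panel_rows$known_cn, config$panel_cn)),
    assay = config$channels$assay[panel_rows$chan],
    dye = config$channels$dye[panel_rows$chan],
    test_area = panel_ratio * panel_ref_area,
    reference_area = panel_ref_area,
    known_cn = panel_rows$known_cn,
    stringsAsFactors = FALSE)

  # cohort PRT ratios, channel by channel in fixed order
  stream("ratios")
  ratio <- matrix(NA_real_, n, nchan)
  for (j in seq_len(nchan)) {
    ratio[, j] <- (config$ratio_slope * cn) *
      (1 + stats::rnorm(n, 0, config$ratio_cv)) + config$ratio_intercept
  }
  stream("areas")
  ref_area <- matrix(stats::runif(n * nchan, 8000, 12000), n, nchan)

  stream("typing")
  failed <- stats::runif(n) < config$typing_failure_rate
  # degrade all channels except the last assay's for failed subjects
  last_assay <- config$channels$assay[nchan]
  degrade <- which(config$channels$assay != last_assay)

  peaks <- data.frame(
    sample_id = rep(ids, each = nchan),
    assay = rep(config$channels$assay, times = n),
    dye = rep(config$channels$dye, times = n),
    test_area = as.vector(t(ratio * ref_area)),
    reference_area = as.vector(t(ref_area)),
    stringsAsFactors = FALSE)
  if (any(failed)) {
    kill_rows <- as.vector(outer(degrade, (which(failed) - 1L) * nchan, `+`))
    peaks$test_area[kill_rows] <- 0
  }

  stream("outcome")
  u <- stats::runif(n)
  p1 <- config$miscarriage_prob
  p2 <- p1 + config$termination_prob
  p3 <- p2 + config$preterm_prob
  outcome <- ifelse(u < p1, "miscarriage",
                    ifelse(u < p2, "termination",
                           ifelse(u < p3, "preterm", "term")))

  stream("flags")
  cerclage <- stats::runif(n) < config$cerclage_prob
  post_prog <- stats::runif(n) < config$post_progesterone_prob
  pre_prog <- stats::runif(n) < config$pre_progesterone_prob

  stream("cfu")
  ctrl_reps <- matrix(config$cfu_control_cfu_ml *
                        (1 + stats::rnorm(3L * n, 0, config$cfu_rep_cv)),
                      n, 3L)
  test_true <- config$cfu_control_cfu_ml * (1 - pct_kill / 100)
  test_reps <- matrix(pmax(test_true *
                             (1 + stats::rnorm(3L * n, 0, config$cfu_rep_cv)),
                           0), n, 3L)

  assays <- data.frame(
    sample_id = ids,
    hbd2_pg_ml = ifelse(hbd2_raw < config$lod_pg_ml, "ND",
                        format(hbd2_raw, digits = 15, trim = TRUE,
                               scientific = FALSE)),
    total_protein_ug_ml = protein,
    cfu_test_1 = test_reps[, 1L], cfu_test_2 = test_reps[, 2L],
    cfu_test_3 = test_reps[, 3L],
    cfu_control_1 = ctrl_reps[, 1L], cfu_control_2 = ctrl_reps[, 2L],
    cfu_control_3 = ctrl_reps[, 3L],
    stringsAsFactors = FALSE)

  metadata <- data.frame(
    sample_id = ids,
    gestational_age_days = ga,
    outcome = outcome,
    pre_sampling_progesterone = pre_prog,
    post_sampling_cerclage = cerclage,
    post_sampling_progesterone = post_prog,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = ids,
    true_cn = cn,
    gestational_age_days = ga,
    hbd2_norm_true = hbd2_norm,
    hbd2_raw_pg_ml = hbd2_raw,
    kill_per_protein_true = kill_norm,
    percent_kill_true = pct_kill,
    total_protein_ug_ml = protein,
    typing_failed = failed,
    stringsAsFactors = FALSE)

  structure(list(truth = truth, peaks = peaks, panel = panel,
                 assays = assays, metadata = metadata,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort's input files to a directory
#'
#' Writes `peaks.csv`, `panel.csv`, `assays.csv`, `metadata.csv`, the
#' ground-truth table `truth.csv`, and the resolved configuration as
#' `config.json`. Output is deterministic: the same cohort object always
#' produces byte-identical files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             panel = file.path(dir, "panel.csv"),
             assays = file.path(dir, "assays.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(cohort$peaks, paths["peaks"], row.names = FALSE)
  utils::write.csv(cohort$panel, paths["panel"], row.names = FALSE)
  utils::write.csv(cohort$assays, paths["assays"], row.names = FALSE)
  utils::write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- cfg[setdiff(names(cfg), "channels")]
  cfg_list$channels <- cfg$channels
  cfg_list$seed <- cohort$seed
  writeLines(jsonlite::toJSON(cfg_list, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             paths["config"])
  invisible(paths)
}

#' Replicate-level calibration report for the generator
#'
#' Simulates `n_replicates` cohorts under `config`, runs the full analysis
#' pipeline on each (genotyping, assay processing, exclusions, pairwise
#' correlations), and summarises the emergent statistics: the mean and
#' spread of each target Spearman correlation, the sign pattern, the median
#' normalized HBD2 and kill activity, the censored fraction, and the typing
#' success rate. This is how the defaults are verified to land near their
#' calibration anchors.
#'
#' @param config A [cohort_config()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed; replicate `r` uses substream `seed, 1000 + r`.
#' @return List of class `cohort_calibration_report` with `replicates` (one
#'   row per cohort) and `summary`.
#' @export
calibration_report <- function(config = cohort_config(), n_replicates = 20L,
                               seed = 1L) {
  stopifnot(n_replicates >= 1L)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(config, seed = sub_seed(seed, 1000L + r))
    an <- analyse_cohort(sim)
    cors <- an$correlations
    grab <- function(vx, vy) {
      hit <- (cors$var_x == vx & cors$var_y == vy) |
        (cors$var_x == vy & cors$var_y == vx)
      if (any(hit)) cors$rho[hit][1L] else NA_real_
    }
    rows[[r]] <- data.frame(
      replicate = r,
      rho_cn_hbd2 = grab("weighted_mean_cn", "hbd2_norm_pg_per_ug"),
      rho_ga_hbd2 = grab("gestational_age_days", "hbd2_norm_pg_per_ug"),
      rho_hbd2_kill = grab("hbd2_norm_pg_per_ug", "kill_per_protein"),
      rho_cn_kill = grab("weighted_mean_cn", "kill_per_protein"),
      median_hbd2 = stats::median(an$cohort$hbd2_norm_pg_per_ug, na.rm = TRUE),
      median_kill = stats::median(an$cohort$kill_per_protein, na.rm = TRUE),
      censor_fraction = mean(an$cohort$hbd2_censored, na.rm = TRUE),
      typing_success = mean(!is.na(an$calls$ml_integer_cn)),
      n_analysed = nrow(an$cohort))
  }
  reps <- do.call(rbind, rows)
  targets <- config$rho_targets
  sign_ok <- sign(reps$rho_cn_hbd2) == sign(targets[["cn_hbd2"]]) &
    sign(reps$rho_ga_hbd2) == sign(targets[["ga_hbd2"]]) &
    sign(reps$rho_hbd2_kill) == sign(targets[["hbd2_kill"]]) &
    sign(reps$rho_cn_kill) == sign(targets[["cn_kill"]])
  summary <- list(
    mean_rho = c(cn_hbd2 = mean(reps$rho_cn_hbd2),
                 ga_hbd2 = mean(reps$rho_ga_hbd2),
                 hbd2_kill = mean(reps$rho_hbd2_kill),
                 cn_kill = mean(reps$rho_cn_kill)),
    rho_targets = targets,
    sign_pattern_fraction = mean(sign_ok),
    mean_censor_fraction = mean(reps$censor_fraction),
    target_censor_fraction = config$target_censor_fraction,
    mean_typing_success = mean(reps$typing_success),
    median_hbd2 = stats::median(reps$median_hbd2),
    median_kill = stats::median(reps$median_kill),
    n_replicates = n_replicates)
  structure(list(replicates = reps, summary = summary),
            class = "cohort_calibration_report")
}

#' @export
print.cohort_calibration_report <- function(x, ...) {
  s <- x$summary
  cat("Synthetic-cohort calibration report (", s$n_replicates,
      " replicates)\n", sep = "")
  tab <- rbind(mean = s$mean_rho, target = s$rho_targets)
  print(round(tab, 3))
  cat(sprintf("sign pattern (+,-,+,+) fraction: %.2f\n",
              s$sign_pattern_fraction))
  cat(sprintf("censored fraction: %.3f (target %.3f)\n",
              s$mean_censor_fraction, s$target_censor_fraction))
  cat(sprintf("typing success: %.3f; median HBD2 %.2f pg/ug; median kill %.3f %%kill/ug\n",
              s$mean_typing_success, s$median_hbd2, s$median_kill))
  invisible(x)
}

# In-memory end-to-end analysis of a simulated cohort: genotype, process
# assays, merge, exclude, correlate. Shared by calibration_report() and the
# pipeline stages.
analyse_cohort <- function(sim,
                           variables = c("weighted_mean_cn",
                                         "hbd2_norm_pg_per_ug",
                                         "kill_per_protein",
                                         "gestational_age_days"),
                           assay_cfg = assay_config(
                             lod_pg_ml = sim$config$lod_pg_ml),
                           support = 1:12) {
  peaks <- validate_peak_table(sim$peaks, quiet = TRUE)
  panel <- validate_peak_table(sim$panel, source = "panel", quiet = TRUE)
  calls <- genotype_samples(peaks, panel, support = support)
  assays <- sim$assays
  hb <- assays$hbd2_pg_ml
  if (is.character(hb)) {
    hb[toupper(trimws(hb)) == "ND"] <- NA
    assays$hbd2_pg_ml <- as.numeric(hb)
  }
  processed <- process_assays(assays, config = assay_cfg)
  cohort <- merge(merge(sim$metadata, calls, by = "sample_id"),
                  processed, by = "sample_id")
  sets <- apply_exclusions(cohort)
  correlations <- pairwise_matrix(sets$all_comers, variables)
  list(calls = calls, processed = processed, cohort = sets$all_comers,
       sets = sets, correlations = correlations)
}
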