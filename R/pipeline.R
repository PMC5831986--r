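#' Run the full analysis pipeline
#'
#' Orchestrates the four stages as one reproducible run: (1) obtain inputs,
#' either by simulating a synthetic cohort or from user-supplied files;
#' (2) PRT genotyping (calibration + integer calls); (3) assay processing
#' (censoring, normalization, percent kill); (4) association analysis
#' (exclusions, pairwise correlations overall and within term/preterm
#' strata, Mann-Whitney group comparisons). All stage outputs, a resolved
#' configuration, and a manifest with file checksums and per-stage row
#' counts are written under `out_dir`. A stage failure aborts with an error
#' after writing a manifest that records the stages completed so far.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (used only when simulating).
#' @param sim_config [cohort_config()] for the simulation stage.
#' @param assay_cfg [assay_config()] for the assay stage.
#' @param inputs Optional named list/vector of existing input files
#'   (`peaks`, `panel`, `assays`, `metadata`); when given, no simulation is
#'   performed.
#' @param variables Variables for the correlation layer.
#' @param support Integer copy-number support for calling.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly, as a list; all outputs are on disk.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         sim_config = cohort_config(),
                         assay_cfg = assay_config(
                           lod_pg_ml = sim_config$lod_pg_ml),
                         inputs = NULL,
                         variables = c("weighted_mean_cn",
                                       "hbd2_norm_pg_per_ug",
                                       "kill_per_protein",
                                       "gestational_age_days"),
                         support = 1:12,
                         quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(package_version = as.character(utils::packageVersion("defensinCNV")),
                   seed = as.integer(seed),
                   stages = list(), outputs = character(0))
  finish <- function() {
    files <- manifest$outputs
    manifest$checksums <- as.list(tools::md5sum(files))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    manifest
  }
  fail <- function(stage, msg) {
    manifest$stages[[stage]] <<- list(status = "failed", error = msg)
    finish()
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }

  # stage 1: inputs ----------------------------------------------------
  stage <- "inputs"
  if (is.null(inputs)) {
    sim <- simulate_cohort(sim_config, seed = seed)
    paths <- write_cohort(sim, out_dir)
    input_files <- paths[c("peaks", "panel", "assays", "metadata")]
    manifest$outputs <- c(manifest$outputs, unname(paths))
    manifest$stages[[stage]] <- list(status = "completed", mode = "simulated",
                                     n_subjects = nrow(sim$metadata))
    say("stage 1 (inputs): simulated cohort of ", nrow(sim$metadata),
        " subjects")
  } else {
    input_files <- unlist(inputs)
    needed <- c("peaks", "panel", "assays", "metadata")
    missing_keys <- setdiff(needed, names(input_files))
    if (length(missing_keys)) {
      fail(stage, paste("missing input file entries:",
                        paste(missing_keys, collapse = ", ")))
    }
    absent <- input_files[!file.exists(input_files)]
    if (length(absent)) {
      fail(stage, paste("input file(s) not found:",
                        paste(absent, collapse = ", ")))
    }
    manifest$stages[[stage]] <- list(status = "completed", mode = "provided")
    say("stage 1 (inputs): using provided files")
  }
  manifest$input_checksums <- as.list(tools::md5sum(unname(input_files)))

  # stage 2: genotyping -------------------------------------------------
  stage <- "genotyping"
  calls <- tryCatch({
    peaks <- read_peak_table(input_files[["peaks"]], quiet = quiet)
    panel <- read_reference_panel(input_files[["panel"]],
                                  support = support, quiet = quiet)
    genotype_samples(peaks, panel, support = support)
  }, error = function(e) fail(stage, conditionMessage(e)))
  calls_file <- file.path(out_dir, "calls.csv")
  utils::write.csv(calls, calls_file, row.names = FALSE)
  calib_file <- file.path(out_dir, "calibration.json")
  calibration_report_json(attr(calls, "calibration"), file = calib_file)
  n_called <- sum(!is.na(calls$ml_integer_cn))
  manifest$outputs <- c(manifest$outputs, calls_file, calib_file)
  manifest$stages[[stage]] <- list(status = "completed",
                                   samples_in = nrow(calls),
                                   samples_called = n_called,
                                   samples_failed = nrow(calls) - n_called)
  say("stage 2 (genotyping): ", n_called, "/", nrow(calls),
      " samples called")

  # stage 3: assay processing -------------------------------------------
  stage <- "assays"
  processed <- tryCatch({
    process_assays(read_assay_table(input_files[["assays"]]),
                   config = assay_cfg)
  }, error = function(e) fail(stage, conditionMessage(e)))
  processed_file <- file.path(out_dir, "assays_processed.csv")
  utils::write.csv(processed, processed_file, row.names = FALSE)
  manifest$outputs <- c(manifest$outputs, processed_file)
  manifest$stages[[stage]] <- list(
    status = "completed", samples = nrow(processed),
    censored = sum(processed$hbd2_censored, na.rm = TRUE),
    qc_flagged = sum(nzchar(processed$qc_flags)))
  say("stage 3 (assays): ", nrow(processed), " samples, ",
      sum(processed$hbd2_censored, na.rm = TRUE), " censored")

  # stage 4: association analysis ---------------------------------------
  stage <- "association"
  assoc <- tryCatch({
    metadata <- utils::read.csv(input_files[["metadata"]],
                                stringsAsFactors = FALSE)
    cohort <- merge(merge(metadata, calls, by = "sample_id"),
                    processed, by = "sample_id")
    sets <- apply_exclusions(cohort)
    overall <- pairwise_matrix(sets$all_comers, variables)
    strat <- stratified_correlations(sets$outcome_set, variables)
    groups <- do.call(rbind, Filter(Negate(is.null), lapply(
      c("weighted_mean_cn", "hbd2_norm_pg_per_ug", "kill_per_protein"),
      function(v) compare_groups(sets$outcome_set, v))))
    list(sets = sets, correlations = rbind(overall, strat), groups = groups,
         scatter = attr(overall, "scatter_data"))
  }, error = function(e) fail(stage, conditionMessage(e)))

  cor_file <- file.path(out_dir, "correlations.csv")
  utils::write.csv(assoc$correlations, cor_file, row.names = FALSE)
  audit_file <- file.path(out_dir, "exclusions_audit.csv")
  utils::write.csv(assoc$sets$audit, audit_file, row.names = FALSE)
  group_file <- file.path(out_dir, "group_comparison.csv")
  utils::write.csv(assoc$groups, group_file, row.names = FALSE)
  scatter_file <- file.path(out_dir, "scatter_matrix.json")
  writeLines(jsonlite::toJSON(assoc$scatter, auto_unbox = FALSE, digits = NA),
             scatter_file)
  manifest$outputs <- c(manifest$outputs, cor_file, audit_file, group_file,
                        scatter_file)
  manifest$stages[[stage]] <- list(
    status = "completed",
    cohort_in = nrow(assoc$sets$all_comers) + sum(
      assoc$sets$audit$set_removed_from == "all"),
    all_comers = nrow(assoc$sets$all_comers),
    outcome_set = nrow(assoc$sets$outcome_set),
    correlations = nrow(assoc$correlations))
  say("stage 4 (association): ", nrow(assoc$correlations),
      " correlation rows; all-comers n=", nrow(assoc$sets$all_comers),
      ", outcome set n=", nrow(assoc$sets$outcome_set))

  invisible(finish())
}
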