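#' Assay-processing configuration
#'
#' Bundles the constants of the biomarker and kill-assay computations: the
#' ELISA lower limit of detection, the censoring substitution divisor
#' (sub-LOD readings are replaced by `lod_pg_ml / substitution_divisor`),
#' the nominal bacterial inoculum, the policy for negative percent-kill
#' values (bacterial growth over the buffer control), and the triplicate
#' coefficient-of-variation threshold above which a QC flag is raised.
#'
#' @param lod_pg_ml ELISA lower limit of detection, pg/ml.
#' @param substitution_divisor Divisor for the sub-LOD substitution value
#'   (default `sqrt(2)`).
#' @param inoculum_cfu_ml Nominal bacterial input, cfu/ml.
#' @param kill_floor_policy `"allow_negative"` keeps negative percent-kill
#'   values (preserves rank order); `"clip_to_zero"` clips them to 0 and
#'   flags `GROWTH_OBSERVED`.
#' @param cv_threshold Triplicate CV above which `HIGH_CV` is flagged.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(lod_pg_ml = 16,
                         substitution_divisor = sqrt(2),
                         inoculum_cfu_ml = 1e5,
                         kill_floor_policy = c("allow_negative", "clip_to_zero"),
                         cv_threshold = 0.30) {
  stopifnot(lod_pg_ml > 0, substitution_divisor > 0, cv_threshold >= 0)
  structure(list(lod_pg_ml = lod_pg_ml,
                 substitution_divisor = substitution_divisor,
                 substitution_value = lod_pg_ml / substitution_divisor,
                 inoculum_cfu_ml = inoculum_cfu_ml,
                 kill_floor_policy = match.arg(kill_floor_policy),
                 cv_threshold = cv_threshold),
            class = "assay_config")
}

#' Substitute readings below the limit of detection
#'
#' Undetectable readings (`NA`) and numeric readings below the LOD are
#' replaced by `lod / divisor` (default `16 / sqrt(2)` = 11.3137 pg/ml) and
#' flagged censored; readings at or above the LOD pass through unchanged.
#' The operation is idempotent: the substitution value itself is below the
#' LOD but already equals the substituted value.
#'
#' @param readings Numeric vector; `NA` marks an undetectable reading.
#' @param lod Lower limit of detection (same units as `readings`).
#' @param divisor Substitution divisor, default `sqrt(2)`.
#' @return Data frame with columns `value` and `censored`.
#' @export
substitute_below_lod <- function(readings, lod = 16, divisor = sqrt(2)) {
  stopifnot(lod > 0, divisor > 0)
  if (any(readings < 0, na.rm = TRUE)) {
    stop("negative assay reading(s): concentrations must be non-negative")
  }
  censored <- is.na(readings) | readings < lod
  value <- ifelse(censored, lod / divisor, readings)
  data.frame(value = value, censored = censored)
}

#' Normalize a quantity to total protein
#'
#' Divides a per-ml quantity by the total-protein concentration of the same
#' sample, e.g. HBD2 pg/ml divided by protein ug/ml gives pg per ug total
#' protein; percent kill divided by protein gives %kill per ug. Samples with
#' non-positive protein get `NA` (the value is withheld, not guessed).
#'
#' @param value Numeric vector to normalize.
#' @param total_protein Total-protein concentration, ug/ml, must be > 0.
#' @return Numeric vector `value / total_protein`, `NA` where protein <= 0.
#' @export
normalize_to_protein <- function(value, total_protein) {
  ok <- is.finite(total_protein) & total_protein > 0
  out <- rep(NA_real_, length(value))
  out[ok] <- value[ok] / total_protein[ok]
  out
}

#' Aggregate replicate cfu quantifications
#'
#' Arithmetic mean and coefficient of variation over the usable (finite)
#' replicates. Fewer than two usable replicates yields no estimate and the
#' `REPLICATES_INSUFFICIENT` flag; a CV above the threshold yields `HIGH_CV`.
#'
#' @param replicates Numeric vector of replicate readings (cfu/ml).
#' @param cv_threshold CV above which the QC flag is raised.
#' @return List with `mean`, `cv`, `n`, and `flags` (character vector).
#' @export
aggregate_triplicates <- function(replicates, cv_threshold = 0.30) {
  reps <- replicates[is.finite(replicates)]
  if (length(reps) < 2L) {
    return(list(mean = NA_real_, cv = NA_real_, n = length(reps),
                flags = "REPLICATES_INSUFFICIENT"))
  }
  m <- mean(reps)
  cv <- if (m == 0) Inf else stats::sd(reps) / m
  flags <- if (is.finite(cv) && cv > cv_threshold) "HIGH_CV" else character(0)
  list(mean = m, cv = cv, n = length(reps), flags = flags)
}

#' Percent kill relative to the buffer control
#'
#' The bacterial count surviving in buffer defines 100% survival, so
#' `percent_kill = 100 * (1 - cfu_test / cfu_control)`. A test count equal
#' to the control gives 0% kill; zero surviving bacteria give 100%. Under
#' `clip_to_zero`, net growth over the control (negative kill) is clipped to
#' 0; the default keeps the negative value, which leaves rank-based
#' downstream statistics unaffected.
#'
#' @param cfu_test Surviving count in the test sample, cfu/ml.
#' @param cfu_control Surviving count in the buffer control, cfu/ml (> 0).
#' @param policy `"allow_negative"` or `"clip_to_zero"`.
#' @return List with `percent_kill` and `flags`.
#' @export
percent_kill <- function(cfu_test, cfu_control,
                         policy = c("allow_negative", "clip_to_zero")) {
  policy <- match.arg(policy)
  if (!is.finite(cfu_control) || cfu_control <= 0) {
    return(list(percent_kill = NA_real_, flags = "CONTROL_FAILURE"))
  }
  pk <- 100 * (1 - cfu_test / cfu_control)
  flags <- character(0)
  if (policy == "clip_to_zero" && is.finite(pk) && pk < 0) {
    pk <- 0
    flags <- "GROWTH_OBSERVED"
  }
  list(percent_kill = pk, flags = flags)
}

#' Read a per-sample assay table
#'
#' @param file CSV with columns `sample_id`, `hbd2_pg_ml` (numeric or the
#'   token `"ND"` for an undetectable reading), `total_protein_ug_ml`,
#'   `cfu_test_1..3`, `cfu_control_1..3`.
#' @return Data frame with `hbd2_pg_ml` parsed to numeric (`NA` for ND).
#' @export
read_assay_table <- function(file) {
  if (!file.exists(file)) stop("assay table file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("sample_id", "hbd2_pg_ml", "total_protein_ug_ml",
                paste0("cfu_test_", 1:3), paste0("cfu_control_", 1:3))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(file, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  hb <- df$hbd2_pg_ml
  if (is.character(hb)) {
    nd <- toupper(trimws(hb)) == "ND"
    hb[nd] <- NA
    df$hbd2_pg_ml <- as.numeric(hb)
  }
  df
}

#' Process raw assay readings into analysis variables
#'
#' The fixed processing order is: censor the HBD2 ELISA reading (sub-LOD
#' substitution), then normalize to total protein; aggregate the cfu
#' triplicates; compute percent kill against the buffer control; normalize
#' kill to total protein. Per-sample QC flags are collected in
#' `qc_flags` (semicolon-joined).
#'
#' @param assays Data frame from [read_assay_table()].
#' @param config An [assay_config()].
#' @return Data frame with, per sample: `hbd2_raw_pg_ml`, `hbd2_censored`,
#'   `hbd2_pg_ml` (post-substitution), `total_protein_ug_ml`,
#'   `hbd2_norm_pg_per_ug`, `cfu_test_mean`, `cfu_control_mean`,
#'   `percent_kill`, `kill_per_protein`, `qc_flags`.
#' @export
process_assays <- function(assays, config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  n <- nrow(assays)
  cens <- substitute_below_lod(assays$hbd2_pg_ml,
                               lod = config$lod_pg_ml,
                               divisor = config$substitution_divisor)
  protein <- as.numeric(assays$total_protein_ug_ml)
  hbd2_norm <- normalize_to_protein(cens$value, protein)

  out <- data.frame(sample_id = assays$sample_id,
                    hbd2_raw_pg_ml = assays$hbd2_pg_ml,
                    hbd2_censored = cens$censored,
                    hbd2_pg_ml = cens$value,
                    total_protein_ug_ml = protein,
                    hbd2_norm_pg_per_ug = hbd2_norm,
                    cfu_test_mean = NA_real_,
                    cfu_test_cv = NA_real_,
                    cfu_control_mean = NA_real_,
                    cfu_control_cv = NA_real_,
                    percent_kill = NA_real_,
                    kill_per_protein = NA_real_,
                    qc_flags = "",
                    stringsAsFactors = FALSE)

  test_cols <- paste0("cfu_test_", 1:3)
  ctrl_cols <- paste0("cfu_control_", 1:3)
  for (i in seq_len(n)) {
    flags <- character(0)
    if (!is.finite(protein[i]) || protein[i] <= 0) {
      flags <- c(flags, "PROTEIN_NONPOSITIVE")
    }
    tst <- aggregate_triplicates(as.numeric(assays[i, test_cols]),
                                 cv_threshold = config$cv_threshold)
    ctl <- aggregate_triplicates(as.numeric(assays[i, ctrl_cols]),
                                 cv_threshold = config$cv_threshold)
    out$cfu_test_mean[i] <- tst$mean
    out$cfu_test_cv[i] <- tst$cv
    out$cfu_control_mean[i] <- ctl$mean
    out$cfu_control_cv[i] <- ctl$cv
    flags <- c(flags,
               if (length(tst$flags)) paste0("TEST_", tst$flags),
               if (length(ctl$flags)) paste0("CONTROL_", ctl$flags))
    if (is.finite(tst$mean) && is.finite(ctl$mean)) {
      pk <- percent_kill(tst$mean, ctl$mean, policy = config$kill_floor_policy)
      out$percent_kill[i] <- pk$percent_kill
      flags <- c(flags, pk$flags)
      out$kill_per_protein[i] <- normalize_to_protein(pk$percent_kill,
                                                      protein[i])
    }
    out$qc_flags[i] <- join_flags(flags)
  }
  out
}
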