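#' @name prt_genotyping
#' @title PRT copy-number genotyping
#'
#' @description
#' The paralogue ratio test (PRT) co-amplifies a test locus inside a
#' copy-number-variable region and a reference locus outside it with shared
#' primers, so the ratio of the two capillary-electrophoresis peak areas is
#' proportional to diploid copy number. These functions convert peak-area
#' tables into calibrated integer copy-number calls: a linear regression of
#' reference-panel ratios on their known integer copy numbers calibrates each
#' assay/dye channel, calibrated per-channel estimates are averaged within
#' each PRT assay, and the assay estimates are pooled by a Gaussian
#' maximum-likelihood scan over the integer support.
NULL

prt_required_cols <- c("sample_id", "assay", "dye", "test_area", "reference_area")

#' Read and validate a PRT peak-area table
#'
#' @param file Path to a CSV file with header columns `sample_id`, `assay`,
#'   `dye`, `test_area`, `reference_area` (peak areas in arbitrary
#'   fluorescence units).
#' @param quiet Suppress the parse-report message.
#'
#' @details Rows with a missing or zero peak area are retained but flagged
#'   unusable (`usable = FALSE`); they are excluded from calibration and
#'   calling. The `ratio` column is always recomputed as
#'   `test_area / reference_area`. A parse report (rows read / usable /
#'   flagged) is attached as attribute `"parse_report"`.
#'
#' @return A data frame of PRT measurements with added `usable` and `ratio`
#'   columns.
#' @export
read_peak_table <- function(file, quiet = FALSE) {
  if (!file.exists(file)) stop("peak table file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_peak_table(df, source = file, quiet = quiet)
}

#' Validate an in-memory PRT peak-area table
#'
#' @param df Data frame with the peak-table columns (see [read_peak_table()]).
#' @param source Label used in error messages.
#' @param quiet Suppress the parse-report message.
#' @return The validated data frame with `usable` and `ratio` columns.
#' @export
validate_peak_table <- function(df, source = "peak table", quiet = FALSE) {
  missing_cols <- setdiff(prt_required_cols, names(df))
  if (length(missing_cols)) {
    stop(source, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$sample_id, df$assay, df$dye, sep = "|")
  dups <- unique(key[duplicated(key)])
  if (length(dups)) {
    stop(source, ": duplicate (sample, assay, dye) rows: ",
         paste(dups, collapse = "; "))
  }
  df$test_area <- as.numeric(df$test_area)
  df$reference_area <- as.numeric(df$reference_area)
  bad_sign <- (df$test_area < 0 | df$reference_area < 0)
  if (any(bad_sign, na.rm = TRUE)) {
    stop(source, ": negative peak areas for sample(s): ",
         paste(unique(df$sample_id[which(bad_sign)]), collapse = ", "))
  }
  df$usable <- is.finite(df$test_area) & is.finite(df$reference_area) &
    df$test_area > 0 & df$reference_area > 0
  df$ratio <- ifelse(df$usable, df$test_area / df$reference_area, NA_real_)
  report <- list(rows_read = nrow(df),
                 usable = sum(df$usable),
                 flagged = sum(!df$usable))
  attr(df, "parse_report") <- report
  if (!quiet) {
    message(sprintf("%s: %d rows read, %d usable, %d flagged unusable",
                    source, report$rows_read, report$usable, report$flagged))
  }
  df
}

#' Read a reference-panel file of samples with known copy number
#'
#' @param file CSV with the peak-table columns plus an integer `known_cn`
#'   column.
#' @param support Integer copy-number support the panel must lie in.
#' @param quiet Suppress the parse-report message.
#' @return Validated data frame including `known_cn`.
#' @export
read_reference_panel <- function(file, support = 1:12, quiet = FALSE) {
  if (!file.exists(file)) stop("reference panel file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"known_cn" %in% names(df)) {
    stop(file, ": missing required column(s): known_cn")
  }
  df <- validate_peak_table(df, source = file, quiet = quiet)
  validate_reference_panel(df, support = support)
}

validate_reference_panel <- function(df, support = 1:12) {
  cn <- df$known_cn
  if (any(!is.finite(cn)) || any(cn != round(cn))) {
    stop("reference panel: known_cn must be integer")
  }
  if (any(cn < min(support) | cn > max(support))) {
    stop("reference panel: known_cn outside support ",
         min(support), "..", max(support))
  }
  df$known_cn <- as.integer(cn)
  df
}

#' Fit per-channel regression calibration from a reference panel
#'
#' For every assay/dye channel, fits an ordinary least-squares regression of
#' the observed peak-area ratio (response) on the known integer copy number
#' (predictor). The channel's residual dispersion `residual_sd` is the
#' standard deviation, in copy-number units, of the back-calibrated panel
#' estimates `(ratio - intercept)/slope` around their known integers. When a
#' channel has fewer residual degrees of freedom than `min_resid_df`, its
#' `residual_sd` falls back to the value pooled across all non-failed
#' channels.
#'
#' A fitted slope that is not strictly positive (ratio must increase with
#' copy number) marks the channel as failed; so does a panel with fewer than
#' two distinct known copy numbers in that channel. If every channel fails,
#' calibration aborts with an error.
#'
#' @param panel Reference-panel data frame (see [read_reference_panel()]).
#' @param min_resid_df Minimum residual degrees of freedom (`n_ref - 2`)
#'   required to trust a channel's own `residual_sd`.
#' @return An object of class `prt_calibration`: a list with a per-channel
#'   data frame (`channels`), the pooled residual SD (`pooled_sd`), and the
#'   panel size.
#' @export
fit_calibration <- function(panel, min_resid_df = 3L) {
  if (is.null(panel$usable) || is.null(panel$ratio)) {
    panel <- validate_peak_table(panel, source = "reference panel", quiet = TRUE)
  }
  if (is.null(panel$known_cn)) stop("reference panel: missing known_cn")
  panel <- validate_reference_panel(panel)
  panel <- panel[panel$usable, , drop = FALSE]

  chan_key <- unique(panel[, c("assay", "dye")])
  chan_key <- chan_key[order(chan_key$assay, chan_key$dye), , drop = FALSE]
  rows <- vector("list", nrow(chan_key))
  residuals_all <- list()

  for (i in seq_len(nrow(chan_key))) {
    sel <- panel$assay == chan_key$assay[i] & panel$dye == chan_key$dye[i]
    sub <- panel[sel, , drop = FALSE]
    row <- data.frame(assay = chan_key$assay[i], dye = chan_key$dye[i],
                      slope = NA_real_, intercept = NA_real_,
                      residual_sd = NA_real_, n_ref = nrow(sub),
                      failed = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (length(unique(sub$known_cn)) < 2L) {
      row$failed <- TRUE
      row$reason <- "fewer than 2 distinct known copy numbers"
    } else {
      fit <- stats::lm(ratio ~ known_cn, data = sub)
      cf <- stats::coef(fit)
      row$intercept <- unname(cf[1L])
      row$slope <- unname(cf[2L])
      if (!is.finite(row$slope) || row$slope <= 0) {
        row$failed <- TRUE
        row$reason <- "non-positive slope"
      } else {
        back <- (sub$ratio - row$intercept) / row$slope - sub$known_cn
        row$residual_sd <- if (length(back) > 1L) stats::sd(back) else 0
        residuals_all[[length(residuals_all) + 1L]] <- back
      }
    }
    rows[[i]] <- row
  }
  channels <- do.call(rbind, rows)
  if (all(channels$failed)) {
    stop("calibration failed for every channel: ",
         paste(unique(channels$reason), collapse = "; "))
  }
  pooled <- unlist(residuals_all)
  pooled_sd <- if (length(pooled) > 1L) stats::sd(pooled) else 0
  low_df <- !channels$failed & (channels$n_ref - 2L) < min_resid_df
  channels$residual_sd[low_df] <- pooled_sd

  structure(list(channels = channels, pooled_sd = pooled_sd,
                 min_resid_df = min_resid_df),
            class = "prt_calibration")
}

#' @export
print.prt_calibration <- function(x, ...) {
  cat("PRT channel calibration (", sum(!x$channels$failed), " of ",
      nrow(x$channels), " channels usable)\n", sep = "")
  print(x$channels, row.names = FALSE)
  cat("pooled residual SD:", format(x$pooled_sd, digits = 4), "copies\n")
  invisible(x)
}

#' Apply a channel calibration to PRT measurements
#'
#' Inverts each channel's regression: the calibrated copy-number estimate is
#' `(ratio - intercept) / slope`, with standard deviation equal to the
#' channel's `residual_sd`. Estimates falling outside
#' `[min(support) - 1, max(support) + 1]` are flagged `OUT_OF_SUPPORT` but
#' retained. Measurements on failed or uncalibrated channels are dropped
#' with a warning.
#'
#' @param model A `prt_calibration` object.
#' @param peaks Validated peak-table data frame.
#' @param support Integer copy-number support (used only for the
#'   out-of-support flag).
#' @return Data frame with one row per usable calibrated measurement:
#'   `sample_id`, `assay`, `dye`, `cn_est`, `sd`, `out_of_support`.
#' @export
apply_calibration <- function(model, peaks, support = 1:12) {
  stopifnot(inherits(model, "prt_calibration"))
  if (is.null(peaks$usable) || is.null(peaks$ratio)) {
    peaks <- validate_peak_table(peaks, quiet = TRUE)
  }
  ok_channels <- model$channels[!model$channels$failed, , drop = FALSE]
  peaks <- peaks[peaks$usable, , drop = FALSE]
  chan <- paste(peaks$assay, peaks$dye, sep = "|")
  cal_chan <- paste(ok_channels$assay, ok_channels$dye, sep = "|")
  idx <- match(chan, cal_chan)
  if (anyNA(idx)) {
    missing_chan <- sort(unique(chan[is.na(idx)]))
    warning("no usable calibration for channel(s) ",
            paste(missing_chan, collapse = ", "),
            "; their estimates are omitted")
  }
  keep <- !is.na(idx)
  peaks <- peaks[keep, , drop = FALSE]
  idx <- idx[keep]
  est <- (peaks$ratio - ok_channels$intercept[idx]) / ok_channels$slope[idx]
  lo <- min(support) - 1
  hi <- max(support) + 1
  data.frame(sample_id = peaks$sample_id,
             assay = peaks$assay,
             dye = peaks$dye,
             cn_est = est,
             sd = ok_channels$residual_sd[idx],
             out_of_support = est < lo | est > hi,
             stringsAsFactors = FALSE)
}

#' Pool dye-channel estimates within each PRT assay
#'
#' The default (`pool = "assay"`) averages the dye channels of each assay to
#' a single per-assay estimate, with the standard deviation of the mean of
#' independent channel estimates (`sqrt(sum(sd^2)) / n`); with equal channel
#' SDs this is `sd / sqrt(n)`. `pool = "channel"` keeps each dye channel as
#' its own pooled unit instead.
#'
#' @param channel_estimates Output of [apply_calibration()].
#' @param pool `"assay"` (average dye channels, then pool assays) or
#'   `"channel"` (pool raw channels directly).
#' @return Data frame `sample_id`, `unit`, `cn_est`, `sd`, `out_of_support`.
#' @export
pool_assay_estimates <- function(channel_estimates, pool = c("assay", "channel")) {
  pool <- match.arg(pool)
  ce <- channel_estimates
  if (pool == "channel") {
    return(data.frame(sample_id = ce$sample_id,
                      unit = paste(ce$assay, ce$dye, sep = ":"),
                      cn_est = ce$cn_est, sd = ce$sd,
                      out_of_support = ce$out_of_support,
                      stringsAsFactors = FALSE))
  }
  key <- paste(ce$sample_id, ce$assay, sep = "\r")
  est <- tapply(ce$cn_est, key, mean)
  sdm <- tapply(ce$sd, key, function(s) sqrt(sum(s^2)) / length(s))
  oos <- tapply(ce$out_of_support, key, any)
  parts <- strsplit(names(est), "\r", fixed = TRUE)
  out <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                    unit = vapply(parts, `[`, "", 2L),
                    cn_est = as.numeric(est),
                    sd = as.numeric(sdm),
                    out_of_support = as.logical(oos),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$unit), , drop = FALSE]
}

#' Maximum-likelihood integer copy-number call
#'
#' Treats the pooled assay estimates as independent Gaussian observations of
#' a common integer copy number. For each integer `k` in the support the
#' log-likelihood is `sum(dnorm(x_i, k, sd_i, log = TRUE))`; the call is the
#' arg-max, with ties broken to the smaller integer. The confidence is the
#' normalized likelihood weight of the winning integer,
#' `L(k*) / sum_k L(k)`, computed with max-subtraction for numerical
#' stability.
#'
#' @param estimates Numeric vector of pooled copy-number estimates.
#' @param sds Their standard deviations (copy-number units); values below
#'   `sd_floor` are floored to avoid degenerate likelihoods.
#' @param support Sorted integer support (default 1..12).
#' @param sd_floor Minimum usable SD, in copies.
#' @return List with `ml_integer_cn`, `confidence`, and the named
#'   log-likelihood vector `loglik`.
#' @export
call_integer_cn <- function(estimates, sds, support = 1:12, sd_floor = 1e-3) {
  stopifnot(length(estimates) == length(sds), length(estimates) >= 1L)
  support <- sort(as.integer(support))
  sds <- pmax(sds, sd_floor)
  loglik <- vapply(support,
                   function(k) sum(stats::dnorm(estimates, k, sds, log = TRUE)),
                   numeric(1))
  best <- which.max(loglik)   # first maximum: ties go to the smaller integer
  w <- exp(loglik - loglik[best])
  list(ml_integer_cn = support[best],
       confidence = 1 / sum(w),
       loglik = stats::setNames(loglik, support))
}

#' Inverse-variance-weighted mean copy number
#'
#' `sum(x_i / sd_i^2) / sum(1 / sd_i^2)`; equals the arithmetic mean when
#' all SDs are equal. This is the continuous "weighted mean PRT copy number"
#' used as the copy-number axis in association analyses.
#'
#' @inheritParams call_integer_cn
#' @return A single numeric copy-number estimate.
#' @export
weighted_mean_cn <- function(estimates, sds, sd_floor = 1e-3) {
  stopifnot(length(estimates) == length(sds), length(estimates) >= 1L)
  sds <- pmax(sds, sd_floor)
  w <- 1 / sds^2
  sum(estimates * w) / sum(w)
}

#' Genotype a cohort of samples from peak tables
#'
#' End-to-end channel calibration and integer calling: fits the reference
#' panel calibration, calibrates every usable measurement, pools dye
#' channels within assays, and emits one call per sample. Samples with fewer
#' than `min_channels` pooled estimates receive no call and the
#' `TOO_FEW_CHANNELS` flag (the mechanism behind typing failure); calls with
#' confidence below `low_conf` are flagged `LOW_CONFIDENCE`; samples with
#' any pooled estimate outside the extended support are flagged
#' `OUT_OF_SUPPORT`.
#'
#' @param peaks Validated cohort peak table.
#' @param panel Reference panel data frame.
#' @param support Integer copy-number support.
#' @param min_channels Minimum pooled estimates required for a call.
#' @param pool Channel pooling mode, see [pool_assay_estimates()].
#' @param sd_floor Minimum SD in copies.
#' @param low_conf Confidence threshold below which `LOW_CONFIDENCE` is set.
#' @param min_resid_df Passed to [fit_calibration()].
#' @return Data frame of calls: `sample_id`, `n_units`, `weighted_mean_cn`,
#'   `ml_integer_cn`, `confidence`, `qc_flags`; the fitted calibration is
#'   attached as attribute `"calibration"`.
#' @export
genotype_samples <- function(peaks, panel, support = 1:12, min_channels = 2L,
                             pool = c("assay", "channel"), sd_floor = 1e-3,
                             low_conf = 0.60, min_resid_df = 3L) {
  pool <- match.arg(pool)
  if (is.null(peaks$usable)) peaks <- validate_peak_table(peaks, quiet = TRUE)
  cal <- fit_calibration(panel, min_resid_df = min_resid_df)
  ce <- apply_calibration(cal, peaks, support = support)
  pe <- pool_assay_estimates(ce, pool = pool)

  ids <- unique(peaks$sample_id)
  out <- data.frame(sample_id = ids,
                    n_units = 0L,
                    weighted_mean_cn = NA_real_,
                    ml_integer_cn = NA_integer_,
                    confidence = NA_real_,
                    qc_flags = "",
                    stringsAsFactors = FALSE)
  pe_split <- split(pe, pe$sample_id)
  for (i in seq_along(ids)) {
    sub <- pe_split[[ids[i]]]
    flags <- character(0)
    n_units <- if (is.null(sub)) 0L else nrow(sub)
    out$n_units[i] <- n_units
    if (n_units < min_channels) {
      out$qc_flags[i] <- join_flags(c(flags, "TOO_FEW_CHANNELS"))
      next
    }
    call <- call_integer_cn(sub$cn_est, sub$sd, support = support,
                            sd_floor = sd_floor)
    out$weighted_mean_cn[i] <- weighted_mean_cn(sub$cn_est, sub$sd,
                                                sd_floor = sd_floor)
    out$ml_integer_cn[i] <- call$ml_integer_cn
    out$confidence[i] <- call$confidence
    if (call$confidence < low_conf) flags <- c(flags, "LOW_CONFIDENCE")
    if (any(sub$out_of_support)) flags <- c(flags, "OUT_OF_SUPPORT")
    out$qc_flags[i] <- join_flags(flags)
  }
  attr(out, "calibration") <- cal
  out
}

#' Serialize a channel calibration to a JSON report
#'
#' @param model A `prt_calibration` object.
#' @param file Optional path; when given, the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
calibration_report_json <- function(model, file = NULL) {
  stopifnot(inherits(model, "prt_calibration"))
  payload <- list(channels = model$channels, pooled_residual_sd = model$pooled_sd)
  txt <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
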