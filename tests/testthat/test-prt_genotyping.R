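test_that("peak-table validation computes ratios and flags unusable rows", {
  df <- data.frame(sample_id = c("S1", "S2"),
                   assay = c("PRT107A", "HSPD21"),
                   dye = c("FAM", "HEX"),
                   test_area = c(1200, 0),
                   reference_area = c(600, 500))
  out <- validate_peak_table(df, quiet = TRUE)
  expect_equal(out$ratio[1], 2.0)
  expect_true(out$usable[1])
  expect_false(out$usable[2])
  expect_true(is.na(out$ratio[2]))
  expect_equal(attr(out, "parse_report"),
               list(rows_read = 2L, usable = 1L, flagged = 1L))
})

test_that("peak-table contract errors name the offending column or rows", {
  df <- data.frame(sample_id = "S1", assay = "PRT107A", dye = "FAM",
                   test_area = 100)
  expect_error(validate_peak_table(df, quiet = TRUE), "reference_area")
  dup <- make_peaks(c("S1", "S1"), "PRT107A", "FAM", c(2, 2.1))
  expect_error(validate_peak_table(dup, quiet = TRUE), "duplicate")
  neg <- make_peaks("S1", "PRT107A", "FAM", 2)
  neg$test_area <- -5
  expect_error(validate_peak_table(neg, quiet = TRUE), "negative")
})

test_that("calibration recovers exact linear and affine reference data", {
  panel <- make_panel(2:5, slope = 0.5, intercept = 0)
  cal <- fit_calibration(panel)
  expect_equal(cal$channels$slope, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(cal$channels$intercept, rep(0, 5), tolerance = 1e-12)
  expect_equal(cal$channels$residual_sd, rep(0, 5), tolerance = 1e-12)

  panel2 <- make_panel(2:5, slope = 0.5, intercept = 0.1)
  cal2 <- fit_calibration(panel2)
  expect_equal(cal2$channels$slope, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(cal2$channels$intercept, rep(0.1, 5), tolerance = 1e-12)
})

test_that("calibration matches the closed-form least-squares oracle on noisy panels", {
  set.seed(42)
  for (rep in 1:10) {
    cns <- 2:7
    panel <- make_panel(cns, slope = 0.5)
    panel$test_area <- panel$test_area * (1 + rnorm(nrow(panel), 0, 0.05))
    cal <- fit_calibration(panel)
    panel <- validate_peak_table(panel, quiet = TRUE)
    for (i in seq_len(nrow(cal$channels))) {
      ch <- cal$channels[i, ]
      sel <- panel$assay == ch$assay & panel$dye == ch$dye
      exp_fit <- oracle_ols(panel$known_cn[sel], panel$ratio[sel])
      expect_equal(ch$slope, unname(exp_fit["slope"]), tolerance = 1e-10)
      expect_equal(ch$intercept, unname(exp_fit["intercept"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("calibration failure modes are reported per channel and fatally when universal", {
  panel <- make_panel(c(4, 4))  # a single distinct copy number everywhere
  expect_error(fit_calibration(panel), "calibration failed for every channel")

  # one channel with decreasing ratios (negative slope) is marked failed
  panel <- make_panel(2:5)
  bad <- panel$assay == "PRT3"
  panel$test_area[bad] <- rev(panel$test_area[bad])
  cal <- fit_calibration(panel)
  expect_true(cal$channels$failed[cal$channels$assay == "PRT3"])
  expect_false(any(cal$channels$failed[cal$channels$assay != "PRT3"]))
})

test_that("applying a calibration inverts the regression and flags out-of-support", {
  panel <- make_panel(2:5, slope = 0.5, intercept = 0.1)
  cal <- fit_calibration(panel)
  peaks <- make_peaks(c("A", "B"), "PRT107A", "FAM", c(2.1, 6.7))
  est <- apply_calibration(cal, peaks, support = 1:12)
  expect_equal(est$cn_est[est$sample_id == "A"], 4.0, tolerance = 1e-12)
  expect_equal(est$cn_est[est$sample_id == "B"], 13.2, tolerance = 1e-12)
  expect_false(est$out_of_support[est$sample_id == "A"])
  expect_true(est$out_of_support[est$sample_id == "B"])
})

test_that("measurements on uncalibrated channels are omitted with a warning", {
  panel <- make_panel(2:5)
  panel <- panel[panel$assay != "PRT3", ]
  cal <- fit_calibration(panel)
  peaks <- rbind(make_peaks("A", "PRT107A", "FAM", 2),
                 make_peaks("A", "PRT3", "NED", 2))
  expect_warning(est <- apply_calibration(cal, peaks), "PRT3")
  expect_equal(nrow(est), 1L)
  expect_equal(est$assay, "PRT107A")
})

test_that("ML integer calling: trivial, tie-break and oracle-derived cases", {
  res <- call_integer_cn(c(4, 4, 4), rep(0.3, 3))
  expect_equal(res$ml_integer_cn, 4L)
  expect_gt(res$confidence, 0.99)

  # symmetric tie between 2 and 3 resolves to the smaller integer
  tie <- call_integer_cn(c(2.5, 2.5), c(0.3, 0.3))
  expect_equal(tie$ml_integer_cn, 2L)
  expect_equal(unname(tie$loglik["2"]), unname(tie$loglik["3"]))

  # frozen expected values from the enumeration oracle:
  # oracle_ml_enum(c(3.6,4.2,4.1), c(0.30,0.25,0.35)) -> cn 4, conf 0.9612897...
  res <- call_integer_cn(c(3.6, 4.2, 4.1), c(0.30, 0.25, 0.35))
  orc <- oracle_ml_enum(c(3.6, 4.2, 4.1), c(0.30, 0.25, 0.35))
  expect_equal(res$ml_integer_cn, orc$ml_integer_cn)
  expect_equal(res$ml_integer_cn, 4L)
  expect_equal(res$confidence, orc$confidence, tolerance = 1e-12)
})

test_that("likelihood weights over the support normalize to one", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    res <- call_integer_cn(runif(k, 0, 13), runif(k, 0.05, 0.6))
    w <- exp(res$loglik - max(res$loglik))
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
    expect_gt(res$confidence, 0)
    expect_lte(res$confidence, 1)
  }
})

test_that("weighted mean copy number equals the inverse-variance oracle", {
  expect_equal(weighted_mean_cn(c(4, 4, 4), rep(0.3, 3)), 4)
  expect_equal(weighted_mean_cn(c(3, 5), c(0.2, 0.2)), 4)
  wm <- weighted_mean_cn(c(3.6, 4.2, 4.1), c(0.30, 0.25, 0.35))
  expect_equal(wm, oracle_ivw(c(3.6, 4.2, 4.1), c(0.30, 0.25, 0.35)),
               tolerance = 1e-12)
})

test_that("noise-free round trip recovers every known integer exactly", {
  panel <- make_panel(2:7, slope = 0.5, intercept = 0.05)
  cal <- fit_calibration(panel)
  est <- apply_calibration(cal, panel)
  known <- panel$known_cn[match(est$sample_id, panel$sample_id)]
  expect_equal(est$cn_est, known, tolerance = 1e-9)
  calls <- genotype_samples(panel, panel, support = 1:12)
  expect_equal(calls$ml_integer_cn,
               panel$known_cn[match(calls$sample_id, panel$sample_id)])
  expect_equal(calls$weighted_mean_cn,
               as.numeric(panel$known_cn[match(calls$sample_id,
                                               panel$sample_id)]),
               tolerance = 1e-9)
})

test_that("shifting all panel copy numbers by +1 shifts every estimate by +1", {
  cns <- 2:6
  panel_a <- make_panel(cns)
  panel_b <- make_panel(cns + 1)
  peaks <- make_peaks("X", "PRT107A", "FAM", 0.5 * 3.3)
  est_a <- apply_calibration(fit_calibration(panel_a), peaks)
  # same peaks regenerated for the shifted world: ratio for cn+1
  peaks_b <- make_peaks("X", "PRT107A", "FAM", 0.5 * 4.3)
  est_b <- apply_calibration(fit_calibration(panel_b), peaks_b)
  expect_equal(est_b$cn_est, est_a$cn_est + 1, tolerance = 1e-9)
})

test_that("raising all of a sample's ratios never lowers the integer call", {
  panel <- make_panel(2:7)
  cal <- fit_calibration(panel)
  set.seed(11)
  for (i in 1:25) {
    base_ratio <- runif(5, 0.6, 3.4)
    bump <- runif(1, 0, 1)
    chans <- data.frame(assay = c("PRT107A", "PRT107A", "HSPD21", "HSPD21",
                                  "PRT3"),
                        dye = c("FAM", "HEX", "FAM", "HEX", "NED"))
    p1 <- make_peaks("S", chans$assay, chans$dye, base_ratio)
    p2 <- make_peaks("S", chans$assay, chans$dye, base_ratio + bump)
    c1 <- genotype_samples(p1, panel)
    c2 <- genotype_samples(p2, panel)
    expect_gte(c2$ml_integer_cn, c1$ml_integer_cn)
  }
})

test_that("samples below the channel minimum get no call and a QC flag", {
  panel <- make_panel(2:7)
  peaks <- rbind(
    make_peaks("OK", c("PRT107A", "PRT107A", "HSPD21", "HSPD21", "PRT3"),
               c("FAM", "HEX", "FAM", "HEX", "NED"), rep(2, 5)),
    make_peaks("FAIL", "PRT3", "NED", 2))
  calls <- genotype_samples(peaks, panel, min_channels = 2L)
  fail_row <- calls[calls$sample_id == "FAIL", ]
  expect_true(is.na(fail_row$ml_integer_cn))
  expect_match(fail_row$qc_flags, "TOO_FEW_CHANNELS")
  ok_row <- calls[calls$sample_id == "OK", ]
  expect_equal(ok_row$ml_integer_cn, 4L)
})

test_that("assay pooling averages dye channels and shrinks the sd", {
  ce <- data.frame(sample_id = "S", assay = c("PRT107A", "PRT107A"),
                   dye = c("FAM", "HEX"), cn_est = c(3.8, 4.2),
                   sd = c(0.3, 0.3), out_of_support = FALSE,
                   stringsAsFactors = FALSE)
  pooled <- pool_assay_estimates(ce, pool = "assay")
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$cn_est, 4.0)
  expect_equal(pooled$sd, 0.3 / sqrt(2), tolerance = 1e-12)
  raw <- pool_assay_estimates(ce, pool = "channel")
  expect_equal(nrow(raw), 2L)
})
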