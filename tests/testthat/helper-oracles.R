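# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# Closed-form ordinary least squares: slope = Sxy/Sxx, intercept from means.
oracle_ols <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  c(intercept = my - slope * mx, slope = slope)
}

# Brute-force Gaussian log-likelihood enumeration over the integer support.
oracle_ml_enum <- function(estimates, sds, support = 1:12, sd_floor = 1e-3) {
  sds <- pmax(sds, sd_floor)
  loglik <- sapply(support, function(k) {
    sum(-log(sds * sqrt(2 * pi)) - (estimates - k)^2 / (2 * sds^2))
  })
  best <- support[loglik == max(loglik)][1L]  # tie -> smaller integer
  w <- exp(loglik - max(loglik))
  list(ml_integer_cn = best,
       confidence = w[support == best] / sum(w),
       loglik = loglik)
}

# Direct-formula inverse-variance-weighted mean.
oracle_ivw <- function(estimates, sds, sd_floor = 1e-3) {
  sds <- pmax(sds, sd_floor)
  sum(estimates / sds^2) / sum(1 / sds^2)
}

# Pearson correlation from raw sums (no call into cor()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Own permutation generator (list-based) for the exact-p oracles.
oracle_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exact two-sided Spearman permutation p by full enumeration.
oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(oracle_pearson(rx, ry))
  stats <- vapply(oracle_perms(ry), function(p) abs(oracle_pearson(rx, p)),
                  numeric(1))
  mean(stats >= obs - 1e-12)
}

# Mann-Whitney U by direct pair counting (ties count one half).
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Exact two-sided Mann-Whitney p: enumerate all choose(n1+n2, n1) group
# assignments of the pooled values, compare |U - n1*n2/2|.
oracle_mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  mu <- n1 * n2 / 2
  obs <- abs(oracle_u_stat(x, y) - mu)
  combos <- utils::combn(n1 + n2, n1)
  devs <- apply(combos, 2L, function(idx) {
    abs(oracle_u_stat(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# Coefficient of variation from raw sums.
oracle_cv <- function(reps) {
  m <- sum(reps) / length(reps)
  sqrt(sum((reps - m)^2) / (length(reps) - 1)) / m
}

# Small in-memory peak table builder used across the PRT tests.
make_peaks <- function(sample_id, assay, dye, ratio, ref_area = 1000) {
  data.frame(sample_id = sample_id, assay = assay, dye = dye,
             test_area = ratio * ref_area, reference_area = ref_area,
             stringsAsFactors = FALSE)
}

# Noise-free panel: one row per channel and copy number, ratio affine in cn.
make_panel <- function(cns, channels = data.frame(
                         assay = c("PRT107A", "PRT107A", "HSPD21", "HSPD21",
                                   "PRT3"),
                         dye = c("FAM", "HEX", "FAM", "HEX", "NED"),
                         stringsAsFactors = FALSE),
                       slope = 0.5, intercept = 0) {
  grid <- expand.grid(i = seq_along(cns), ch = seq_len(nrow(channels)))
  df <- make_peaks(sprintf("REF%02d", grid$i),
                   channels$assay[grid$ch], channels$dye[grid$ch],
                   slope * cns[grid$i] + intercept)
  df$known_cn <- cns[grid$i]
  df
}
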