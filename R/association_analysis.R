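#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes the Spearman coefficient as the Pearson correlation of mid-ranks
#' (ties receive average ranks) on pairwise-complete observations. The
#' two-sided p-value is obtained by full permutation enumeration when
#' `n <= exact_n_max` and neither vector has ties, and otherwise by the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with any missing value
#'   are dropped.
#' @param exact_n_max Largest `n` for which the exact permutation p-value is
#'   enumerated (default 9; 9! = 362,880 permutations).
#' @return List with `rho`, `p_value`, `n`, and `method_note` (one of
#'   `"exact_permutation"`, `"t_approximation"`, `"CONSTANT_INPUT"`,
#'   `"INSUFFICIENT_N"`).
#' @export
spearman_cor <- function(x, y, exact_n_max = 9L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method_note = "INSUFFICIENT_N"))
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method_note = "CONSTANT_INPUT"))
  }
  rho <- stats::cor(rx, ry)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= exact_n_max && no_ties) {
    p <- spearman_exact_p(rx, ry)
    note <- "exact_permutation"
  } else {
    p <- spearman_t_p(rho, n)
    note <- "t_approximation"
  }
  list(rho = rho, p_value = p, n = n, method_note = note)
}

# Exact two-sided permutation p for tie-free ranks: enumerate all n!
# orderings of y's ranks against x's and count |rho| at least as extreme.
spearman_exact_p <- function(rx, ry, tol = 1e-12) {
  n <- length(rx)
  perms <- all_permutations(n)
  ry_perm <- matrix(ry[perms], nrow = nrow(perms))
  d2 <- sweep(ry_perm, 2L, rx)^2
  rho_perm <- 1 - 6 * rowSums(d2) / (n^3 - n)
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / (n^3 - n)
  mean(abs(rho_perm) >= abs(rho_obs) - tol)
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(.Machine$double.xmin)  # keep p in (0, 1]
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Pairwise Spearman correlation matrix
#'
#' One correlation per unordered pair of the requested variables, computed
#' on pairwise-complete observations. Pairs whose usable `n` is below 3 or
#' whose ranks are constant are not emitted; they are recorded in the
#' `"skipped"` attribute. The per-pair x/y value lists needed to draw a
#' scatterplot matrix are attached as attribute `"scatter_data"`.
#'
#' @param data Data frame holding the variables.
#' @param variables Character vector (length >= 2) of column names.
#' @param stratum Label stored in the `stratum` column of the result.
#' @param exact_n_max Passed to [spearman_cor()].
#' @return Data frame with columns `stratum`, `var_x`, `var_y`, `n`, `rho`,
#'   `p_value`, `method_note`.
#' @export
pairwise_matrix <- function(data, variables, stratum = "all",
                            exact_n_max = 9L) {
  unknown <- setdiff(variables, names(data))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  if (length(variables) < 2L) stop("need at least 2 variables")
  pairs <- utils::combn(variables, 2L)
  rows <- list()
  skipped <- list()
  scatter <- list()
  for (j in seq_len(ncol(pairs))) {
    vx <- pairs[1L, j]; vy <- pairs[2L, j]
    res <- spearman_cor(data[[vx]], data[[vy]], exact_n_max = exact_n_max)
    row <- data.frame(stratum = stratum, var_x = vx, var_y = vy,
                      n = res$n, rho = res$rho, p_value = res$p_value,
                      method_note = res$method_note,
                      stringsAsFactors = FALSE)
    if (res$method_note %in% c("INSUFFICIENT_N", "CONSTANT_INPUT")) {
      skipped[[length(skipped) + 1L]] <- row
    } else {
      rows[[length(rows) + 1L]] <- row
      ok <- is.finite(data[[vx]]) & is.finite(data[[vy]])
      scatter[[paste(vx, vy, sep = "~")]] <-
        list(x = data[[vx]][ok], y = data[[vy]][ok])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0), var_x = character(0),
               var_y = character(0), n = integer(0), rho = numeric(0),
               p_value = numeric(0), method_note = character(0),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "scatter_data") <- scatter
  out
}

#' Apply the cohort exclusion rules
#'
#' Two nested analysis sets are produced. Subjects who started progesterone
#' before sample collection are excluded from everything (their biomarkers
#' could reflect treatment, not baseline biology). The outcome-analysis set
#' additionally excludes subjects who received treatment intended to prevent
#' preterm birth after sampling (cervical cerclage, post-sampling
#' progesterone) and pregnancies ending in miscarriage or termination, since
#' delivery-outcome labels are not interpretable for them.
#'
#' @param cohort Data frame with logical columns `pre_sampling_progesterone`,
#'   `post_sampling_cerclage`, `post_sampling_progesterone` and a character
#'   `outcome` column (`term`/`preterm`/`miscarriage`/`termination`/...).
#' @return List with `all_comers` (data frame), `outcome_set` (data frame),
#'   and `audit` (data frame `sample_id`, `rule`, `set_removed_from`).
#' @export
apply_exclusions <- function(cohort) {
  needed <- c("sample_id", "pre_sampling_progesterone",
              "post_sampling_cerclage", "post_sampling_progesterone",
              "outcome")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  audit <- list()
  note <- function(ids, rule, set) {
    if (length(ids)) {
      audit[[length(audit) + 1L]] <<- data.frame(
        sample_id = ids, rule = rule, set_removed_from = set,
        stringsAsFactors = FALSE)
    }
  }
  pre <- as.logical(cohort$pre_sampling_progesterone)
  note(cohort$sample_id[pre], "pre_sampling_progesterone", "all")
  all_comers <- cohort[!pre, , drop = FALSE]

  cerc <- as.logical(all_comers$post_sampling_cerclage)
  post <- as.logical(all_comers$post_sampling_progesterone)
  mis <- all_comers$outcome == "miscarriage"
  term_pg <- all_comers$outcome == "termination"
  note(all_comers$sample_id[cerc], "post_sampling_cerclage", "outcome")
  note(all_comers$sample_id[post], "post_sampling_progesterone", "outcome")
  note(all_comers$sample_id[mis], "miscarriage", "outcome")
  note(all_comers$sample_id[term_pg], "termination", "outcome")
  outcome_set <- all_comers[!(cerc | post | mis | term_pg), , drop = FALSE]

  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(sample_id = character(0), rule = character(0),
               set_removed_from = character(0), stringsAsFactors = FALSE)
  list(all_comers = all_comers, outcome_set = outcome_set, audit = audit_df)
}

#' Correlations within delivery-outcome strata
#'
#' Runs [pairwise_matrix()] separately within each requested stratum of the
#' outcome variable. Strata with fewer than `min_n` subjects are still
#' reported, with an `UNDERPOWERED` note and no coefficient, rather than
#' silently dropped.
#'
#' @param cohort Data frame (normally the outcome-analysis set from
#'   [apply_exclusions()]).
#' @param variables Variables to correlate.
#' @param outcome_var Name of the stratifying column.
#' @param strata Stratum labels to analyse.
#' @param min_n Minimum stratum size for correlations to be computed.
#' @param exact_n_max Passed to [spearman_cor()].
#' @return Data frame in the [pairwise_matrix()] layout, rows for all strata.
#' @export
stratified_correlations <- function(cohort, variables, outcome_var = "outcome",
                                    strata = c("term", "preterm"), min_n = 3L,
                                    exact_n_max = 9L) {
  if (!outcome_var %in% names(cohort)) {
    stop("unknown outcome variable: ", outcome_var)
  }
  out <- list()
  for (s in strata) {
    sub <- cohort[cohort[[outcome_var]] == s, , drop = FALSE]
    if (nrow(sub) < min_n) {
      pairs <- utils::combn(variables, 2L)
      out[[s]] <- data.frame(stratum = s, var_x = pairs[1L, ],
                             var_y = pairs[2L, ], n = nrow(sub),
                             rho = NA_real_, p_value = NA_real_,
                             method_note = "UNDERPOWERED",
                             stringsAsFactors = FALSE)
    } else {
      out[[s]] <- pairwise_matrix(sub, variables, stratum = s,
                                  exact_n_max = exact_n_max)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Mann-Whitney U test between two groups
#'
#' Rank-sum test of a common distribution against a two-sided shift
#' alternative. The U statistic counts, over all cross-group pairs, how
#' often an `x` value exceeds a `y` value (ties count one half). For small
#' groups the two-sided p-value is computed by exact enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the pooled values (so ties are
#' handled exactly), counting assignments whose U deviates from the null
#' mean `n1 * n2 / 2` at least as much as the observed U; identical groups
#' therefore give p = 1. Larger groups use the normal approximation with the
#' tie-corrected variance.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @param exact_max Use exact enumeration when `min(n1, n2) <= exact_max`.
#' @param max_combinations Cap on the number of enumerated assignments;
#'   above it the normal approximation is used even for small groups.
#' @return List with `U`, `p_value`, `n_x`, `n_y`, `median_x`, `median_y`,
#'   `method_note`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L, max_combinations = 250000) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    return(list(U = NA_real_, p_value = NA_real_, n_x = n1, n_y = n2,
                median_x = NA_real_, median_y = NA_real_,
                method_note = "EMPTY_GROUP"))
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  u_from_idx <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U <- u_from_idx(seq_len(n1))
  mu <- n1 * n2 / 2

  exact <- min(n1, n2) <= exact_max &&
    choose(n1 + n2, n1) <= max_combinations
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    note <- "exact_enumeration"
  } else {
    ties <- table(pooled)
    N <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      note <- "degenerate_all_tied"
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      note <- "normal_approximation_tie_corrected"
    }
  }
  list(U = U, p_value = p, n_x = n1, n_y = n2,
       median_x = stats::median(x), median_y = stats::median(y),
       method_note = note)
}

#' Compare a variable between two outcome groups
#'
#' @param cohort Data frame.
#' @param variable Column to compare.
#' @param group_var Grouping column (default `"outcome"`).
#' @param groups The two group labels, in order.
#' @param ... Passed to [mann_whitney()].
#' @return One-row data frame: `variable`, group sizes and medians, `U`,
#'   `p_value`, `method_note`; `NULL` if either group is empty.
#' @export
compare_groups <- function(cohort, variable, group_var = "outcome",
                           groups = c("term", "preterm"), ...) {
  stopifnot(variable %in% names(cohort), group_var %in% names(cohort),
            length(groups) == 2L)
  x <- cohort[[variable]][cohort[[group_var]] == groups[1L]]
  y <- cohort[[variable]][cohort[[group_var]] == groups[2L]]
  res <- mann_whitney(x, y, ...)
  if (res$method_note == "EMPTY_GROUP") return(NULL)
  data.frame(variable = variable,
             group_x = groups[1L], group_y = groups[2L],
             n_x = res$n_x, n_y = res$n_y,
             median_x = res$median_x, median_y = res$median_y,
             U = res$U, p_value = res$p_value,
             method_note = res$method_note,
             stringsAsFactors = FALSE)
}
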