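#' @keywords internal
"_PACKAGE"

# Derive a reproducible 32-bit sub-seed for a named random component.
# Distinct components get decoupled streams so changing the parameters of
# one component never perturbs the draws of another.
sub_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 113 + component * 7919) %% 2147483629)
}

# Collapse a character vector of QC flags to the semicolon-joined form used
# in all output tables ("" when no flags).
join_flags <- function(flags) {
  flags <- unique(flags[nzchar(flags)])
  paste(sort(flags), collapse = ";")
}

# All permutations of 1..n as an n! x n integer matrix (lexicographic by
# first column). Used by the exact permutation tests; n is capped by the
# callers well before this becomes expensive.
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    blocks[[i]] <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  out
}
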