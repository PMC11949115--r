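# Independent oracles used across the suite.

# Brute-force bounded minimisation by iterative dense-grid refinement
# (no derivatives, no golden section): scan, zoom on the best cell, repeat.
oracle_grid_min <- function(f, lower, upper, n = 4001, levels = 4) {
  for (lvl in seq_len(levels)) {
    x <- seq(lower, upper, length.out = n)
    y <- vapply(x, f, numeric(1))
    i <- which.min(y)
    lower <- x[max(1L, i - 1L)]
    upper <- x[min(n, i + 1L)]
  }
  x[i]
}

# Closed-form polyprotic fractions written out directly (plain powers of ten,
# no log-space rearrangement) for cross-checking speciate().
oracle_alpha <- function(pKa, ph) {
  H <- 10^(-ph)
  Ka <- 10^(-pKa)
  terms <- c(1, cumprod(Ka) / H^seq_along(Ka))
  terms / sum(terms)
}

# Random buffer definitions for property tests.
random_buffer <- function() {
  n <- sample(1:4, 1)
  pKa <- sort(runif(n, 1, 13))
  while (any(diff(pKa) < 0.2)) pKa <- sort(runif(n, 1, 13))
  buffer_definition(sprintf("rand%d", sample.int(1e6, 1)), pKa)
}

# Total ionic concentration bookkeeping for electroneutrality checks.
net_charge <- function(spec) {
  sum(spec$charge * spec$conc_mM)
}
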