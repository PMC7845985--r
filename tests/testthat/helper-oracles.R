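# Independent oracles used across test files.

# full-support enumeration of the two-sided conditional binomial p-value
# (method of small probabilities, tie tolerance matching the frozen rule)
brute_binom_p <- function(x, t, pr, eps = 1e-10) {
  if (t == 0) return(1)
  d <- dbinom(0:t, t, pr)
  sum(d[d <= dbinom(x, t, pr) * (1 + eps)])
}

# brute-force N50: try every observed length as candidate, keep the largest
# whose at-least-that-long contigs cover half the assembly
brute_n50 <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  }
  min(lengths)
}

# small default config for fast simulations
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 400L,
                   library_sizes = c(SW = 5e4, SD = 5e4, TW = 5e4, TD = 5e4),
                   de_fraction = 0.1, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
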