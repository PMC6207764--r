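# Stable log(sum(exp(x))) for possibly very large |x|.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Cumulative cooperator payoff advantage C_i = sum_{k<=i} D_k, i = 0..N-1,
# with D_k the Fermi-rule payoff difference including interference.
cumulative_delta <- function(game, params, scheme) {
  k <- seq_len(params$N - 1)
  c(0, cumsum(delta_k(k, game, params, scheme)))
}
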