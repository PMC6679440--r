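# Independent brute-force oracles. These deliberately avoid the code paths
# they check: the Poisson tail is summed term by term, and the Fisher test
# is enumerated over the full hypergeometric support with choose().

poisson_tail_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  1 - exp(-lambda) * sum(lambda^(0:(k - 1)) / factorial(0:(k - 1)))
}

fisher_oracle <- function(k_fwd, k_rev, K_fwd, K_rev) {
  m <- k_fwd + k_rev
  xs <- max(0, m - K_rev):min(K_fwd, m)
  pr <- choose(K_fwd, xs) * choose(K_rev, m - xs) / choose(K_fwd + K_rev, m)
  p_obs <- pr[xs == k_fwd]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
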