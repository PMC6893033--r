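# Small fixture builders shared across test files.

tiny_net <- function(M = 5, mu_BM = -0.05, seed = 3, beta = 1) {
  make_random_sampling_network(M, mu_BM, seed = seed, beta = beta)
}

# Brute-force Boltzmann oracle: independent of the Gray-code enumeration path.
brute_boltzmann <- function(net) {
  M <- net$M
  codes <- 0:(2^M - 1)
  S <- sapply(seq_len(M), function(k) as.integer(bitwAnd(codes, 2^(k - 1)) > 0))
  if (M == 1) S <- matrix(S, ncol = 1)
  expo <- apply(S, 1, function(s) {
    net$beta * (0.5 * sum(net$W * outer(s, s)) + sum(net$b * s))
  })
  p <- exp(expo - max(expo))
  p / sum(p)
}

small_noise_params <- function(...) {
  utils::modifyList(noise_params(K = 50L, N = 100L), list(...))
}
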