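# Shared builders for small test networks.

small_ca3 <- function(N = 1000, C = 200, a = 0.05, seed = 1, ...) {
  con <- build_diluted_connectivity(N, C, seed = seed)
  ca3_network(con, a_target = a, ...)
}

store_binary <- function(net, p, a = net$a_target, seed = 2) {
  pats <- generate_patterns(net$N, p, a, seed = seed)
  W <- store_patterns(net, pats, rule = "covariance", a_pre = a, a_post = a)
  list(patterns = pats, W = W)
}

# Independent brute-force synchronous k-WTA map: plain loops, no matrix
# algebra, used as the oracle for small-network equivalence tests.
brute_step <- function(W, state, k, C) {
  N <- length(state)
  h <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) acc <- acc + W[i, j] * state[j]
    h[i] <- acc / C
  }
  out <- numeric(N)
  out[order(h, decreasing = TRUE)[seq_len(k)]] <- 1
  out
}

brute_fixed_points <- function(W, states, k, C) {
  apply(states, 1L, function(s) identical(brute_step(W, s, k, C), as.numeric(s)))
}

# All binary states of length N with exactly k active units, one per row.
enumerate_states <- function(N, k) {
  combs <- utils::combn(N, k)
  t(apply(combs, 2L, function(idx) {
    s <- numeric(N); s[idx] <- 1; s
  }))
}

kendall_tau <- function(x, y) stats::cor(x, y, method = "kendall")
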