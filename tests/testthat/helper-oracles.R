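# independent oracles for the spectral pruning stage

# exhaustive maximiser of x'Wx / |x|^2 over binary one-to-one assignments
brute_force_prune <- function(W, pairs) {
  n <- nrow(pairs)
  best <- list(score = -Inf, set = integer(0))
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (anyDuplicated(pairs$m[idx]) || anyDuplicated(pairs$t[idx])) next
    score <- sum(W[idx, idx]) / length(idx)
    if (score > best$score) best <- list(score = score, set = idx)
  }
  best$set
}

make_pairs <- function(m, t, dist = 0) {
  structure(list(pairs = data.frame(m = m, t = t, m_vertex = m, t_vertex = t,
                                    dist = dist),
                 stage = "C"), class = "correspondence_set")
}

planted_instance <- function(n_good, n_out, seed, unary_out = 0.05) {
  set.seed(seed)
  n <- n_good + n_out
  W <- matrix(runif(n * n, 0, 0.05), n, n)
  W <- (W + t(W)) / 2
  W[seq_len(n_good), seq_len(n_good)] <- 0.9
  diag(W) <- c(rep(0.9, n_good), rep(unary_out, n_out))
  # distinct features: fully one-to-one candidate set
  list(W = W, C = make_pairs(seq_len(n), seq_len(n)))
}
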