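# slow, loop-based reference implementation of the Dirichlet fixed point,
# kept deliberately independent of the vectorised version in the package
.ref_rfx <- function(log_ev, alpha0 = 1, iters = 2000) {
  N <- nrow(log_ev); K <- ncol(log_ev)
  alpha <- rep(alpha0, K)
  for (it in seq_len(iters)) {
    u <- matrix(0, N, K)
    for (n in seq_len(N)) {
      for (k in seq_len(K)) {
        u[n, k] <- exp(log_ev[n, k] + digamma(alpha[k]) - digamma(sum(alpha)) -
                         max(log_ev[n, ]))
      }
      u[n, ] <- u[n, ] / sum(u[n, ])
    }
    alpha_new <- rep(alpha0, K)
    for (k in seq_len(K)) alpha_new[k] <- alpha_new[k] + sum(u[, k])
    if (max(abs(alpha_new - alpha)) < 1e-12) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  alpha
}

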