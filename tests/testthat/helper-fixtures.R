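# Shared fixtures and independent oracles used across the test files.

vance_model <- survival_model("vance")

# Brute-force fixed-step Euler integration of the fusion kinetics;
# independent of the production Runge-Kutta kernel.
euler_fusion <- function(N0, alpha, T_window, n_steps = 2e5) {
  S <- length(N0)
  h <- T_window / n_steps
  N <- N0
  Fm <- matrix(0, S, S)
  r <- outer(alpha, alpha, "+") / 2
  for (s in seq_len(n_steps)) {
    dN <- -N * as.numeric(r %*% N)
    dF <- r * outer(N, N)
    diag(dF) <- diag(dF) / 2
    N <- N + h * dN
    Fm <- Fm + h * dF
  }
  list(N = N, F = Fm)
}

# Conservation defect of a fusion outcome: per-genotype cells at T plus
# cells bound in fused pairs must equal the initial count.
conservation_defect <- function(out, N0) {
  recon <- out$N + 2 * diag(out$F) + (rowSums(out$F) - diag(out$F))
  max(abs(recon - N0) / pmax(N0, 1))
}

random_population <- function(S, plastic = FALSE) {
  f <- runif(S)
  f <- f / sum(f)
  if (plastic) {
    population_state(m1 = runif(S, 0.2, 2), alpha1 = runif(S, 0, 0.5),
                     m2 = runif(S, 0.2, 2), alpha2 = runif(S, 0, 0.5),
                     f = f)
  } else {
    population_state(m = runif(S, 0.2, 2), alpha = runif(S, 0, 0.5), f = f)
  }
}
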