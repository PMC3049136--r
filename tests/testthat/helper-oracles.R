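# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation paths they check.

OM <- 1e-15 * 6.02214179e23 * 1e-6 # molecules per uM in 1 fL

# Dense CME right-hand side assembled state by state from the master equation
# terms (independent of the package's sparse triplet assembly).
dense_cme_matrix <- function(rates, A, MP, MPm, ks_mol) {
  ns <- (MP + 1) * (MPm + 1)
  idx <- function(n, m) m * (MP + 1) + n + 1
  G <- matrix(0, ns, ns)
  kc <- rates$kf + rates$ka * A
  for (n in 0:MP) {
    for (m in 0:MPm) {
      j <- idx(n, m)
      G[j, j] <- -(ks_mol + n * (rates$dP + kc) + m * (rates$kr + rates$dPm))
      if (n < MP) G[idx(n + 1, m), j] <- G[idx(n + 1, m), j] + ks_mol
      if (n > 0) G[idx(n - 1, m), j] <- G[idx(n - 1, m), j] + n * rates$dP
      if (n > 0 && m < MPm)
        G[idx(n - 1, m + 1), j] <- G[idx(n - 1, m + 1), j] + n * kc
      if (m > 0 && n < MP)
        G[idx(n + 1, m - 1), j] <- G[idx(n + 1, m - 1), j] + m * rates$kr
      if (m > 0) G[idx(n, m - 1), j] <- G[idx(n, m - 1), j] + m * rates$dPm
    }
  }
  G
}

# Explicit fixed-step Euler integration of dp/dt = G p.
euler_cme <- function(G, p0, t_end, dt) {
  p <- p0
  steps <- round(t_end / dt)
  for (s in seq_len(steps)) p <- p + dt * (G %*% p)
  as.numeric(p)
}

# Fixed-step explicit Euler for the deterministic two-state ODEs.
euler_ode <- function(rates, signal, init, t_end, dt) {
  x <- as.numeric(init[c("P", "Pm")])
  t <- signal$t_start[1]
  steps <- round((t_end - t) / dt)
  for (s in seq_len(steps)) {
    A <- signal_level(signal, t)
    k1 <- rates$kf + rates$ka * A
    dx <- c(rates$ks + rates$kr * x[2] - (rates$dP + k1) * x[1],
            k1 * x[1] - (rates$kr + rates$dPm) * x[2])
    x <- x + dt * dx
    t <- t + dt
  }
  x
}
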