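## Independent oracles, deliberately built on a different route than the
## package solver: the embedded jump chain and its fundamental matrix.

## all interior states of the trapezoid, in an arbitrary (m-major) order
oracle_states <- function(Ni, Nf) {
  st <- expand.grid(m = 1:(Nf - 1), n = 1:(Nf - 1))
  st[st$m + st$n >= Ni & st$m + st$n <= Nf, ]
}

## channel rates straight from their definitions (no reuse of package code)
oracle_rates <- function(m, n, Ni, Nf, cost, alpha = 1) {
  N <- m + n
  c(bS = (Nf - N) * alpha * n * m / N,
    bA = (Nf - N) * alpha * n * n / N,
    dS = (N - Ni) * alpha * m * m / N,
    dA = cost * (N - Ni) * alpha * m * n / N)
}

## absorbing-chain fixation probabilities via the fundamental matrix:
## pi = (I - Q)^{-1} R_A on the embedded jump chain
oracle_fixation_dense <- function(Ni, Nf, cost) {
  st <- oracle_states(Ni, Nf)
  K <- nrow(st)
  idx <- setNames(seq_len(K), paste(st$m, st$n))
  Q <- matrix(0, K, K)
  RA <- numeric(K)
  for (i in seq_len(K)) {
    m <- st$m[i]; n <- st$n[i]
    r <- oracle_rates(m, n, Ni, Nf, cost)
    tot <- sum(r)
    dest <- list(c(m + 1, n), c(m, n + 1), c(m - 1, n), c(m, n - 1))
    for (ch in 1:4) {
      if (r[ch] <= 0) next
      d <- dest[[ch]]
      p <- r[ch] / tot
      if (d[1] == 0) RA[i] <- RA[i] + p
      else if (d[2] == 0) NULL
      else Q[i, idx[paste(d[1], d[2])]] <- Q[i, idx[paste(d[1], d[2])]] + p
    }
  }
  st$pi <- as.numeric(solve(diag(K) - Q, RA))
  st
}
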