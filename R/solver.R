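#' Enumerate the interior states of the trapezoid
#'
#' Maps every interior state `(m, n)` (with `m >= 1`, `n >= 1`,
#' `Ni <= m + n <= Nf`) to a contiguous 1-based linear index `k` by scanning
#' the anti-diagonal lines `delta = m + n - Ni = 0, 1, ...` in order of
#' increasing `n` within each line:
#' \deqn{k(m, n) = \delta (N_i - 1) + \delta(\delta - 1)/2 + n.}
#' Line `delta` holds `Ni - 1 + delta` states, so consecutive lines occupy
#' consecutive index blocks and the map is a bijection onto
#' `1, ..., |interior|`.
#'
#' @param params A [model_params()] object.
#' @return A data frame with columns `k`, `m`, `n`, `delta`, ordered by `k`.
#' @examples
#' st <- enumerate_states(model_params(Ni = 5, Nf = 8))
#' st$k[st$m == 4 & st$n == 1]  # 1
#' @seealso [state_to_index()] for the closed-form index.
#' @export
enumerate_states <- function(params) {
  stopifnot(inherits(params, "model_params"))
  Ni <- params$Ni; Nf <- params$Nf
  delta <- rep.int(0:(Nf - Ni), Ni - 1 + (0:(Nf - Ni)))
  n <- sequence(Ni - 1 + (0:(Nf - Ni)))
  m <- Ni + delta - n
  data.frame(k = seq_along(n), m = m, n = n, delta = delta)
}

#' Linear index of an interior state
#'
#' Closed-form version of the anti-diagonal scan used by
#' [enumerate_states()]: `k = delta*(Ni-1) + delta*(delta-1)/2 + n` with
#' `delta = m + n - Ni`. Vectorized over `m`, `n`.
#'
#' @param m,n Interior state counts (`m >= 1`, `n >= 1`).
#' @param params A [model_params()] object; the state must satisfy
#'   `Ni <= m + n <= Nf`.
#' @return Integer index `k >= 1`.
#' @export
state_to_index <- function(m, n, params) {
  stopifnot(inherits(params, "model_params"))
  check_state(m, n, params, interior = TRUE)
  delta <- m + n - params$Ni
  as.integer(delta * (params$Ni - 1) + delta * (delta - 1) / 2 + n)
}

#' Assemble the backward Kolmogorov linear system
#'
#' For each interior state `k` the fixation probability of the altruist
#' allele satisfies `sum_q (pi_k - pi_q) W(k -> q) = 0`, the sum running
#' over the (at most four) nearest neighbors reachable through the birth
#' and death channels. Absorbing boundary conditions are folded into the
#' right-hand side: a neighbor on `m = 0` has `pi = 1` and contributes its
#' rate to `B`; a neighbor on `n = 0` has `pi = 0` and contributes nothing.
#' The result is a sparse matrix with the channel-rate sum on the diagonal
#' and at most four negative off-diagonals per row.
#'
#' Rows are scaled by their diagonal before the solve (pure
#' equilibration; it leaves the solution unchanged but keeps the residual
#' check meaningful across population sizes).
#'
#' @param params A [model_params()] object.
#' @return A list with elements `W` (sparse `dgCMatrix`, row-equilibrated),
#'   `B` (right-hand side), `states` (the [enumerate_states()] table), and
#'   `diag` (the unscaled diagonal, i.e. total exit rate per state).
#' @export
build_linear_system <- function(params) {
  st <- enumerate_states(params)
  K <- nrow(st)
  r <- transition_rates(st$m, st$n, params)

  ## destination of each channel; rates already vanish on the trapezoid rim
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  B <- numeric(K)
  dg <- r$birth_S + r$birth_A + r$death_S + r$death_A

  add_channel <- function(rate, m2, n2) {
    live <- rate > 0
    if (!any(live)) return(NULL)
    k <- st$k[live]; m2 <- m2[live]; n2 <- n2[live]; rate <- rate[live]
    to_A <- m2 == 0                      # absorbing: altruists fixed, pi = 1
    to_S <- n2 == 0                      # absorbing: altruists lost, pi = 0
    int <- !to_A & !to_S
    if (any(to_A)) B[k[to_A]] <<- B[k[to_A]] + rate[to_A]
    if (any(int)) {
      ii <<- c(ii, k[int])
      jj <<- c(jj, state_to_index(m2[int], n2[int], params))
      xx <<- c(xx, -rate[int])
    }
    NULL
  }
  add_channel(r$birth_S, st$m + 1, st$n)
  add_channel(r$birth_A, st$m, st$n + 1)
  add_channel(r$death_S, st$m - 1, st$n)
  add_channel(r$death_A, st$m, st$n - 1)

  ii <- c(ii, st$k); jj <- c(jj, st$k); xx <- c(xx, dg)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / dg[ii], dims = c(K, K))
  list(W = W, B = B / dg, states = st, diag = dg)
}

#' Exact fixation probabilities of the altruist allele
#'
#' Solves the backward Kolmogorov system of [build_linear_system()] by a
#' sparse direct solve, returning the fixation probability `pi(m, n)` of
#' the altruists from every interior state together with the two scalar
#' summaries: `pi_A = pi(m = Ni - 1, n = 1)`, the fixation probability of a
#' single altruist mutant in an all-selfish community at its carrying
#' capacity, and `pi_S = 1 - pi(m = 1, n = Nf - 1)`, the fixation
#' probability of a single selfish mutant among altruists.
#'
#' At `cost = 1` the altruist proportion is a martingale and
#' `pi(m, n) = n/(m + n)` exactly; the solver reproduces this to numerical
#' precision. Fixation probabilities are independent of `alpha`.
#'
#' @param params A [model_params()] object.
#' @param tol Residual tolerance (infinity norm of `W pi - B` on the
#'   equilibrated system). Default `1e-10`.
#' @return An object of class `fixation_table`: a list with `table` (data
#'   frame `k, m, n, delta, pi`), `pi_A`, `pi_S`, `residual`, `params`.
#' @examples
#' ft <- solve_fixation(model_params(Ni = 15, Nf = 20, cost = 1))
#' max(abs(ft$table$pi - ft$table$n / (ft$table$m + ft$table$n)))  # ~1e-16
#' @export
solve_fixation <- function(params, tol = 1e-10) {
  sys <- build_linear_system(params)
  pi_hat <- as.numeric(Matrix::solve(sys$W, sys$B))
  residual <- max(abs(as.numeric(sys$W %*% pi_hat) - sys$B))
  if (!is.finite(residual) || residual > tol) {
    stop(sprintf("sparse solve did not reach tolerance: residual = %.3e", residual))
  }
  st <- sys$states
  st$pi <- pi_hat
  pi_A <- st$pi[st$m == params$Ni - 1 & st$n == 1]
  pi_S <- 1 - st$pi[st$m == 1 & st$n == params$Nf - 1]
  structure(
    list(table = st, pi_A = pi_A, pi_S = pi_S,
         residual = residual, params = params),
    class = "fixation_table"
  )
}

#' @export
print.fixation_table <- function(x, ...) {
  p <- x$params
  cat("Fixation probabilities (altruist allele)\n")
  cat(sprintf("  Ni = %d, Nf = %d, cost = %.6g (Nf*s_bar = %.4g)\n",
              p$Ni, p$Nf, p$cost, p$Nf * p$s_bar))
  cat(sprintf("  interior states: %d   residual: %.2e\n",
              nrow(x$table), x$residual))
  cat(sprintf("  pi_A = %.6g   (single altruist among %d selfish)\n",
              x$pi_A, p$Ni - 1))
  cat(sprintf("  pi_S = %.6g   (single selfish among %d altruists)\n",
              x$pi_S, p$Nf - 1))
  invisible(x)
}

#' Fixation probabilities in the Moran limit
#'
#' Solves the one-dimensional birth-death chain defined by the two-step
#' Moran-limit rates of [moran_limit_rates()] (constant-rate variant,
#' `Nf = Ni + 1`) with absorbing ends `pi(0) = 0`, `pi(N) = 1`, using the
#' same backward-system formulation as the two-dimensional solver. Because
#' the chain's down/up bias is exactly `cost`, the result coincides with
#' the classical closed form `(1 - c^n)/(1 - c^N)` (see
#' [moran_fixation_exact()]), which makes this a cross-check between the
#' linear-solver route and the closed form.
#'
#' @param params A [model_params()] with `Nf == Ni + 1`; the chain lives on
#'   the lower line `m + n = Ni`.
#' @return A data frame with columns `n` (0 to `Ni`) and `pi`.
#' @export
solve_fixation_moran <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$Nf != params$Ni + 1) {
    stop("the Moran limit requires Nf = Ni + 1")
  }
  N <- params$Ni
  n <- 1:(N - 1)
  r <- moran_limit_rates(m = N - n, n = n, params)
  ## rows: (up + down) pi_n - up pi_{n+1} - down pi_{n-1} = [n = N-1] up
  dg <- r$rate_up + r$rate_down
  W <- Matrix::bandSparse(
    N - 1, N - 1, k = -1:1,
    diagonals = list(-r$rate_down[-1], dg, -r$rate_up[-(N - 1)])
  )
  B <- numeric(N - 1)
  B[N - 1] <- r$rate_up[N - 1]
  pi_int <- as.numeric(Matrix::solve(W, B))
  data.frame(n = 0:N, pi = c(0, pi_int, 1))
}
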