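#' Simulate one trajectory to fixation
#'
#' Runs the embedded jump chain of the four reaction channels from an
#' interior initial state until one type is lost (`n = 0`, selfish
#' fixation) or the other (`m = 0`, altruist fixation). Since only the
#' identity of each event matters for the fixation outcome, waiting times
#' are never sampled; the chain draws one uniform per event from R's RNG
#' stream, so runs are reproducible under [set.seed()].
#'
#' @param params A [model_params()] object.
#' @param m0,n0 Initial interior state (`m0 >= 1`, `n0 >= 1`,
#'   `Ni <= m0 + n0 <= Nf`).
#' @param max_events Guard against runaway loops; absorption is certain in
#'   finite time, so hitting the cap is an error, not a censoring.
#' @param keep_trajectory If `TRUE`, also return the full `(m, n)` path
#'   (one row per event, including the initial state).
#' @return A list with `outcome` (`"A_fixed"` or `"S_fixed"`), `n_events`,
#'   and, if requested, `trajectory` (data frame with columns `event`,
#'   `m`, `n`).
#' @examples
#' set.seed(1)
#' p <- model_params(Ni = 10, Nf = 15, cost = 1)
#' simulate_to_fixation(p, m0 = 9, n0 = 1)$outcome
#' @export
simulate_to_fixation <- function(params, m0, n0, max_events = 1e9,
                                 keep_trajectory = FALSE) {
  stopifnot(inherits(params, "model_params"))
  check_state(m0, n0, params, interior = TRUE)
  if (keep_trajectory) {
    res <- gillespie_trajectory_cpp(params$Ni, params$Nf, params$cost,
                                    m0, n0, max_events)
    list(outcome = if (res$outcome == 1L) "A_fixed" else "S_fixed",
         n_events = res$n_events,
         trajectory = data.frame(event = seq_along(res$m) - 1L,
                                 m = res$m, n = res$n))
  } else {
    res <- gillespie_batch_cpp(params$Ni, params$Nf, params$cost,
                               m0, n0, 1L, max_events)
    list(outcome = if (res$outcome[1] == 1L) "A_fixed" else "S_fixed",
         n_events = res$n_events[1])
  }
}

#' Monte-Carlo estimate of a fixation probability
#'
#' Generates `R` independent trajectories with [simulate_to_fixation()]'s
#' jump chain and estimates the altruist fixation probability from the
#' initial state as the fraction of runs ending in `m = 0`, with the
#' binomial standard error `sqrt(p_hat (1 - p_hat) / R)`. Given the same
#' `seed`, `R`, parameters and initial state the result is bit-identical
#' across runs (a single Mersenne-Twister stream seeded once, consumed one
#' uniform per event).
#'
#' @param params A [model_params()] object.
#' @param m0,n0 Initial interior state.
#' @param R Number of replicate trajectories (default `1e5`).
#' @param seed Integer seed. If `NULL`, the current RNG state is used and
#'   `seed` is recorded as `NA`.
#' @param max_events Per-trajectory event cap (error if hit).
#' @return An object of class `fixation_estimate`: a list with `p_hat`,
#'   `se`, `R`, `seed`, `mean_events`, `params`, `m0`, `n0`.
#' @examples
#' p <- model_params(Ni = 10, Nf = 15, cost = 1)
#' est <- estimate_fixation_prob(p, m0 = 9, n0 = 1, R = 1000, seed = 42)
#' est$p_hat  # close to the neutral value 0.1
#' @export
estimate_fixation_prob <- function(params, m0, n0, R = 1e5, seed = NULL,
                                   max_events = 1e9) {
  stopifnot(inherits(params, "model_params"))
  check_state(m0, n0, params, interior = TRUE)
  R <- as.integer(R)
  if (R < 1) stop("R must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  res <- gillespie_batch_cpp(params$Ni, params$Nf, params$cost,
                             m0, n0, R, max_events)
  p_hat <- mean(res$outcome)
  structure(
    list(p_hat = p_hat,
         se = sqrt(p_hat * (1 - p_hat) / R),
         R = R,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         mean_events = mean(res$n_events),
         params = params, m0 = m0, n0 = n0),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo fixation estimate from (m = %d, n = %d)\n",
              x$m0, x$n0))
  cat(sprintf("  p_hat = %.6g  (se = %.3g, R = %d, seed = %s)\n",
              x$p_hat, x$se, x$R, x$seed))
  cat(sprintf("  mean events to absorption: %.1f\n", x$mean_events))
  invisible(x)
}
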