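#' Parameters of a geographically structured (stepping-stone) population
#'
#' A one-dimensional chain of `M` colonies, each an instance of the base
#' model, exchanging migrants with nearest neighbours at per-capita rate
#' `m_mig`. The analysis is valid in the low-migration (viscous) regime,
#' where a migrant is either lost or fixed in its target colony before the
#' next migration event, so each colony is effectively monomorphic (all-A
#' at capacity `Nf` or all-S at capacity `Ni`) and the border between an
#' A-block and an S-block performs a biased random walk. No quantitative
#' threshold is enforced: the regime requires `m_mig` small compared to
#' the inverse fixation time, and the flag is advisory.
#'
#' @param M Number of colonies, `M >= 2`.
#' @param m_mig Per-capita migration rate (per unit time), `> 0`.
#' @param base A [model_params()] object describing each colony.
#' @return An object of class `structured_params`.
#' @export
structured_params <- function(M, m_mig, base) {
  stopifnot(inherits(base, "model_params"))
  if (length(M) != 1L || M < 2 || M != round(M)) {
    stop("M must be an integer >= 2")
  }
  if (length(m_mig) != 1L || !is.finite(m_mig) || m_mig <= 0) {
    stop("m_mig must be positive")
  }
  structure(list(M = as.integer(M), m_mig = m_mig, base = base),
            class = "structured_params")
}

#' @export
print.structured_params <- function(x, ...) {
  cat(sprintf("Stepping-stone chain: M = %d colonies, migration rate %.4g\n",
              x$M, x$m_mig))
  print(x$base)
  invisible(x)
}

#' Border conversion rates between monomorphic colonies
#'
#' At a border between an all-A colony (population `Nf`) and an all-S
#' colony (population `Ni`), the S colony converts to A at rate
#' `p_SA = m_mig * Nf * pi_A` (one of the `Nf` altruists emigrates and
#' fixes) and the A colony converts to S at rate
#' `p_AS = m_mig * Ni * pi_S`. The border therefore performs a biased
#' random walk with bias
#' \deqn{r = \frac{p_{AS}}{p_{SA}} = \frac{N_i \pi_S}{N_f \pi_A},}
#' independent of the migration rate. Whenever the single-colony criterion
#' for altruist advantage holds (`pi_A > pi_S`), `r < 1` and the A-domain
#' tends to expand.
#'
#' @param sp A [structured_params()] object.
#' @param pi_A,pi_S Single-mutant fixation probabilities of the base
#'   colony, typically from [solve_fixation()] (or their first-order
#'   approximations).
#' @return A list with `p_SA`, `p_AS`, `r`.
#' @export
border_rates <- function(sp, pi_A, pi_S) {
  stopifnot(inherits(sp, "structured_params"))
  if (pi_A <= 0 || pi_A > 1 || pi_S < 0 || pi_S > 1) {
    stop("pi_A must lie in (0, 1] and pi_S in [0, 1]")
  }
  p_SA <- sp$m_mig * sp$base$Nf * pi_A
  p_AS <- sp$m_mig * sp$base$Ni * pi_S
  list(p_SA = p_SA, p_AS = p_AS, r = p_AS / p_SA)
}

## gambler's-ruin factor (1 - r) / (1 - r^(M-1)), with the r -> 1 limit
## and expm1-based evaluation so that r far from 1 stays accurate for
## large M (r^(M-1) under- or overflows harmlessly inside expm1).
ruin_factor <- function(r, M) {
  if (r <= 0) stop("r must be positive")
  if (abs(r - 1) < 1e-8) return(1 / (M - 1))
  num <- -expm1(log(r))            # 1 - r
  den <- -expm1((M - 1) * log(r))  # 1 - r^(M-1)
  if (is.infinite(den)) return(0)
  num / den
}

#' Global fixation probability of an altruist mutant
#'
#' Probability that a single altruist mutant takes over the entire
#' stepping-stone community: it must first fix in its own colony
#' (probability `pi_A`) and that colony must then absorb the whole chain
#' via the biased border walk (a gambler's ruin with bias `r`):
#' \deqn{\Pi_A = \pi_A \frac{1 - r}{1 - r^{M-1}},}
#' with the limit `pi_A / (M - 1)` at `r = 1`. For `r < 1` and many
#' colonies this tends to `pi_A (1 - r) = pi_A - (Ni/Nf) pi_S > 0`:
#' structuring does not destroy the altruist advantage.
#'
#' @inheritParams border_rates
#' @return A list with `Pi_A` (or `Pi_S`), `r`, `M`, and `limit_inf`, the
#'   `M -> Inf` limit.
#' @examples
#' p <- model_params(Ni = 90, Nf = 100, cost = 1.0005)
#' ft <- solve_fixation(p)
#' sp <- structured_params(M = 20, m_mig = 1e-4, base = p)
#' global_fixation_A(sp, ft$pi_A, ft$pi_S)$Pi_A
#' @export
global_fixation_A <- function(sp, pi_A, pi_S) {
  stopifnot(inherits(sp, "structured_params"))
  r <- border_rates(sp, pi_A, pi_S)$r
  list(Pi_A = pi_A * ruin_factor(r, sp$M),
       r = r, M = sp$M,
       limit_inf = if (r < 1) pi_A * (1 - r) else 0)
}

#' @rdname global_fixation_A
#'
#' @details
#' The selfish mutant faces the mirrored walk with bias `1/r`:
#' \deqn{\Pi_S = \pi_S \frac{1 - 1/r}{1 - (1/r)^{M-1}},}
#' again with limit `pi_S / (M - 1)` at `r = 1`. When the altruists hold
#' the advantage (`r < 1`), `Pi_S` decreases geometrically with `M` and
#' vanishes as `M -> Inf`: once altruists dominate a large viscous
#' community, selfish invaders are essentially shut out.
#' @export
global_fixation_S <- function(sp, pi_A, pi_S) {
  stopifnot(inherits(sp, "structured_params"))
  r <- border_rates(sp, pi_A, pi_S)$r
  list(Pi_S = pi_S * ruin_factor(1 / r, sp$M),
       r = r, M = sp$M,
       limit_inf = if (r > 1) pi_S * (1 - 1 / r) else 0)
}

#' Structured-population summary
#'
#' Convenience wrapper: solves the base colony exactly with
#' [solve_fixation()], forms the border bias and both global fixation
#' probabilities.
#'
#' @param sp A [structured_params()] object.
#' @return A list with `pi_A`, `pi_S`, `r`, `Pi_A`, `Pi_S`, `Pi_A_inf`,
#'   `Pi_S_inf`, `M`, `m_mig`.
#' @export
structured_fixation <- function(sp) {
  stopifnot(inherits(sp, "structured_params"))
  ft <- solve_fixation(sp$base)
  a <- global_fixation_A(sp, ft$pi_A, ft$pi_S)
  s <- global_fixation_S(sp, ft$pi_A, ft$pi_S)
  list(pi_A = ft$pi_A, pi_S = ft$pi_S, r = a$r,
       Pi_A = a$Pi_A, Pi_S = s$Pi_S,
       Pi_A_inf = a$limit_inf, Pi_S_inf = s$limit_inf,
       M = sp$M, m_mig = sp$m_mig)
}
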