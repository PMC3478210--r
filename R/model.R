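#' Model parameters for the variable-carrying-capacity birth-death model
#'
#' Bundles the scalars defining one model instance: the two bounds of the
#' carrying capacity, the cost of altruism, and the overall event rate.
#' The habitat supports `Ni` individuals when only selfish (S) individuals
#' are present and `Nf > Ni` when only altruists (A) are present; in between,
#' the total population performs a random walk on the trapezoid
#' `Ni <= m + n <= Nf` of (selfish, altruist) counts `(m, n)`.
#'
#' The cost enters through the death channel: `1/cost` is the relative
#' fitness of an altruist, so `cost > 1` means altruists are selected
#' against. Two derived quantities are stored: `k = Ni/Nf`, the relative
#' floor of the carrying capacity, and the selection coefficient
#' `s_bar = cost - 1`.
#'
#' @param Ni Integer, minimum carrying capacity (all-selfish population size),
#'   `Ni >= 2`.
#' @param Nf Integer, maximum carrying capacity (all-altruist population
#'   size), `Nf > Ni`.
#' @param cost Positive numeric, cost factor of altruism (`cost > 1`:
#'   altruists pay a fitness cost). Default 1 (neutral).
#' @param alpha Positive numeric, event rate scale per unit time. Fixation
#'   probabilities do not depend on `alpha`; it only sets the clock.
#'
#' @return An object of class `model_params`: a list with elements `Ni`,
#'   `Nf`, `cost`, `alpha`, `k`, `s_bar`.
#' @examples
#' p <- model_params(Ni = 90, Nf = 100, cost = 1.001)
#' p$s_bar        # 0.001
#' p$k            # 0.9
#' @export
model_params <- function(Ni, Nf, cost = 1, alpha = 1) {
  if (length(Ni) != 1L || length(Nf) != 1L || length(cost) != 1L ||
      length(alpha) != 1L) {
    stop("all parameters must be scalars")
  }
  Ni <- as.numeric(Ni)
  Nf <- as.numeric(Nf)
  if (Ni != round(Ni) || Nf != round(Nf)) stop("Ni and Nf must be integers")
  if (Ni < 2) stop("Ni must be at least 2")
  if (Nf <= Ni) stop("Nf must exceed Ni (the model needs a nonempty trapezoid)")
  if (!is.finite(cost) || cost <= 0) stop("cost must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  structure(
    list(Ni = Ni, Nf = Nf, cost = cost, alpha = alpha,
         k = Ni / Nf, s_bar = cost - 1),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Variable-carrying-capacity model\n")
  cat(sprintf("  Ni = %d, Nf = %d  (k = %.4g)\n", x$Ni, x$Nf, x$k))
  cat(sprintf("  cost = %.6g  (s_bar = %.6g, Nf*s_bar = %.6g)\n",
              x$cost, x$s_bar, x$Nf * x$s_bar))
  cat(sprintf("  alpha = %.6g\n", x$alpha))
  invisible(x)
}

## shared state validation; vectorized over m, n
check_state <- function(m, n, params, interior = FALSE) {
  if (any(m < 0) || any(n < 0)) stop("m and n must be non-negative")
  if (any(m != round(m)) || any(n != round(n))) stop("m and n must be integers")
  N <- m + n
  if (any(N == 0)) stop("the empty population (m = n = 0) is not a valid state")
  if (any(N < params$Ni) || any(N > params$Nf)) {
    stop(sprintf("state outside the trapezoid: need %d <= m + n <= %d",
                 params$Ni, params$Nf))
  }
  if (interior && (any(m == 0) || any(n == 0))) {
    stop("absorbing state: an interior state needs m >= 1 and n >= 1")
  }
  invisible(TRUE)
}

#' Transition rates of the four reaction channels
#'
#' At state `(m, n)` (selfish and altruist counts, total `N = m + n`) the
#' model has two birth channels and two death channels. Empty spots are
#' created at rate `alpha * n * (Nf - N)` (the common good is produced by
#' altruists) and colonized by an S or an A in proportion to their share of
#' the population; deaths occur at rate `alpha * m * (N - Ni)` (the crowding
#' pressure comes from selfish individuals) and hit an S or an A in
#' proportion to their share, except that the altruist death channel carries
#' the extra cost factor:
#' \deqn{W_{birth,S} = (N_f - N)\,\alpha n\, m/N, \quad
#'       W_{birth,A} = (N_f - N)\,\alpha n\, n/N,}
#' \deqn{W_{death,S} = (N - N_i)\,\alpha m\, m/N, \quad
#'       W_{death,A} = c\,(N - N_i)\,\alpha m\, n/N.}
#' Given that a death occurs, the probability that it removes an altruist is
#' therefore `c*n/(m + c*n)`, larger than the neutral share `n/N` when
#' `c > 1` (see [conditional_death_prob_A()]).
#'
#' Birth rates vanish at the ceiling `N = Nf` and when `n = 0`; death rates
#' vanish at the floor `N = Ni` and when `m = 0`. The boundaries `n = 0`
#' (selfish fixation) and `m = 0` (altruist fixation) are absorbing.
#'
#' @param m,n Non-negative integer counts of selfish and altruist
#'   individuals (vectorized); `Ni <= m + n <= Nf` and `m + n > 0`.
#' @param params A [model_params()] object.
#' @return A data frame with one row per state and columns `birth_S`,
#'   `birth_A`, `death_S`, `death_A` (rates per unit time).
#' @examples
#' p <- model_params(Ni = 2, Nf = 4, cost = 1)
#' transition_rates(m = 1, n = 2, p)   # 2/3, 4/3, 1/3, 2/3
#' @export
transition_rates <- function(m, n, params) {
  stopifnot(inherits(params, "model_params"))
  check_state(m, n, params)
  N <- m + n
  a <- params$alpha
  data.frame(
    birth_S = (params$Nf - N) * a * n * m / N,
    birth_A = (params$Nf - N) * a * n * n / N,
    death_S = (N - params$Ni) * a * m * m / N,
    death_A = params$cost * (N - params$Ni) * a * m * n / N
  )
}

#' Conditional probability that a death removes an altruist
#'
#' Given that a death event occurs at state `(m, n)`, the victim is an
#' altruist with probability `c*n / (m + c*n)`. At `cost = 1` this is the
#' neutral share `n/(m+n)`; for `cost > 1` altruists are over-represented
#' among deaths, which is how the fitness cost enters the model.
#'
#' @param m,n Non-negative counts with `m + n > 0` (vectorized).
#' @param cost Positive cost factor.
#' @return Probability in `[0, 1]`.
#' @examples
#' conditional_death_prob_A(1, 1, cost = 2)   # 2/3
#' @export
conditional_death_prob_A <- function(m, n, cost) {
  if (any(m < 0) || any(n < 0)) stop("m and n must be non-negative")
  if (any(m + n == 0)) stop("m + n must be positive")
  if (any(cost <= 0)) stop("cost must be positive")
  cost * n / (m + cost * n)
}

#' Two-step Moran-limit transition rates
#'
#' In the constant-rate variant of the model (a constant `alpha` replaces
#' `alpha*n` and `alpha*m` in all four channels) with `Nf = Ni + 1`, the
#' population alternates between the two anti-diagonals `N = Ni` and
#' `N = Nf`: every birth is followed by a death and vice versa. Composing
#' the two elementary rates yields the effective one-dimensional chain in
#' the altruist count `n`:
#' \deqn{W^M(n \to n+1) = \alpha^2 m n / (N_i N_f), \qquad
#'       W^M(n \to n-1) = c\,\alpha^2 m n / (N_i N_f),}
#' whose bias `rate_down/rate_up = c` is exactly the classical Moran
#' death-birth bias. The same products are obtained whether the two-step
#' cycle starts from the lower or the upper line.
#'
#' @param m,n Non-negative counts (vectorized); `m + n` must equal `Ni` or
#'   `Nf`.
#' @param params A [model_params()] with `Nf == Ni + 1`.
#' @return A data frame with columns `rate_up` (`n -> n+1, m -> m-1`) and
#'   `rate_down` (`n -> n-1, m -> m+1`). Both vanish at the absorbing
#'   states `m = 0` and `n = 0`.
#' @examples
#' p <- model_params(Ni = 10, Nf = 11, cost = 1.5)
#' r <- moran_limit_rates(m = 4, n = 6, p)
#' r$rate_down / r$rate_up   # exactly 1.5
#' @export
moran_limit_rates <- function(m, n, params) {
  stopifnot(inherits(params, "model_params"))
  if (params$Nf != params$Ni + 1) {
    stop("the Moran limit requires Nf = Ni + 1")
  }
  check_state(m, n, params)
  base <- params$alpha^2 * m * n / (params$Ni * params$Nf)
  data.frame(rate_up = base, rate_down = params$cost * base)
}

#' Classify a population state
#'
#' @param m,n Non-negative counts (vectorized), not both zero.
#' @return Character vector: `"A_fixed"` when the selfish type is lost
#'   (`m = 0`), `"S_fixed"` when the altruists are lost (`n = 0`),
#'   `"interior"` otherwise.
#' @examples
#' classify_state(0, 100)  # "A_fixed"
#' classify_state(50, 3)   # "interior"
#' @export
classify_state <- function(m, n) {
  if (any(m < 0) || any(n < 0)) stop("m and n must be non-negative")
  if (any(m + n == 0)) stop("the empty population (m = n = 0) is unreachable")
  ifelse(m == 0, "A_fixed", ifelse(n == 0, "S_fixed", "interior"))
}

#' Read model parameters from a plain-text config file
#'
#' Parses a `key = value` file (one pair per line, `#` comments allowed)
#' with keys `Ni`, `Nf`, `cost` (alias `c`), `alpha`.
#'
#' @param path Path to the config file.
#' @return A [model_params()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- ifelse(keys == "c", "cost", keys)
  known <- c("Ni", "Nf", "cost", "alpha")
  if (!all(names(vals) %in% known)) {
    stop("unknown config key: ", setdiff(names(vals), known)[1])
  }
  args <- as.list(vals)
  do.call(model_params, args)
}
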