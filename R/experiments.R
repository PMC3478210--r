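#' Sweep of selection pressure: exact versus analytic fixation probabilities
#'
#' For each selection pressure `Nf * s_bar` in the grid, solves the model
#' exactly with [solve_fixation()] and evaluates the first-order
#' perturbation solution [perturbation_pi()] at every interior state,
#' recording the deviation between the two. The default grid spans the
#' weak-to-moderate selection regime on a `Nf = 100`, `Ni = 90` habitat.
#'
#' @param Ni,Nf Carrying-capacity bounds.
#' @param Ns_grid Selection pressures `Nf * s_bar` to scan.
#' @return A data frame with one row per (pressure, interior state):
#'   columns `Nf_s_bar`, `s_bar`, `m`, `n`, `mu`, `eta`, `pi_exact`,
#'   `pi_analytic`, `abs_dev`; the per-pressure maxima are attached as
#'   attribute `deviations` (data frame `Nf_s_bar`, `max_abs_dev`).
#' @examples
#' \donttest{
#' sw <- sweep_selection_pressure(Ns_grid = c(0.1, 0.5))
#' attr(sw, "deviations")
#' }
#' @export
sweep_selection_pressure <- function(Ni = 90, Nf = 100,
                                     Ns_grid = c(0.02, 0.05, 0.1, 0.2,
                                                 0.5, 1, 2)) {
  if (length(Ns_grid) == 0) stop("Ns_grid must be non-empty")
  rows <- lapply(Ns_grid, function(Ns) {
    params <- model_params(Ni, Nf, cost = 1 + Ns / Nf)
    ft <- solve_fixation(params)
    tb <- ft$table
    mu <- tb$n / (tb$m + tb$n)
    eta <- (tb$m + tb$n) / Nf
    pa <- perturbation_pi(mu, eta, params)
    data.frame(Nf_s_bar = Ns, s_bar = params$s_bar,
               m = tb$m, n = tb$n, mu = mu, eta = eta,
               pi_exact = tb$pi, pi_analytic = pa,
               abs_dev = abs(tb$pi - pa))
  })
  out <- do.call(rbind, rows)
  dev <- data.frame(
    Nf_s_bar = Ns_grid,
    max_abs_dev = vapply(rows, function(d) max(d$abs_dev), 0)
  )
  attr(out, "deviations") <- dev
  out
}

#' Locate the crossing of the two single-mutant fixation probabilities
#'
#' Finds, by bisection on the exact solver, the selection coefficient
#' `s_bar^*` at which a single altruist and a single selfish mutant have
#' equal fixation probabilities (`pi_A = pi_S`). At `s_bar = 0`,
#' `pi_A = 1/Ni > 1/Nf = pi_S`, and `pi_A - pi_S` decreases with `s_bar`,
#' so the crossing is unique; the initial bracket
#' `[0, 4 * DeltaN / N_bar^2]` is widened automatically if needed.
#'
#' @param Ni,Nf Carrying-capacity bounds.
#' @param tol Bisection tolerance on `s_bar` (default `1e-7`).
#' @return The crossing `s_bar_star`.
#' @export
locate_crossing <- function(Ni, Nf, tol = 1e-7) {
  gap <- function(sb) {
    ft <- solve_fixation(model_params(Ni, Nf, cost = 1 + sb))
    ft$pi_A - ft$pi_S
  }
  lo <- 0
  hi <- 4 * equilibrium_selection(Ni, Nf)$s_bar_star
  g_hi <- gap(hi)
  tries <- 0
  while (g_hi > 0) {
    hi <- 2 * hi
    g_hi <- gap(hi)
    tries <- tries + 1
    if (tries > 20) stop(sprintf("no sign change found for Ni=%d, Nf=%d", Ni, Nf))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Scan the altruist-advantage criterion across habitat geometries
#'
#' For each `(Ni, Nf)` pair, locates the equilibrium selection coefficient
#' numerically with [locate_crossing()] and tabulates the scaled crossing
#' `N_bar * s_bar^*` against the leading-order prediction
#' `DeltaN / N_bar` of [equilibrium_selection()]. The default grid scans
#' `Nf = 100` with `Ni` from 85 to 97 and `Nf = 150` with `Ni` from 130
#' to 148.
#'
#' @param pairs A two-column matrix or data frame of `(Ni, Nf)` pairs.
#' @param tol Bisection tolerance passed to [locate_crossing()].
#' @return A data frame with columns `Ni`, `Nf`, `delta_N`, `N_bar`,
#'   `rel_increase` (`= delta_N / N_bar`), `s_bar_star` (numerical),
#'   `Ns_star` (`= N_bar * s_bar_star`), `Ns_star_theory`
#'   (`= delta_N / N_bar`), `scaled_gap`
#'   (`= N_bar * (Ns_star - Ns_star_theory)`).
#' @examples
#' \donttest{
#' scan_crossing(pairs = cbind(Ni = c(90, 95), Nf = 100))
#' }
#' @export
scan_crossing <- function(pairs = default_crossing_grid(), tol = 1e-7) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("Ni", "Nf")
  if (nrow(pairs) == 0) stop("pairs must be non-empty")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    Ni <- pairs$Ni[i]; Nf <- pairs$Nf[i]
    eq <- equilibrium_selection(Ni, Nf)
    sb <- locate_crossing(Ni, Nf, tol = tol)
    data.frame(Ni = Ni, Nf = Nf,
               delta_N = eq$delta_N, N_bar = eq$N_bar,
               rel_increase = eq$Ns_star,
               s_bar_star = sb,
               Ns_star = eq$N_bar * sb,
               Ns_star_theory = eq$Ns_star,
               scaled_gap = eq$N_bar * (eq$N_bar * sb - eq$Ns_star))
  })
  do.call(rbind, res)
}

#' @rdname scan_crossing
#' @export
default_crossing_grid <- function() {
  rbind(
    data.frame(Ni = c(85, 87, 90, 93, 95, 97), Nf = 100),
    data.frame(Ni = c(130, 136, 142, 148), Nf = 150)
  )
}
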