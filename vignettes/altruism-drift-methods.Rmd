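---
title: "Methods: drift-driven selection for altruism under a variable carrying capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift-driven selection for altruism under a variable carrying capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altdrift)
```

## The model

Two haploid types compete in a well-mixed habitat: altruists (A), who
produce a common good that enlarges the habitat's carrying capacity, and
selfish individuals (S), who consume the common good without paying for
it. The state is the pair of counts $(m, n)$ of S and A individuals. The
carrying capacity interpolates between $N_i$ (all-selfish) and
$N_f > N_i$ (all-altruist), and the total $N = m + n$ performs a random
walk on the trapezoid $N_i \le N \le N_f$.

Four reaction channels drive the dynamics. Empty spots are created at
rate $\alpha n (N_f - N)$ — the common good is produced by altruists —
and are colonized by an S or an A in proportion to their current shares
$m/N$ and $n/N$. Deaths occur at rate $\alpha m (N - N_i)$ — the
crowding pressure is exerted by selfish individuals — and strike an S or
an A in proportion to their shares, except that the altruist death
channel carries the cost factor $c$:

$$W_{b,S} = (N_f - N)\,\alpha n\,\frac{m}{N}, \quad
  W_{b,A} = (N_f - N)\,\alpha n\,\frac{n}{N}, \quad
  W_{d,S} = (N - N_i)\,\alpha m\,\frac{m}{N}, \quad
  W_{d,A} = c\,(N - N_i)\,\alpha m\,\frac{n}{N}.$$

Given that a death occurs, the victim is an altruist with probability
$cn/(m + cn) > n/N$ when $c > 1$: $1/c$ is the relative fitness of an
altruist, and $\bar{s} = c - 1$ its selection coefficient. The
boundaries $n = 0$ and $m = 0$ are absorbing; once altruists are lost
the population settles at $N_i$, once the selfish are lost it settles at
$N_f$.

Two properties anchor everything else:

* **$\alpha$-invariance.** All four channels scale linearly in
  $\alpha$, so the embedded jump chain — and with it every fixation
  probability — is independent of $\alpha$. The rate scale only matters
  for (unimplemented) fixation times, which is why `alpha = 1` is the
  default. For the same reason the per-event normalization $1/N$ in the
  rates is immaterial for fixation probabilities: dividing all four
  channels at a state by the same factor re-times the clock without
  touching the jump chain.
* **Neutral martingale.** At $c = 1$ the altruist proportion
  $n/(m+n)$ is an exact martingale of the chain (the birth and death
  contributions to its expected increment cancel state by state), so
  $\pi(m, n) = n/(m+n)$ exactly. This supplies a machine-precision
  oracle for the solver and the simulator.

The interesting regime is $c > 1$: the altruist is *always* locally
disfavoured, yet a single altruist mutant (state $(N_i - 1, 1)$, neutral
fixation probability $1/N_i$) starts in a *smaller* population than a
single selfish mutant (state $(1, N_f - 1)$, neutral value $1/N_f$).
Genetic drift is stronger at $N_i$ than at $N_f$, and for small enough
cost this demographic asymmetry outweighs the fitness deficit:
$\pi_A > \pi_S$.

## Exact solver

The fixation probability of the altruist allele satisfies the backward
Kolmogorov equations $\sum_q (\pi_k - \pi_q) W(k \to q) = 0$ over the
interior states ($m, n \ge 1$), with $\pi = 1$ on $m = 0$ and $\pi = 0$
on $n = 0$. `enumerate_states()` linearizes the two-dimensional interior
by scanning anti-diagonals $\delta = N - N_i = 0, 1, \dots$, giving the
closed-form index $k = \delta(N_i - 1) + \delta(\delta - 1)/2 + n$; the
resulting matrix has the total exit rate on the diagonal and at most
four off-diagonal entries per row. Boundary neighbours on $m = 0$
contribute their rate to the right-hand side; those on $n = 0$
contribute nothing.

Numerical choices:

* rows are divided by their diagonal before the solve (pure
  equilibration). Raw rates grow like $N_f^2 \alpha$, so an absolute
  residual threshold on the unscaled system would conflate problem
  scale with solver quality; on the equilibrated system the residual
  $\|W\pi - B\|_\infty$ is required to be $\le 10^{-10}$ and is
  reported in the result. In practice a sparse LU (`Matrix::solve`)
  reaches $10^{-14}$ or better for every size used here
  (up to $N_f = 150$, about 3&nbsp;000 unknowns).
* states outside the trapezoid are rejected, not clamped: they are
  unreachable from valid initial conditions, and silently accepting
  them would mask indexing bugs.
* `solve_fixation_moran()` handles the classical fixed-size limit: in
  the constant-rate variant of the model (a constant $\alpha$ replaces
  $\alpha n$ and $\alpha m$) with $N_f = N_i + 1$, every birth is
  followed by a death and the two-step rate products define a
  one-dimensional chain with up/down bias exactly $c$
  (`moran_limit_rates()`). Solving that chain with the same
  backward-system machinery reproduces $(1 - c^n)/(1 - c^N)$ to solver
  precision. We deliberately build the limit from the two-step rates:
  the full two-dimensional constant-rate chain differs from the
  classical formula at $O(1/N)$ (the death probabilities are
  normalized at the post-birth composition), an effect the two-step
  composition removes.

The test suite cross-checks the sparse route against an independent
dense computation (fundamental matrix of the embedded jump chain,
$\pi = (I - Q)^{-1}R_A$) for every habitat with $N_f \le 12$, at
$10^{-10}$.

## Stochastic simulation

`simulate_to_fixation()` runs the embedded jump chain: at each step the
next event is drawn with probability proportional to the four channel
rates, with no waiting-time sampling — only the fixation outcome is of
interest, and the jump chain determines it. The inner loop is compiled
(Rcpp) and consumes one uniform per event from R's Mersenne-Twister
stream, so `estimate_fixation_prob(..., seed = )` is bit-reproducible:
a single `set.seed()` precedes the replicate loop, which makes the
estimate deterministic in (seed, R, parameters, initial state). We use
one stream rather than per-replicate substreams; replicates are
consumed sequentially from it, which is equally deterministic and
simpler to audit.

Defaults: $R = 10^5$ replicates (binomial standard error
$\approx 1.5\times10^{-4}$ on probabilities of order $10^{-2}$,
adequate to resolve the $\pi_A$–$\pi_S$ gap at the habitats used here;
larger $R$ is a parameter away), and an event cap of $10^9$ per
trajectory. Absorption is certain in finite time, so the cap exists
only to turn a hypothetical bug into an error instead of a hang; at the
test sizes ($N_f \le 50$) trajectories absorb in a few hundred events.

Monte-Carlo agreement with the exact solver is asserted at $3\,\mathrm{SE}$
with pinned seeds; across the handful of such assertions a rare
$>3\sigma$ excursion under a different seed would be expected and is not
evidence of a defect.

## Analytic approximations

In the diffusion limit ($N_f \gg 1$, weak selection) write
$\mu = n/N$ for the altruist proportion and $\eta = N/N_f$ for the
relative population. The neutral solution is $\pi = \mu$; expanding to
first order in $\bar{s}$ around it yields the closed form implemented
in `perturbation_pi()`:

$$\pi(\mu, \eta) =
  \frac{e^{N_f\bar{s}\mu\,g(\eta)} - 1}{e^{N_f\bar{s}\,g(\eta)} - 1},
  \qquad
  g(\eta) = \gamma\left(1 - \frac{1}{N_f\,\eta}\right), \qquad
  \gamma = \frac{1}{N_f} + \frac{1 + k}{2},$$

with $k = N_i/N_f$. The functional form of $g$ was fixed by a
three-way validation rather than taken on faith: (i) expanding the
exponential ansatz to first order and matching the single-mutant
corners reproduces the expansions below exactly; (ii) at $k \to 1$
(fixed population size) $g \to 1$ and the expression collapses to the
Kimura diffusion formula $\big(e^{-N\mu s}-1\big)/\big(e^{-Ns}-1\big)$
with $c = 1/(1+s)$; (iii) against the exact solver on the
$N_f = 100$, $N_i = 90$ habitat the maximum absolute deviation over
*all* interior states grows from $2\times10^{-5}$ at
$N_f\bar{s} = 0.02$ to $1.6\times10^{-3}$ at $N_f\bar{s} = 2$ — an
order of magnitude inside the acceptance bands (0.02 weak, 0.05 at
$N_f\bar{s}=2$) used by the test suite. Rejected candidate forms
containing $(1/\eta)^{N_f}$ either vanish at $\eta = 1$ (contradicting
the non-zero first-order correction for a selfish mutant) or blow up
exponentially.

First-order single-mutant expansions (`pi_A_first_order()`,
`pi_S_first_order()`), obtained by evaluating the solution at
$(\mu, \eta) = (1/N_i,\, k)$ and $((N_f-1)/N_f,\, 1)$:

$$\pi_A = \frac{1}{N_i} - \frac{\gamma}{2}\frac{(N_i-1)^2 N_f}{N_i^3}\bar{s},
  \qquad
  \pi_S = \frac{1}{N_f} + \frac{\gamma}{2}\frac{(N_f-1)^2}{N_f^2}\bar{s}.$$

Note the signs: cost hurts the altruist invader and *helps* the selfish
invader. Setting $\pi_A = \pi_S$ and keeping leading terms gives the
selection criterion of `equilibrium_selection()`:

$$\bar{N}\bar{s}^* = \frac{\Delta N}{\bar{N}}, \qquad
  \Delta N = N_f - N_i,\quad \bar{N} = \frac{N_f + N_i}{2}:$$

altruists are favoured while the population-scaled cost stays below the
relative capacity increase they provide. `locate_crossing()` finds the
true crossing by bisection on the exact solver (tolerance
$10^{-7}$ on $\bar{s}$, bracket $[0, 4\Delta N/\bar{N}^2]$ widened
adaptively); across the default grid ($N_f = 100$,
$N_i \in \{85,\dots,97\}$; $N_f = 150$, $N_i \in \{130,\dots,148\}$)
the scaled gap $\bar{N}\,|\bar{N}\bar{s}^* - \Delta N/\bar{N}|$ stays
below $0.14$, comfortably a leading-order agreement.

Singular limits ($c = 1$, $s = 0$) are explicit branches returning the
neutral value, not small-$\epsilon$ workarounds, and the exponential
ratios are evaluated with `expm1` so the formulas remain accurate
arbitrarily close to neutrality.

## Mean field

Neglecting fluctuations and rescaling time by $N_f^2\alpha$:

$$\frac{d\mu}{d\tau} = -(c-1)\,\eta(\eta-k)\,\mu(1-\mu)^2, \qquad
  \frac{d\eta}{d\tau} = \eta^2\big[(1-k)\mu + k - \eta
    - (c-1)(\eta-k)\mu(1-\mu)\big].$$

For $c > 1$, $d\mu/d\tau \le 0$ everywhere: deterministically the
altruists always die out, and $(\eta, \mu) = (k, 0)$ is the only stable
fixed point. The altruist advantage computed by the rest of the package
is thus invisible at mean-field level — it is a finite-size, purely
stochastic effect. The late-time approach to extinction is algebraic
($\mu \sim 1/[(c-1)k(1-k)\tau]$), which is why the convergence test
integrates to $\tau = 5\times10^5$ at $c - 1 = 10^{-2}$.

With $\mu$ pinned, the quasi-stationary population size to first order
in $c - 1$ is

$$\eta^*(\mu) = k + (1-k)\mu - (c-1)(1-k)\mu^2(1-\mu),$$

implemented in `stationary_eta()`. The first-order coefficient follows
directly from setting the bracket in $d\eta/d\tau$ to zero, and was
confirmed against direct integration of the pinned ODE: the residual
shrinks fourfold when $c - 1$ is halved, i.e. the expression is
accurate to $O((c-1)^2)$. A candidate variant carrying an extra
$1/(k + (1-k)\mu)^2$ factor on the correction term fails this test
(residual shrinks only linearly) and was discarded.

Integration uses `deSolve::ode` (lsoda, `rtol = 1e-10`,
`atol = 1e-12`); a failed integrator status is raised as an error
rather than returned.

## Structured populations

`structured_params()` describes a one-dimensional chain of $M$ colonies
exchanging migrants with nearest neighbours at per-capita rate
$m_{mig}$, in the *low-migration (viscous) limit*: a migrant fixes or is
lost before the next migration event, so colonies are monomorphic —
all-A at size $N_f$ or all-S at size $N_i$ — and only the border between
blocks moves. The border converts an S colony at rate
$p_{SA} = m_{mig} N_f \pi_A$ (one of $N_f$ altruists emigrates, then
fixes) and an A colony at rate $p_{AS} = m_{mig} N_i \pi_S$; the rates
are read as products (migration rate × source-colony size × fixation
probability), which is the unique reading under which the large-$M$
limit below is an algebraic identity. The border walk bias

$$r = \frac{p_{AS}}{p_{SA}} = \frac{N_i\,\pi_S}{N_f\,\pi_A}$$

is independent of the migration rate, and $r < 1$ exactly when the
single-colony criterion favours altruists. Global fixation follows a
gambler's ruin over the $M - 1$ border positions:

$$\Pi_A = \pi_A\,\frac{1 - r}{1 - r^{M-1}}, \qquad
  \Pi_S = \pi_S\,\frac{1 - 1/r}{1 - (1/r)^{M-1}},$$

with limits $\pi_A/(M-1)$, $\pi_S/(M-1)$ at $r = 1$ (taken explicitly
within $|r - 1| < 10^{-8}$) and `expm1`-based evaluation elsewhere, so
$r$ far from 1 with large $M$ neither under- nor overflows. At $M = 2$
both reduce exactly to the single-colony values. For $r < 1$,
$\Pi_A \to \pi_A(1 - r) = \pi_A - (N_i/N_f)\pi_S > 0$ while
$\Pi_S \to 0$ geometrically: structuring amplifies the altruist
advantage until selfish invasion becomes essentially impossible.

The low-migration validity condition is advisory and reported, not
enforced: no quantitative threshold is imposed, and the formulas are
exact only in the $m_{mig} \to 0$ limit. The package does not simulate
the metapopulation stochastically, treat intermediate migration rates,
or handle geometries other than the nearest-neighbour chain.

## Default study conditions and problem sizes

The packaged sweeps use the habitat $N_f = 100$, $N_i = 90$ with
selection pressures $N_f\bar{s} \in \{0.02, 0.05, 0.1, 0.2, 0.5, 1, 2\}$
(`sweep_selection_pressure()`), and the crossing scan uses
$N_f = 100$, $N_i \in \{85, 87, 90, 93, 95, 97\}$ together with
$N_f = 150$, $N_i \in \{130, 136, 142, 148\}$ — four evenly spaced
samples of the wider $N_i$ range at $N_f = 150$
(`default_crossing_grid()`). Monte-Carlo cross-checks run
$R = 10^5$ replicates on the $N_f = 50$, $N_i = 45$ habitat, where the
exact solver is available as ground truth and $3\,\mathrm{SE}$
resolves the effects of interest. Structured-population summaries
default to $m_{mig} = 10^{-4}$, small enough that the advisory viscous
assumption is plausible for the colony sizes above.

## What the checks do and do not establish

All validation in this package is internal to the model: exact linear
algebra against an independent dense oracle, simulation against the
exact solver, closed forms against both. Passing these checks
establishes that the implementation solves *this* birth–death model
correctly, not that the model describes any particular organism. Real
microbial systems add frequency-dependent benefits, continuous (rather
than two-valued) fitness structure, environmental fluctuation, and
spatial geometry beyond a nearest-neighbour chain — all outside the
model class. Within the model, the analytic formulas are first-order in
$\bar{s}$ and large-$N_f$: they degrade gracefully up to
$N_f\bar{s} \approx 2$ (deviations $\lesssim 2\times10^{-3}$ at
$N_f = 100$) but the exact solver, not the expansion, is authoritative
at strong selection. Fixation *times*, more than two alleles,
frequency-dependent fitness, and diploid genetics are out of scope.
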