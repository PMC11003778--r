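---
title: "Modelling transposable-element dynamics under copy-number-dependent epigenetic silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transposable-element dynamics under copy-number-dependent epigenetic silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesim)
```

## The model

`tesim` simulates the copy-number evolution of a transposable-element (TE)
family in a diploid Wright-Fisher population: constant census size $N$,
separate sexes, random mating, discrete generations. A genome is
`n_chroms` chromosomes of `chrom_length` bp (defaults: two chromosomes of
50 Mb), and a TE copy is an insertion at a distinct (chromosome, position,
homolog) site. Each generation runs the cycle

1. parents are sampled within each sex with probability proportional to
   fitness $W$ (with replacement);
2. each parent contributes a recombinant gamete — crossovers are a Poisson
   process at rate $r$ per bp with no interference, chromosomes assort
   independently;
3. the offspring's silencing state is drawn, its copies transpose, the
   ectopic-recombination hazard is applied, and fitness is evaluated.

Fitness at diploid copy number $n$ follows one of three interaction modes:

* additive: $W = 1 - s\,n$
* multiplicative: $W = (1-s)^n$
* synergistic: $W = 1 - s\,n^2$

with $W$ clamped to $[0, 1]$ and $W = 1$ at $n = 0$.

### Epigenetic silencing

Silencing is re-established every generation: each of an individual's $n$
copies draws an integer magnitude $M_i \sim \mathrm{Poisson}(a'n)$, the
copy-number dependence that makes host repression stronger in heavily
loaded genomes ($a' = a = 0.02$ without a modifier allele). One draw per
copy serves all three consumers:

* selection: the spreading of repressive marks into flanking sequence
  inflates selection against a silenced copy, $s_i' = s(1 + b M_i)$;
  additive fitness becomes $W = 1 - \sum_i s_i'$ and multiplicative
  fitness $W = \prod_i (1 - s_i')$ (each factor floored at 0);
* transposition: repression curbs replication,
  $u_i' = \max\{0, u(1 - k M_i)\}$;
* ectopic eligibility: with suppression on, a copy with $M_i > T$ is
  shielded from ectopic exchange.

With $b = k = 0$ and no ectopic model the silenced forms reduce exactly to
the plain fitness laws, and the magnitudes are never drawn.

Because the spreading cost enters additively per copy while its mean grows
linearly with $n$, expected additive fitness under silencing is
$\bar W(n) = 1 - s n(1 + b\,a\,n)$ — curvature equivalent to synergistic
epistasis, which is what allows stable containment far outside the plain
additive regime.

### Order within a generation and newborn copies

Magnitudes are drawn after reproduction using the offspring's
pre-transposition copy number; transposition then uses the same $M_i$, and
fitness and ectopic eligibility are evaluated afterwards on the full
genome. Copies born in the current generation carry $M = 0$ (silencing of
a new insertion is only established the following generation) and do not
transpose in the generation of their birth. A transposing copy inserts at
a uniformly random unoccupied (chromosome, position, homolog) site.

### Ectopic recombination

Every unordered pair of *heterozygous* copies (no insertion at the same
position on the opposite homolog) is an opportunity for ectopic exchange,
realized independently with probability $r_e$ per generation; any event is
dominant lethal ($W = 0$, the individual is censused but never
reproduces). With $P$ eligible pairs the survival probability is
$(1-r_e)^P$. Threshold suppression removes copies with $M_i > T$ from the
eligible set. The per-pair Bernoulli interpretation is the simplest model
consistent with a rate quoted "per pair", and the threshold is read
per copy (strictly $M_i > T$), not as an individual-level aggregate.

### Modifier alleles

A single biallelic locus (by default mid-chromosome 1) rescales the
silencing parameter semi-dominantly in its carriers:
$a' = a(1 + 0.5H)$ for an enhancer and $a' = a(1 - 0.5H)$ for a weakener,
with dosage $H = 0.5$ in heterozygotes and $1$ in homozygotes. The
invasion protocol simulates `burn_in_generations` without the modifier,
introduces `round(2N f)` allele copies into randomly sampled individuals
(one copy each, so initial carriers are heterozygous), and continues for
`invasion_generations`. With $b = k = 0$ and no ectopic model the modifier
is exactly inert — enhance and weaken runs from the same seed are
bit-identical, which the test suite exploits.

## Analytical equilibria

In an infinite population the equilibrium copy number $\hat n$ solves

$$\bar u'(\hat n) = -\frac{\partial \ln \bar W}{\partial n}\Big|_{\hat n},$$

the point where the expected per-copy gain from transposition balances the
per-copy log-fitness cost; stability requires the net growth rate to cross
zero from above. `analytic_equilibrium()` returns closed forms where the
algebra permits — $(u-s)/(us)$ for plain additive fitness, the quadratic
root for silencing acting on selection — and brackets the root numerically
for silencing acting on transposition and for combined effects (where the
balance condition is no longer polynomial).

One modelling point deserves emphasis. The naive mean effective
transposition rate $u(1 - k\,a\,n)$ hits zero at $n = 1/(ka)$, suggesting
transposition shuts off there. But the per-copy rate is clamped *before*
averaging: $\bar u'(n) = u\,\mathbb E[(1-kM)^+]$ with
$M \sim \mathrm{Poisson}(a n)$ keeps a Poisson-tail trickle of weakly
silenced copies at every $n$, and the simulation realizes exactly this
expectation. The solver therefore uses the exact tail sum
(`mean_effective_u()`); with the naive form the predicted equilibria sit
up to 30% below what the simulation reaches, while with the exact form
scaled simulations agree with the solver to within a few percent.
`effective_rate_ratios()` evaluates the two headline ratios — effective
$s$ over $u$, and $s$ over effective $u$ — at an equilibrium copy number
using the same expectations.

## Outcome classification

A replicate ends in one of: `completed`; `te_loss` (mean copy number
reaches zero — absorbing, since transposition needs a template);
`population_crash` (mean fitness below $10^{-3}$); `extinct` (one sex
without a viable parent). `classify_outcome()` aggregates replicates by
majority, and declares `stable_equilibrium` only when (i) the majority of
completed replicates plateau over the final `window` generations and (ii)
the relative variance of final copy numbers across replicates stays below
$1/(Ns)$, the drift-scaled reproducibility criterion. Ties and everything
else are `unsettled`.

Plateau detection is a reproducible surrogate for visual inspection:
an OLS slope of the copy-number trajectory that is either statistically
indistinguishable from zero ($\alpha = 0.01$) *or* practically negligible
— fitted net change over the window below 5% of the window mean or below
twice the residual standard deviation of the fit, whichever is larger.
The equivalence clause matters: over thousands of autocorrelated points
the OLS standard error shrinks far below the true sampling noise, so a
pure significance test brands visibly flat trajectories as trending
(stationary equilibria at a handful of copies, whose fluctuations are
large relative to their level, are the typical casualty).

## Numerical and design choices

* **Random numbers.** All low-volume draws (Poisson, binomial) use R's
  generators; the per-element hot loops use an inline xoshiro256+ stream
  re-seeded from R's RNG at every engine entry, so `set.seed()` determines
  every run bit-for-bit.
* **Gametes.** The engine forms gametes by walking the union of parental
  TE positions (plus the modifier locus) and flipping the active homolog
  between consecutive sites with the recombination fraction
  $(1 - e^{-2rd})/2$ — the probability of an odd Poisson crossover count
  in a gap of $d$ bp. This is distributionally identical to drawing
  explicit Poisson breakpoints (only crossover-count parities between
  relevant sites affect the gamete) but costs $O(\text{copies})$ instead
  of $O(\text{crossovers}\log\text{crossovers})$; at $r = 10^{-6}$ and
  50 Mb chromosomes that is the difference between 50 breakpoints per
  chromosome and one Bernoulli per TE gap. Both implementations are
  exposed (`make_gamete(..., method =)`) and cross-validated against the
  closed-form two-locus recombination fraction. The fraction itself is
  evaluated through a 4096-bin interpolation table (absolute error
  $< 2\times10^{-6}$, far below Monte-Carlo noise).
* **Aggregated silencing draws.** When a single consumer needs the
  magnitudes, exact aggregate laws replace per-copy sampling:
  $\sum_i M_i \sim \mathrm{Poisson}(a n^2)$ for the additive load, a
  duplication count $\sim \mathrm{Binomial}(n, \bar u'/u \cdot u)$ for
  transposition, and an eligible-heterozygote count
  $\sim \mathrm{Binomial}(h, P(M \le T))$ for ectopic suppression.
  Per-copy draws are kept whenever two consumers share the same $M_i$
  (so the correlations they induce are preserved exactly).
* **Initial conditions.** The number of starting copies per individual is
  not dictated by the model; the default is `n0 = 10`, placed at distinct
  uniformly random sites per individual (independent placement across
  individuals). For equilibrium-targeted grids, `suggest_n0()` starts at
  about a tenth of the predicted equilibrium (clamped to $[2, 100]$) so
  the exponential growth phase remains visible while transients stay
  short; equilibria are insensitive to this choice when $Nu, Ns \gg 1$.
  One boundary effect is worth knowing: with per-individual
  initialization every founder carries exactly `n0` copies, so a
  parameter set with $s \cdot n_0 \ge 1$ (additive) reports
  `population_crash` at generation 0 where an initialization with
  TE-free founders would lose the TEs instead. This affects only the
  loss-versus-crash labelling of strong-selection cells, never the
  stable set.
* **Horizons.** `suggest_horizon()` integrates the mean-field dynamics
  $dn/dt = n f(n)$ from the starting copy number to 95% of the
  equilibrium and adds the plateau window, so slowly-approaching cells
  (small $u$) get proportionally longer runs without paying the maximum
  everywhere.

## What the scaled experiments do and do not show

At full scale ('full' profile) the headline experiments use $N = 10^4$,
100 replicates and at least $10^4$ generations. The package's tests and acceptance
script run the same experiments at desk scale — $N$ between 500 and 2000,
2–5 replicates, plateau windows of 1000 generations — which preserves the
deterministic hierarchy wherever $Nu, Ns \gg 1$ but makes drift visible at
the weak-parameter edge of the grids:

* cells with $Ns \lesssim 1$ (e.g. $s = 10^{-4}$ at $N \le 2000$)
  equilibrate noticeably *above* the infinite-$N$ root, because per-copy
  selection at the margin is no longer resolved against drift. The
  effective-rate ratios are therefore evaluated at the *simulated*
  equilibrium copy number of each stable cell — the quantity the printed
  ranges refer to — with the analytic solver serving as the cross-check
  that a stable root exists at all;
* modifier invasions driven by strong direct selection (the weakener
  under silencing costs) scale down cleanly; invasions driven by linked
  selection (the enhancer under tight linkage) are slower and noisier at
  small $N$, so those assertions average several replicates and test
  direction, not fixation;
* the ectopic-recombination experiment is the most scale- and
  model-sensitive: with the per-pair hazard, TE copy number is contained
  near $u/r_e$ copies during the burn-in, where mean silencing magnitudes
  sit far below the suppression threshold $T$; the threshold then has
  little traffic to act on, and the enhancing allele's predicted
  advantage is weak. A mechanism in which the hazard scales per copy
  rather than per pair would keep equilibrium copy numbers high enough
  for the threshold to matter; the per-pair reading follows the stated
  rate definition, and the discrepancy is documented rather than papered
  over.

None of the synthetic experiments model TE families with sequence
identity, excision, non-equilibrium demography, or selfing; trajectories
summarize whole-population means, so conclusions about within-genome
insertion-site structure are outside scope.

## A worked example

```{r example, eval = FALSE}
cfg <- te_config(N = 2000, u = 0.1, s = 0.01, r = 1e-6,
                 max_generations = 1500, seed = 7)
run <- run_simulation(cfg)
tail(run$trajectory, 3)
analytic_equilibrium(u = 0.1, s = 0.01)$n_hat   # 90 copies
```

The simulated mean copy number settles a few percent above the analytic
balance point — the expected finite-$N$ behaviour discussed above.
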