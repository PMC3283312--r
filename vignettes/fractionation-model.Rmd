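---
title: "A null model of post-WGD fractionation: simulation, run statistics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A null model of post-WGD fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdfrac)
```

## The process being modelled

After a whole-genome duplication (WGD) every gene exists in two copies, one
on each homeologous chromosome.  Over time one member of most duplicate
pairs is lost — *fractionation* — but almost never both, because losing both
copies of a functional gene is strongly selected against.  The central
biological controversy this package addresses is whether that loss proceeds
gene by gene or by excision of multi-gene DNA segments.

`wgdfrac` implements a one-parameter null model.  The state is a pair of
binary sequences $g, h$ over an interval of $N$ ancestral loci with
$g(i) + h(i) \ge 1$ everywhere.  A *deletion event* anchors at an eligible
position, draws a requested length $a$ from a geometric distribution

$$\gamma(a) = \tfrac{1}{\mu}\bigl(1 - \tfrac1\mu\bigr)^{a-1}, \qquad a \ge 1,$$

and converts $a$ surviving duplicates to single copies, scanning rightward
and *skipping* positions already deleted — excised DNA is no longer visible
to later events, which is what couples events into runs.  $\mu$ is the mean
number of genes removed per event: $\mu = 1$ is gene-by-gene loss, larger
$\mu$ means segmental excision.  In the *one-sided* model only $g$ is
eroded; in the *two-sided* model each event picks $g$ or $h$ with
probability $\phi$ and $1-\phi$ ($\phi = 0.5$ is unbiased fractionation) and
must stop early when it reaches a position that is single-copy on the other
sequence.  The observable state is summarized by $\theta$, the proportion of
loci still duplicated, and by the runs of the consolidated sequence $g + h$:
single-copy runs of length $l$ (empirical distribution $f(l)$), duplicated
runs (distribution $\rho(l)$), and the number $r$ of events that produced
each single-copy run (distribution $\pi(r)$).

A continuous-time intensity merely orders events and never enters any
calculation, so the simulator applies events sequentially: anchor uniform on
the eligible positions, then target, then length, from a single seeded
stream.  Identical configuration and seed reproduce the event log exactly.

## What is deliberately out of scope

Statistical hypothesis tests of biased fractionation or of geometric-versus-
gene-by-gene alternatives are not implemented; the package builds the null
model those tests would need.  Genome rearrangement distances $d$ are inputs,
never computed.  Mergers of three or more deleted runs are tracked as a
residual mass but not propagated through the recurrence (below).

## Key parameters and defaults

* `mu` ($\mu \ge 1$, genes): mean deletion-event length; no default is
  imposed on analyses — it is the quantity being inferred.
* `theta_target` ($\in (0,1]$): stopping point of a simulation.  The final
  event completes, so the achieved $\theta$ can overshoot by at most one
  event (~$\mu/N$); the achieved value is recorded.
* `N` (default 100 000 loci): interval length.  The model is conceptually
  translation-invariant on an infinite sequence; a long finite interval with
  boundary-truncated events *flagged and excluded by default* from run
  statistics makes edge effects negligible, which the tests verify by
  comparing $N = 100\,000$ against $N = 300\,000$.
* `phi` (default 0.5): deletion bias, exposed as a simulation knob only.
* `alpha` (default 0.5): the adjacency-disruption proportionality constant
  of the rearrangement correction, bounded above by the validity condition
  $\alpha D < 1/\bar u$ which the code enforces rather than clips.

## Run statistics and the conservation identity

Single-copy and duplicated runs alternate, so there is one duplicated run
per single-copy run and the total lengths are fixed by $\theta$:

$$\bar\ell_{\text{deleted}} \;=\; \frac{1-\theta}{\theta}\,
  \bar\ell_{\text{undeleted}}.$$

`summarize_runs()` reports both the literal empirical mean of duplicated
runs and the *paired* mean $\theta N / R$ ($R$ = number of single-copy
runs), the quantity the identity relates; on small hand-worked windows the
two differ because boundary runs break the pairing.  Given $r$, run length
would be a sum of $r$ independent geometric variables — negative binomial
with mean $r\mu$ (`run_length_mixture_pmf()` mixes these over $\pi$).  The
events composing a run are in fact *not* independent (long events are more
likely to bridge into neighbouring runs, so they accumulate in high-$r$
runs); the test suite asserts both that the conditional distribution rejects
the negative binomial and that the $\pi$-mixture remains a close overall
approximation, which is exactly the status the model claims for it.

## The deterministic recurrence for $\pi(r)$

Because run lengths resist direct derivation, the package evolves $\pi(r)$
deterministically in $\theta$ for the one-sided model.  Undeleted-run
lengths are taken geometric with mean $\bar E_\rho$ — each event drops a
uniformly-placed demarcation among the surviving terms, making spacings
geometric — and successive runs independent.  An event then falls in a run
of length $l$ with length-biased weight $l\rho(l)/\bar E_\rho$, at uniform
offset $j$, with geometric length $a$, and is one of five types: **A** opens
a new run ($r = 1$); **B**/**C** extend the deleted run on the left/right
($r \to r+1$); **D**/**E** merge two deleted runs ($r, s \to r + s + 1$).
Under the geometric assumption all sums over $(l, j, a)$ and over the
following undeleted runs collapse to closed forms (with
$q = 1/\bar E_\rho$, $p = 1/\mu$, $\beta = 1-q$, $\alpha = 1-p$, e.g.
$p_B = q - q^2/(1-\alpha\beta)$), so no series cutoffs are needed for the
probabilities at all; the closed forms are verified in the tests against an
independent brute-force numeric summation and against event-type frequencies
observed in simulation.  At $\mu = 1$ they reduce to the exact exchangeable
values $(\beta^2,\, q\beta,\, q\beta,\, 0,\, q^2)$.

A step of $\Lambda$ events updates
$R' = R + \Lambda\sum_r\delta(r)$, $\pi' \propto R\pi + \Lambda\delta$,
$\theta' = \theta - \Lambda\mu/N$, and re-derives the two mean run lengths
from $(\theta', R')$ so the conservation identity holds by construction.
Numerical choices:

* **Initialization.**  At exactly $\theta = 1$ there are no runs; the
  recurrence starts from a burn-in $\theta_0 = 1 - 10\mu/N$ with $R = 10$
  and $\pi$ a point mass at $r = 1$ (every early event is type A).
* **Step size.**  $\Lambda$ defaults to the number of events that deletes
  0.1% of the remaining duplicated mass, favouring accuracy over speed, and
  is additionally capped at $0.05R$ so that no run class can be driven
  negative while $R$ is still small; a step that would do so anyway is an
  error, not a silent clip.  Halving $\Lambda$ changes the final $\pi$ by
  less than $10^{-3}$ in total variation (tested).
* **Support cutoff.**  $\pi$ is carried on $r \le r_{\max}$ (default 200)
  with the mass convolved past the cutoff accumulated and a warning if it
  exceeds $10^{-6}$.
* **Three-or-more-run mergers** are counted (`other_fraction`) but not fed
  back; the recurrence therefore lags the simulation increasingly below
  $\theta \approx 0.3$, and the tests assert agreement (within 0.07
  absolute on the grouped event-type probabilities) only for
  $\theta \ge 0.4$, where agreement is actually expected.

## Inference of $\mu$ and the rearrangement correction

$\mu$ cannot be sampled directly — only run lengths and $\theta$ are
observable — so `build_response_surface()` maps
$(\mu, \theta) \mapsto$ mean single-copy run length by simulation and
`estimate_mu()` inverts it monotonically at the observed $(\bar u, \theta)$,
attaching a heuristic $\pm 1$ standard-error interval (no formal inferential
procedure is claimed).  Observations at or below the $\mu = 1$ curve are
returned as flagged boundary estimates: "no evidence that $\mu$ exceeds 1"
is an explicit, representable outcome.

Real WGD descendants are scrambled by rearrangements, so intact runs are
found as *analytical units* (AUs): two-sided single-copy runs flanked at
both ends by intact duplicate pairs, flanks sharing orientation per
chromosome, with no interior gene having a paralog outside the unit
(`find_analytical_units()`).  An AU of length $u$ has $u + 1$ breakpoints
each surviving with probability $1 - \alpha D$, whence the observed
geometric length distribution with mean $\bar u$ corrects to a geometric
with ratio $z = (1 - 1/\bar u)/(1 - \alpha D)$ and mean
$\nu = 1/(1 - z)$ (`rearrangement_correction()`), fitted on $u \ge 1$ only
(zero-length units are adjacent duplicate pairs, not runs).  The closed form
is verified against brute-force renormalization of the weighted
distribution.  The correction is honest about its fragility: it diverges as
$\alpha D \to 1/\bar u$ and the bound is enforced as an error.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_descendant()` produces the only ground-truthed data in
the package: a two-sided simulation laid out on two chromosomes with deleted
genes removed and survivors re-indexed, 2-member families marking surviving
pairs, then random segment inversions (uniform chromosome and endpoints,
orientations flipped).  This reproduces the features the AU machinery
relies on — interleaved single-copy runs, intact flanking pairs, adjacency
disruption by breakpoints — and the tests close the loop: with no
inversions the AU length multiset equals the simulator's interior run
multiset exactly, and the full pathway (scan, fit, correct with the true
per-adjacency disruption probability, invert the surface) recovers a known
$\mu = 3$ within $\pm 1$ in the median over seeds.

Real genomes differ in ways the generator does not attempt: only
inversions are generated (no translocations or transpositions, which the
correction's breakpoint argument does not distinguish anyway), families are
taken as given rather than inferred from sequence, gene density and
chromosome structure are uniform, and deletion lengths in nature need not
be geometric — that last point is the hypothesis the model exists to test,
not an assumption to hide.  Passing tests therefore demonstrate internal
consistency of the machinery and recoverability of parameters under the
null model, not that any real genome obeys it.

## Problem sizes used in the test suite

Simulation-based checks pool 20 replicates of $N = 100\,000$ intervals
(300 000 for the edge-effect comparison), matching the scale at which the
model's homogeneous-interval approximation is intended to operate; response
surfaces for inference use $N = 50\,000$ with 3 replicates per grid point,
and the synthetic-descendant pathway uses 6 000-gene genomes over 20 seeds.
Goodness-of-fit uses chi-square with tail cells pooled to expected counts
$\ge 5$ at level 0.01 — conservative for discrete tails.

## Known limitations

* The recurrence is one-sided only, and degrades below $\theta \approx 0.3$
  by design (no feedback of multi-run mergers).
* The $\mu$ interval from the response surface is heuristic.
* The rearrangement correction assumes the observed AU length distribution
  is geometric and is acutely sensitive to $\alpha$.
* In the two-sided percolation regime (very small $\theta$) eligible
  anchors can run out before the target; the simulator reports an early
  stop with the achieved $\theta$ rather than guessing.
* One row of the packaged 15-genome table (`N. castelli`) prints a
  published $1-\theta$ of 0.88 that is inconsistent with its own $(n, m)$
  at two decimals (the counts give 0.8748); `wgd_genomes()` exposes both
  the published and the recomputed values so the discrepancy is visible
  rather than silently resolved.
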