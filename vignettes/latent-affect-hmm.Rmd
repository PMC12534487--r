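---
title: "Latent affective states from cross-sectional well-being submissions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent affective states from cross-sectional well-being submissions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affecthmm)
```

## The modelling problem

`affecthmm` analyses anonymous, timestamped submissions of the 7-item Short
Warwick-Edinburgh Mental Well-Being Scale (SWEMWBS), each item rated 1-5,
collected at a public gallery installation. Although every visitor submits
once (a cross-sectional design), the submissions form a chronological
population-level sequence, and the package treats that sequence as the
realisation of a hidden Markov model (HMM): a latent affective state
$z_t \in \{1,\dots,K\}$ evolves as a first-order Markov chain with initial
distribution $\pi$ and transition matrix $A$, and the observed 7-vector of
item scores $x_t$ is drawn from a state-conditional multivariate Gaussian
$\mathcal{N}(\mu_k, \Sigma_k)$.

This is explicitly a *structural analogue* of temporal dynamics, not a
within-person process: consecutive submissions come from different people,
so "transitions" describe how the population's affective composition flows
through time. All downstream summaries (stability, dwell, long-run
occupancy) must be read at that population level.

## Estimation

Parameters are estimated by Baum-Welch expectation-maximization. The
E-step uses a scaled forward-backward recursion (per-observation emission
likelihoods are shifted by their row maximum before exponentiation, so the
recursion is stable for log-densities as extreme as $-10^6$ and sequences
of $10^4$+ observations). The M-step is the standard weighted update of
$\pi$, $A$, $\mu_k$, $\Sigma_k$, with a ridge (default $10^{-6}$) added to
every covariance diagonal — necessary because the ceiling state's
responses are nearly constant at 5, which would otherwise make
$\Sigma_k$ singular. Decoding uses log-space Viterbi with ties broken
toward the lower state index.

Choices the source analysis left unstated, fixed here as package defaults:

* **One chronological sequence.** All cleaned submissions form a single
  sequence ordered by timestamp (ties keep input order). Per-day
  subsequences would also be defensible; the population-level framing and
  the absence of overnight observations make the single-sequence default
  the simpler and adequate choice, and nothing in the package depends on
  day boundaries.
* **Initialization.** Observations are split into $K$ quantile groups of
  their per-record grand mean — a valence-ordered start that is effective
  on valence-structured data — then perturbed by seeded noise, differently
  per restart; restart $r$ uses `seed + r`. A `random_responsibility`
  alternative exists. Default 10 restarts; the highest final
  log-likelihood wins.
* **Convergence.** Relative log-likelihood change below $10^{-6}$, cap of
  500 iterations. Every fit's trace is checked nondecreasing (slack
  $10^{-8}$ relative) in the test suite.
* **Scale.** Raw 1-5 item values are modelled; the published per-state
  means are on that raw scale. Integer scores are treated as continuous
  Gaussian emissions, with no continuity correction.
* **Covariance.** Full covariance by default (matching the source's
  "full-covariance, 7 features" model); diagonal is available, as is a
  feature subset for the 3-item robustness variant.

## Choosing the number of states

`select_n_states()` fits each candidate $K$ with an identical budget and
compares $\mathrm{BIC} = -2\log L + p\ln T$, where for full covariances
$p = (K-1) + K(K-1) + Kd + Kd(d+1)/2$. On data whose emissions really are
Gaussian (the generator with `discretize = FALSE`), BIC recovers the
generating $K = 3$ in 10/10 seeds and $K = 1$ on single-Gaussian data.

A caveat the analysis scripts surface deliberately: on *discretized*
(integer Likert) data, BIC tends to prefer more states than the generator
used, because extra states absorb the grid's departure from Gaussianity —
e.g. the round-and-clip ceiling state is a point mass that a Gaussian can
only approximate. The workflow therefore reports the BIC table and then
proceeds with the 3-state configuration of the study design. This is a
known consequence of using a continuous emission model on ordinal data,
and is the main reason an ordinal-emission HMM is listed as out of scope
rather than silently emulated.

## Valence labels

States carry no intrinsic meaning, so `label_states()` orders them by the
grand mean of their emission means and, for $K = 3$, names them
`negative` / `neutral_moderate` / `positive`; other $K$ get rank labels to
avoid over-interpreting valence. Ties fall back to state-index order. The
source's own narrative labels are internally inconsistent (the same row is
called "positive" in one place and "moderately positive/neutral" in
another); labelling strictly by emission means sidesteps that.

## Transition dynamics

* **Stationary distribution** $\pi^*$ solves $\pi^* A = \pi^*$, computed
  as the left eigenvector for eigenvalue 1 and verified against the fixed
  point to $10^{-8}$. Chains with more than one closed communicating
  class raise an error naming the blocks — never a silent pseudo-answer.
  Periodic irreducible chains are fine (their $\pi^*$ is unique).
* **Dwell times.** Two estimators are exposed side by side: the geometric
  closed form $d_k = 1/(1 - a_{kk})$ (flagged infinite at $a_{kk} = 1$)
  and the empirical mean run length of the decoded path. They are
  reported together because the published dwell values (3.4/1.8/1.3
  steps) are not jointly consistent with the published transition matrix
  under any single formula — applying $1/(1-a_{kk})$ to that matrix gives
  8.0/1.8/5.1 — so the package documents its estimators rather than
  matching unreproducible numbers.
* **Row entropy** $H_k = -\sum_j a_{kj}\log a_{kj}$ with $0\log 0 := 0$;
  natural log by default, base-2 and normalized ($/\log K$) options. The
  published per-state entropies (0.843/0.843/0.842) are likewise not
  derivable from the published matrix rows in any base (those rows give
  0.463/0.938/0.617 nats); the formula above is the documented behaviour.
* **Bootstrap.** The default scheme resamples the $T-1$ consecutive
  decoded transition pairs with replacement ($B = 1000$), recomputes the
  empirical transition matrix (Laplace smoothing $\alpha = 0$ by default)
  and the derived dwell and entropy per replicate, and reports 2.5/97.5
  percentile bounds. It is seeded and exactly reproducible. A state absent
  from the path yields NA statistics with a warning. At reduced scale
  (paths of $T = 2000$), the 95% intervals cover the generating
  self-transitions in $\ge 93$ of 100 replications per state. A full
  EM-refit bootstrap is intentionally not the default: the pair scheme
  matches the stated purpose (intervals for transition probabilities) at
  a small fraction of the cost.

## Temporal contingency analysis

Submissions are binned by clock time, half-open: morning $[06{:}00,
12{:}00)$, afternoon $[12{:}00, 18{:}00)$, everything else `excluded`
(the installation collected no valid evening data). The 2x3 bins-by-valence
table is tested with Pearson's $\chi^2$ (no continuity correction;
expected cells below 5 warn), and effect size is Cramér's
$V = \sqrt{\chi^2 / (N(\min(r,c)-1))}$ with the conventional
0.1/0.3/0.5 reading. The package also reconstructs the published table
from the printed bin sizes (1,042 / 5,517) and printed shares, rounding
each cell to the nearest integer and assigning the remainder to the
negative column (only two of three shares per bin were printed); that
reconstruction yields $\chi^2(2) = 8.27$, $V = 0.036$, matching the
printed 8.20 and 0.04 to printing precision. Decoded states (Viterbi)
rather than posterior-weighted assignments feed the table; the source does
not say which it used.

## The synthetic generator

`generate_dataset()` produces exactly the structure the model assumes: a
simulated state path, state-conditional Gaussian emissions, optional
round-and-clip discretization to the 1-5 grid, invalid-code injection
(one item overwritten with 0 or -1 per affected record), and sorted
timestamps uniform within daily opening hours. The master seed is split
deterministically between path, emissions, anomalies and timestamps, so
changing the anomaly rate cannot perturb the path. The
`happyhere_config()` defaults pin the study conditions: $K = 3$, the
published transition matrix and per-state means, $n = 6559$ records,
anomaly rate 0.001, gallery hours 10:00-17:00 over 60 days, emission sds
(0.5, 0.5, 0.1) — the small ceiling-state sd makes round-and-clip produce
the published all-5.0 profile. The initial distribution is the chain's
stationary vector (none was published). The generator encodes the HMM's
own assumptions; it is the correct test-bed for the pipeline but not a
claim about the real data-generating process — in particular it cannot
show how the method behaves under ordinal measurement, within-day
nonstationarity, or visitor-mix drift.

## What the published numbers can and cannot anchor

Three published summaries are mutually inconsistent with the published
transition matrix: the stationary shares (86.3/7.5/6.2% — the printed
matrix's eigenvector is 47.9/36.3/15.8% over positive/moderate/negative),
the dwell times, and the per-state entropies (both discussed above). The
package computes all three quantities from whatever matrix it is given,
with documented formulas, and the reproduction script reports both the
eigenvector and the decoded-path occupancy so a user can see which
definition a dataset supports. The quantities that *are* reproducible from
printed inputs — the contingency $\chi^2$, $V$, the geometric dwell of the
neutral row ($\approx 1.8$ steps), the 0.875 maximum self-transition — are
asserted in the test suite at printing precision.

## Problem sizes and tolerances in the test suite

Exhaustive-enumeration oracles check forward-backward and Viterbi on 200+
random instances with $T \le 6$, $K \le 3$ at $10^{-9}$; parameter
recovery uses $n = 6000$ undiscretized records (recovered transitions
within 0.05, means within 0.10 of truth after permutation alignment,
typically 0.01/0.04); BIC selection uses $n = 3000$ per seed; the
bootstrap coverage study uses 100 replicates at $T = 2000$; long-run
simulation checks use $10^5$-step paths with autocorrelation-inflated
standard errors. These sizes were chosen to make sampling noise small
relative to the asserted tolerances while keeping the suite quick to run.

## Known limitations

* Gaussian emissions on ordinal data are an approximation; BIC state
  counts on discretized data should be read with the caveat above.
* Population-level transitions are not within-person dynamics; no claim
  about individual affect regulation follows from these fits.
* The pair-resampling bootstrap conditions on the decoded path and so
  ignores decoding uncertainty; the EM-refit scheme addresses this at
  substantial cost.
* `clean_submissions()` drops whole records on any invalid item; no
  item-level imputation is attempted (none was described for the source
  data, where exclusions affect < 0.1% of records).
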