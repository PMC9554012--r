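---
title: "Weighting survey instruments with consistent fuzzy preference relations and importance-performance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting survey instruments with CFPR and IPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpripa)
```

## The problem

Classical AHP weighting asks every expert for all $k(k-1)/2$ pairwise
comparisons per attribute group, which is burdensome and invites
inconsistent answers (primacy, recency, bandwagon effects). The consistent
fuzzy preference relation (CFPR) approach asks each respondent for only the
$k-1$ comparisons between *adjacent* attributes and completes the rest by
construction, so the resulting relation is consistent by definition. This
package implements that elicitation for a two-level instrument hierarchy
(dimensions, and criteria within each dimension), aggregates weights over a
respondent panel, and couples them with mean Likert satisfaction ratings in
an importance-performance analysis (IPA). The bundled instrument is the
HHNJS, a 30-item, 8-dimension job-satisfaction scale for home healthcare
nurses, together with the weight and IPA tables reported by a 31-nurse
reference study of that scale.

## The CFPR procedure

One respondent, one group of $k$ attributes in instrument order:

1. **Elicitation.** Fuzzy preferences $p_{i,i+1} \in [0,1]$ for the $k-1$
   adjacent pairs, where $0.5$ is indifference. Saaty-style ratios
   $r \in [1/9, 9]$ are accepted and converted by
   $f(r) = \tfrac12(1 + \log_9 r)$, which maps reciprocal ratios to
   complementary preferences.
2. **Completion.** Every other entry follows from additive transitivity
   $p_{ij} + p_{jl} - 0.5 = p_{il}$, i.e.
   $p_{i,i+m} = \sum_{t=i}^{i+m-1} p_{t,t+1} - (m-1)/2$, and additive
   reciprocity $p_{ji} = 1 - p_{ij}$. The completed matrix satisfies
   transitivity for *all* triples, not only the elicited ones (asserted in
   the test suite up to $k = 8$).
3. **Rescaling.** Completion can produce entries in $[-a, 1+a]$; the
   transform $f(x) = (x+a)/(1+2a)$ with
   $a = \max(0, \max_{ij} p_{ij} - 1)$ maps them back into $[0,1]$ while
   fixing $0.5$, preserving reciprocity, transitivity and the entry
   ordering. Rescaling is applied per matrix (per respondent per group),
   never globally, so one extreme respondent cannot distort another's
   weights.
4. **Weights.** $w_i = \sum_j p_{ij} / (k^2/2)$ — normalized row sums.
   The row-sum rule is the dominant convention in applied CFPR work; it is
   deterministic, order-preserving in the row sums, and exactly invertible
   (see the generator below), which makes ground-truth validation possible.
   A group with a single attribute has weight 1 by convention.

The elicitation chain order equals the instrument order,
$(1,2), (2,3), \dots$; under noisy judgments a different chain order would
complete to a different matrix, so the order is fixed and documented rather
than left to the data file.

## Aggregation and the confidence level

Group weights are the arithmetic mean of the respondents' weight vectors
(each already sums to one, so the mean does too). Aggregating preference
matrices before deriving weights is a deliberately rejected alternative:
averaging in weight space keeps each respondent's contribution normalized
and makes the mean interpretable as "average weight level".

Global criterion weights are hierarchical products
$w(c \wedge d) = w(d) \, w(c \mid d)$, which conserve mass at every level:
dimension weights, each dimension's local weights, and the 30 global
weights each sum to 1 (tolerance $10^{-9}$ in the pipeline). Ranks are
competition ranks ("1224") computed from full-precision weights, never from
the 4-decimal printed values; ties share the best rank and keep instrument
order for presentation.

Panel stability is assessed by removing one respondent:
$$\mathrm{CL} = \frac{1}{k} \sum_{i=1}^{k}
  \frac{\lvert w_i^{(n)} - w_i^{(n-1)}\rvert}{w_i^{(n)}} \times 100\,\%,$$
compared against a 5 % threshold. Which respondent to remove is an open
choice; the default drops the **last respondent in file order** (the most
recently recruited one), and `confidence_level(..., drop = "all")` reports
the mean and maximum over all $n$ single removals for robustness. The
statistic is scale-free because weights are normalized upstream, and it is
exactly 0 on a panel of identical respondents.

## Importance-performance analysis

Importance is the global weight (not renormalized by criterion count);
performance is the raw mean of the 1–5 ratings. Four threshold strategies
are provided: `grand_mean` (default), `median`, `scale_midpoint`
($\tau_P = 3$, $\tau_I = 1/m$), and `fixed`. "High" means value $\ge$
threshold; a point exactly on both thresholds is quadrant I. Raising the
performance threshold can only move items from {I, II} to {IV, III} — a
monotonicity property the tests assert.

Two open questions were settled as follows:

* **Reverse-worded items** (e.g. "an upgrading of the pay scales is
  needed") are averaged **as-is** by default. The reference study's printed
  performance means are consistent with raw means, so raw is the
  reproducible default; `reverse_code = TRUE` applies the standard $6 - x$
  recoding for flagged items when a satisfaction-oriented reading is
  wanted.
* **The reference study's importance threshold.** Its printed quadrant
  labels are *inconsistent* with a grand-mean importance cut
  ($1/30 \approx 0.0333$ would flip three items) and pin the threshold only
  to the interval $(0.0295, 0.0312]$. The regression tests therefore use
  `fixed` $\tau_I = 0.0304$, the midpoint of that feasible interval, with
  $\tau_P$ the grand mean of the printed performance column; the package
  default for fresh analyses remains `grand_mean` on both axes.

## The synthetic respondent generator

The generator defines the study conditions under which the pipeline is
validated: $n = 31$ respondents on the HHNJS, ground-truth weights taken
from the reference study's local weight table, true item means taken from
its performance column, judgment noise $\sigma_j = 0.05$ and rating noise
$\sigma_r = 0.7$ by default. $\sigma_j = 0.05$ places respondents around a
shared preference structure while leaving the group ordering intact —
adjacent preferences move by about one twentieth of the scale — and
$\sigma_r = 0.7$ is a typical single-item spread on a 5-point Likert scale.

Mechanics, per respondent and group: the ideal chain encoding the true
weights comes from the exact inverse of the row-sum rule,
$p_{ij} = 0.5 + k (w_i - w_j)/2$; independent $N(0, \sigma_j^2)$ noise is
added to each chain value **on the fuzzy scale** (where the CFPR arithmetic
lives, keeping the noise model additive) and clipped to $[0,1]$ so that
per-respondent matrices stay comparable instead of triggering
respondent-specific rescales. Ratings are
$\mathrm{round}(\mathrm{clip}(N(\mu_c, \sigma_r^2), 1, 5))$ — a rounded
clipped Gaussian rather than explicit category probabilities, since two
parameters suffice for recovery testing.

The inverse construction only stays inside $[0,1]$ when the target weights
satisfy the spread constraint $k(\max_i w_i - \min_i w_i)/2 \le 0.5$.
Infeasible targets are **rejected, not rescaled** (rescaling would change
the weights being encoded); `compress_weights()` shrinks a vector toward
uniform by the minimal factor (with a 2 % margin) while preserving sum,
order and ranks. One reference group — "relationship with peer", whose
printed local weights span 0.0935 to 0.3791 at $k = 4$, spread statistic
0.571 — exceeds the constraint, so the default ground truth uses its
compressed version; the printed columns are also renormalized to sum
exactly to 1 (they sum to 1.0001 at 4-decimal precision).

What the generator does **not** emulate: correlated respondents or
clustered hospitals, missing or partial questionnaires, demographic
covariates, ordinal response styles (central tendency, acquiescence), or
elicitation-scale mixing within a respondent. Passing recovery tests
therefore demonstrates correctness of the arithmetic under the stated noise
model, not robustness to the messiness of real panels.

## Numerical choices and degenerate inputs

* Invariant tolerance $10^{-9}$ absolute (completion arithmetic is exact up
  to floating point; the oracle-equivalence tests use $10^{-12}$).
* Report tables print 4 decimals with **round-half-up**, matching the
  convention of the reference tables; full precision is kept internally and
  ranks are computed before rounding.
* Validation is strict with no imputation: a respondent with a missing
  rating or judgment aborts the load with the respondent and field named.
  Non-adjacent comparison pairs are rejected.
* $k = 1$ groups take no judgments and get weight 1; $n = 1$ panels run the
  pipeline but skip the confidence level (it needs $n \ge 2$).
* Weight recomposition from externally printed tables accepts level sums
  within $10^{-3}$ of 1 (4-decimal rounding residue); the pipeline's own
  weights are checked at $10^{-9}$.

## Validation problem sizes

The test suite checks all-triple transitivity and reciprocity for
$k \le 8$, equivalence of the chain completion with an independent
equation-solving oracle for $k \le 5$ (max abs difference $< 10^{-12}$),
exact noiseless round-trips (weights to $10^{-12}$, Kendall $\tau = 1$),
and, at $\sigma_j = 0.05$, $n = 31$, per-group aggregate weight RMSE below
0.01 — a tolerance fixed from pilot oracle runs before being frozen into
the tests. Leave-one-out confidence levels on such panels come out around
0.2–0.5 %, comfortably below the 5 % threshold and of the same order as the
0.7 % the reference study reports for its real panel.

## Limitations

* Only complete adjacent-chain elicitations are supported: no general
  incomplete preference relations, no multiplicative (eigenvector) AHP
  mode, no triangular fuzzy numbers.
* The completed matrix depends on the elicitation order under noise; the
  package fixes the order to the instrument definition rather than
  estimating an order-free consensus.
* The reference study's raw questionnaires are not available, so its
  printed confidence level (0.7 %) cannot be recomputed; the package
  validates the CL statistic by construction and simulation instead.
* IPA's quadrant reading assumes the two axes are independent signals;
  gap scores, diagonal-line variants and competitor benchmarking are out
  of scope.
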