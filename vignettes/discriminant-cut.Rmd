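---
title: "Discriminant-Cut: maximizing differential-expression discoveries under a permutation FDR bound"
author: "discut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant-Cut methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Conventional differential-expression analysis computes one test statistic
per feature and thresholds it. Different statistics make different
distributional assumptions (Gaussian moderated t, rank-based, negative
binomial), and real count data routinely violate any single one of them.
`discut` treats each statistic as a *basic attribute* — one coordinate of a
K-dimensional space in which each feature is a point — and learns a linear
decision boundary

$$ f(s^{(1)}, \dots, s^{(K)}) = \sum_{k=1}^{K} w_k\, s^{(k)} - \tau,
\qquad \sum_k |w_k| = 1, $$

calling feature $i$ a differentially expressed feature (DEF) when its
discriminant value $d_i$ is strictly positive. The weights and the cutoff
are chosen to solve

$$ \max_f \; |\{i : d_i > 0\}| \quad \text{s.t.} \quad
\widehat{\mathrm{FDR}}(f) < \Psi , $$

i.e. detect as many features as possible while the estimated false
discovery rate stays below the user's bound $\Psi$. Up- and down-regulation
are searched separately with sign-constrained weights ($w_k \ge 0$ for up,
$w_k \le 0$ for down, under the uniform orientation that every attribute is
signed group 2 minus group 1): the two tails of the joint attribute
distribution need not be symmetric, and separate boundaries can exploit
that. The L1 constraint makes the search a simplex grid and favours sparse
weightings.

This is an unsupervised learning problem — no feature is labelled — and
the estimated FDR itself is the only available calibration signal.

## The FDR estimator

For a fixed boundary $f$, the estimator is a non-parametric Storey-type
construction on the discriminant values. With $\mathbb{D}(X, f) = \{d_i\}$
and $B$ label permutations $X^*_b$ (group sizes preserved, identity
excluded, complement counted as distinct):

* $\hat P(D_f > 0 \mid \mathrm{NULL})$: the median over $b$ (mean
  available via `e_b_mode`) of the count of positive permutation
  discriminant values, divided by $M$;
* $\hat P(\mathrm{NULL})$: $|\{d_i \le d_\lambda\}| / ((1-\lambda) M)$,
  truncated at 1, where $d_\lambda$ is the lower-interpolation
  $\lambda$-quantile of the pooled permutation values ($\lambda = 0.5$ by
  default, the conservative standard choice);
* $\hat P(D_f > 0 \mid R > 0)$: $(r \vee 1)/M$ with $r$ the observed
  number of calls, the $\vee 1$ guard keeping the ratio defined when
  nothing is called.

Combining gives

$$ \widehat{\mathrm{FDR}}_\lambda =
\frac{|\{d_i \le d_\lambda\}| \cdot
      \hat{\mathbb{E}}_b\!\left(|\{d^*_{i,b} > 0\}|\right)}
     {(1-\lambda)\,(r \vee 1)\,M}, $$

reported clipped to $[0, 1]$. When $r = 0$ and no permutation value is
positive the estimate is exactly 0. Two deliberate numerical choices: the
count $|\{d_i \le d_\lambda\}|$ uses a non-strict inequality exactly as
written, and a degenerate zero count (every observed value above the
pivot) is floored at one so that a vacuous numerator can never certify
FDR = 0; the flag is carried on the estimate. With $K = 1$ and $w = 1$
the whole construction reduces to the classic one-dimensional
permutation-FDR thresholding procedure with $\pi_0$ estimation, which is
how the test suite cross-checks it.

The quantile definition ("value smaller than the $\lambda$ percentile")
is ambiguous between the strict predecessor and the quantile itself; the
lower-interpolation quantile (sorted element
$\max(1, \lceil \lambda n \rceil)$) was chosen and is pinned by tests.

## The search algorithm

The weight simplex is enumerated exhaustively at a unit-fraction step
$\delta$: all non-negative multiples of $\delta$ summing to 1, i.e.
$\binom{1/\delta + K - 1}{K - 1}$ candidates. The default is
$\delta = 0.05$ for $K \le 3$ (231 grid points at $K = 3$) and
$\delta = 0.1$ for larger $K$; with these defaults runtime is dominated by
attribute extraction, not by the search.

For each weight vector the cutoff $\tau$ is tuned on the projected
statistics: the candidate cutoffs are the sorted distinct observed
discriminant values (plus one point below the minimum, which calls
everything). Because the objective is a step function of $\tau$, this
loses nothing relative to a continuous search. The estimator is *not*
monotone in $\tau$ in general, so every candidate is evaluated — but with
sorted arrays, binary-search counting and a single pass of row-wise
medians the per-candidate work is logarithmic; the key observation is
that the pivot count $|\{d_i \le d_\lambda\}|$ is invariant to $\tau$
(both sides shift equally), so only the positive-count terms vary.
Feasible candidates satisfy $\widehat{\mathrm{FDR}} < \Psi$ strictly; the
winner maximizes $r$, with ties broken toward the larger (more
conservative) cutoff.

Across the grid, the boundary with the largest feasible $r$ wins; ties go
to the smaller search-phase FDR estimate, then to fewer nonzero weights,
then to the lexicographically smallest weight vector (the grid is
enumerated in lexicographic order, making the selection fully
deterministic).

Because the same permutations drive both the search and its FDR
certificate, the winning estimate is optimistically biased. The selected
weights are therefore kept fixed and $\tau$ alone is re-tuned on an
independent calibration permutation set drawn from a disjoint seed stream
(overlap with the search set is excluded whenever enough distinct
assignments exist). The final calls and the reported FDR come from the
recalibrated boundary. If no grid point is feasible the result carries a
structured "no detections at psi" status rather than an error.

In `direction = "both"` mode the union of the two call sets is reported
with per-direction models and per-direction FDR estimates; no combined
union-FDR certificate is constructed, since the two boundaries are
separate discriminant functions and a sound union rule is an open
question. A feature on the positive side of both boundaries (rare) is
assigned the direction with the larger discriminant value.

## Basic attributes

All extractors are deterministic, oriented group 2 minus group 1, and are
re-run in full — including re-estimation of every data-dependent constant
— on each permuted label assignment. Permutation statistics are never
obtained by shuffling the original statistic vector.

* `sam_t` — corrected t: $(\bar x_2 - \bar x_1)/(s_g + s_0)$. The fudge
  constant $s_0$ defaults to the median of the per-feature standard
  errors; a fixed quantile or an explicit value are available. The full
  coefficient-of-variation minimization used by the original SAM
  procedure was judged out of proportion to the constant's role here.
  Zero-variance features with $s_0 = 0$ get statistic 0 (no evidence) and
  a flag, so that infinities never enter the boundary search.
* `sam_ranksum` — centered rank-sum: mid-ranks per feature,
  $W - n_2(n_1 + n_2 + 1)/2$.
* `moderated_t` — empirical-Bayes t with posterior variance
  $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$. The prior $(d_0, s_0^2)$ is
  estimated by moment-matching the log sample variances
  (digamma/trigamma equations, Newton-inverted trigamma); $d_0$ is capped
  at $10^6$ as "effectively infinite". Setting $d_0 = 0$ recovers the
  ordinary t exactly.
* `voom_t` — moderated t for counts: log2 counts-per-million with the
  standard half-count offset, a lowess trend of root residual standard
  deviation against average log-CPM, and per-observation precision
  weights equal to the fourth inverse power of the predicted root
  standard deviation (the inverse of the predicted variance) at each
  observation's fitted log-CPM. Below 50 features the trend is
  unreliable; the extractor warns and falls back to unit weights, where
  it coincides exactly with `moderated_t` on log-CPM.
* `nb_wald` — negative-binomial GLM Wald statistic: log link, intercept
  plus group indicator, log size-factor offsets (median-of-ratios
  factors, geometric mean 1). Per-feature dispersion is estimated by
  profile maximum likelihood (bisection on the dispersion score inside a
  compiled kernel, bracket $[10^{-4}, 50]$, the lower end flagged as
  Poisson), then shrunk halfway toward a trend obtained by regressing the
  ML dispersions on 1/mean — a deliberately simple trended-shrinkage
  stand-in that preserves the character of the statistic without
  importing a full empirical-Bayes apparatus. The Wald standard error
  comes from the observed information of the saturated two-group design.
  All-zero features get statistic 0 and a flag; non-convergent fits fall
  back to the Poisson closed form with a flag.

`voom_t` and `nb_wald` refuse non-integer input; continuous measurements
(e.g. methylation proportions) can be passed through
`scale_round(values, 1000)` first, mirroring common practice for feeding
proportions into count-only tools. `sam_t`, `sam_ranksum` and
`moderated_t` accept any real-valued matrix directly.

Exact numerical equality with any external implementation of these
statistics is explicitly not a goal; the contracts above are what the
tests pin down.

## The simulator

The generator aims at realistic bulk RNA-seq counts. Deeply replicated
reference datasets show per-gene count distributions far more varied than
any single parametric family: roughly 63.5% of genes are better described
by a (zero-truncated) Gaussian mixture than by a negative binomial, with
1/2/3-component mixtures in roughly 44:50:6 proportion. The package
reproduces this two ways:

* `fit_gene_library()` fits each gene of a user-supplied reference matrix
  — low-count genes removed first (count below 10 in strictly more than
  half the samples) — with both an NB (profile-ML dispersion, clamped to
  Poisson when the variance does not exceed the mean) and a Gaussian
  mixture (EM via mclust, components chosen by BIC among 1–3, standard
  deviations floored at $10^{-3}$ of the data range). The family kept is
  the one whose fitted distribution correlates better with the gene's
  20-bin equal-width histogram; "equal-size bins" is read as equal-width
  over the observed range, the probability mass per bin is taken from the
  fitted CDF, and exact ties (or doubly undefined correlations) go to
  the simpler NB family.
* `synthetic_reference()` draws a parameter library directly at those
  mixture proportions, with mean count scales log-uniform on
  $[10, 10^4]$, NB dispersions log-uniform on roughly $[0.01, 0.5]$, and
  mixture components spread around the base mean with weights bounded
  away from zero — values a practitioner would accept as typical bulk
  RNA-seq. This mode needs no download and drives the whole test suite.

`simulate_dataset()` then draws each null gene from its family (mixture
draws truncated at zero, all values rounded to integers) and redraws
until the |log2 fold-change| between the two predetermined halves is at
most $4.5\sigma_N$, where $\sigma_N$ is the standard deviation of log2
fold-changes between random disjoint N/2-sample splits of the reference
(pooled over genes and draws; pseudo-count 0.5 on group means; log base 2
and the pseudo-count are field-convention choices, as is the single
global $\sigma_N$). True DEFs are then planted: a chosen gene has one
group multiplied or divided by a factor drawn uniformly from
$[1.5, 3.0]$ — for an up-regulated gene either group 2 is multiplied or
group 1 divided, with the choice uniform at random — and values are
rounded again. The truth table (direction and factor) is recorded for
evaluation.

What the generator does *not* emulate: library-size heterogeneity
(columns are exchangeable by construction), sample-level covariates or
batch structure, gene–gene correlation, and sequencing-error artefacts.
Passing the validation suite therefore demonstrates correct FDR behaviour
under independent, exchangeable-sample nulls — the regime the estimator's
theory addresses — not robustness to confounded real-world designs.

## Evaluation harness

`true_fdr()` scores calls against truth direction-aware: calling a
truth-up gene "down" counts as a false positive (the strict reading).
`sweep_psi()` re-searches the boundary across a grid of targets
(0.01–0.10 by 0.01 by default) on shared attribute matrices and
permutation nulls; reordering its table by calls gives the false
discovery curve. `aggregate_replicates()` produces replicate-matched
means and paired t comparisons between configurations. A configuration is
said to fail FDR control when its mean true FDR exceeds $1.1 \Psi$ — the
10%-tolerance convention used throughout the validation suite.

## Validation problem sizes

The statistical acceptance tests run the full pipeline on synthetic
libraries at the default study conditions: 2000 genes, 6 vs 6 samples,
100 up- and 100 down-regulated DEFs, $\Psi = 0.05$, attributes
\{`voom_t`, `sam_ranksum`, `nb_wald`\}, $B = 50$ search permutations and
$B_{cal} = 100$ independent calibration permutations, over 50 replicates
(20 replicates of 1000 genes for the pure-null calibration check). The
package defaults are larger ($B = 100$, $B_{cal} = 500$ or exhaustive);
the validation sizes were fixed once as a balance between the stability
of replicate means and the cost of recomputing every attribute on every
permutation, and are stated here so the numbers in the test suite are
interpretable.

## Known limitations

* Linear boundaries only; kernel or tree-structured discriminants are out
  of scope.
* One weight vector per direction for all features; per-feature
  combinations are not attempted.
* The permutation null requires enough distinct label assignments —
  with fewer than about 4 samples per group the estimator is unusable,
  and detection power below 5 vs 5 is intrinsically poor.
* Only boundary-level FDR is estimated; per-feature q-values are not
  produced.
* "Both"-direction runs report per-direction certificates; the union
  carries no single combined FDR statement.
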