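---
title: "Mining time-lagged regulation rules from expression time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining time-lagged regulation rules from expression time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagrules)
```

## The problem and the model

Gene regulatory events leave qualitative traces in expression time series:
when a regulator crosses some expression level at time point $j$, its target
tends to be up- or down-regulated at time point $j + w$.  `lagrules` mines
such pairwise, time-lagged rules directly from one or more expression
matrices $X \in \mathbb{R}^{n \times m}$ ($n$ genes, $m$ ordered time
points, log-ratio scale), without assuming any dynamical model.

A rule is a statement

$$\langle\mathrm{sym}\rangle\, \mathrm{gene}_r \; w \rightarrow\;
  \langle\mathrm{sym}\rangle\, \mathrm{gene}_i$$

read as: the state of the regulator $r$ at time $j$ (above/below its
pair-specific threshold) predicts the state of the target $i$ at time
$j + w$.  Seven integer codes describe the possible forms: the two-sided
types $1$ (`+/- r w -> +/- i`) and $-1$ (`+/- r w -> -/+ i`) constrain both
states, the one-sided types $2, 3, -2, -3$ constrain only one premise
(`+ r w -> + i`, `- r w -> - i`, `- r w -> + i`, `+ r w -> - i`), and $0$
means no interaction.  Type 0 is never emitted: it is the label given to
every candidate that survives no filter.

Everything downstream depends on how the continuous values are mapped to
the two states, and the package's central design commitment is that
discretization is *adaptive*, at two levels.

### Target discretization (TDT)

For a target gene the threshold is the midpoint of the bipartition of its
sample values minimizing $\mathrm{var}(S_1) + \mathrm{var}(S_2)$ — the exact
$k = 2$ k-means solution in one dimension, found deterministically by
scanning the $|S| - 1$ split positions of the sorted sample array
(`compute_tdt()`).  Variances are population variances (divide by the part
size): the objective only ranks splits, and this choice is defined even for
the single-element parts met during the unconstrained scan.  If the global
optimum isolates fewer than two samples on either side, the gene is
*excluded* from inference for that dataset and delay: a state observed at a
single time point is indistinguishable from an outlier.  The exclusion test
is applied to the unconstrained optimum on purpose — a constrained search
could never trigger it, and silently keeping a gene whose best bipartition
is outlier-driven is exactly what the rule is meant to prevent.  At least 4
samples are required so that a valid split (2 + 2) exists at all.  When
several splits tie, the smallest split index wins (determinism).

### Regulator discretization (RRT)

The expression level at which a regulator acts is not a property of the
regulator alone: the same gene can switch one target at one level and
another target at a different level.  For each (regulator, target) pair,
every distinct observed value of the regulator is a candidate threshold
$t$; the samples split into $Do$ (value $\le t$) and $Up$ (value $> t$),
and the candidate minimizing the weighted partition entropy

$$E(t) = \frac{|Do|}{N} H(Do) + \frac{|Up|}{N} H(Up)$$

is selected (`compute_rrt()`), where $H$ is the binary Shannon entropy
(base 2) of the already-discretized target states inside each side, with
$0 \log 0 = 0$.  Base 2 makes the bounds exact: $E = 0$ iff both sides are
label-pure, $E = 1$ iff both sides are 50/50.  Candidates leaving a side
empty are skipped (the maximum observed value always empties $Up$), a
constant regulator therefore has no informative threshold and is assigned
type 0, and entropy ties break toward the smallest threshold.  Repeated
observed values are deduplicated before the scan; keeping duplicates would
only re-evaluate identical partitions.

### Scoring and filtering rules

For delay $w$ the series are aligned by dropping the first $w$ target
samples and the last $w$ regulator samples (`align_lagged()`), so $m - w$
sample pairs remain; the TDT is recomputed per delay on the surviving
target samples, and the RRT on the surviving regulator samples.  Each of
the six non-zero types is scored with

$$\sigma = \frac{TP}{TP + FP} \cdot \frac{TN}{TN + FN},$$

the product of the positive and negative predictive values of the rule's
"+" and "−" premises (`score_rule()`); one-sided types use only their one
factor.  The counts are tabulated per type so that factor one is always the
precision of the "+" premise and factor two the precision of the "−"
premise (`confusion_counts()` documents the full mapping); any $0/0$ factor
scores 0.  Two filters apply:

* **accuracy** — minimum $\sigma$ for a rule to be emitted.  Default 0.75;
  pairwise qualitative relationships below that level rarely replicate.
* **SCP** (sample coverage percentage) — for one-sided types only, the
  covered count ($TP$ or $TN$) must be at least `scp` of the *aligned*
  samples.  One-sided rules are cheap to satisfy by chance, so the default
  is 0.95; at `scp = 1` no one-sided rule can ever be emitted.  The
  denominator is $m - w$ rather than $m$: both the coverage and the sample
  set shrink together under lagging, and using $m$ would make one-sided
  rules unreachable at large delays for no statistical reason.

The best surviving type is assigned per regulator independently
(`best_rule_type()`); the per-target vector of assignments is the
gene-profile classifier (`infer_profile()`).  Independence across
regulators makes the greedy per-component maximization exact.  Score ties
prefer type $\pm1$ over one-sided types (they constrain both states, so
they are strictly more informative at equal score) and positive codes over
negative; the paperless tie order is fixed as $1, -1, 2, 3, -2, -3$ purely
for determinism.  Self-loops are skipped at $w = 0$ (a gene trivially
predicts itself) and are off by default at $w \ge 1$
(`allow_self_loops`).

### Consensus across datasets

Rule sets inferred independently from $K$ datasets are intersected delay
component by delay component.  A rule's identity is its full statement —
regulator, target, delay *and* type; a pair matching as type 1 in one
dataset and type 2 in another is two different claims and is not merged.
The RCA parameter relaxes the strict intersection: a rule survives when it
appears in at least $\lceil \mathrm{RCA} \cdot K \rceil$ datasets
(`support_threshold()`; 10 datasets at RCA 0.60 require 6), all datasets
weighted equally.  The surviving rule carries the *minimum* score across
its supporting datasets — the most conservative summary.  A target
excluded by its TDT in some dataset contributes no rules there, which
counts against support: absence of evidence is treated as evidence of
absence, the strictest reading of an intersection.  Delays are abstract
units (one sampling step), not minutes: datasets with different sampling
rates are intersected without resampling, and `compute_max_delay()` turns
an hypothesis "regulation acts within $\Delta t_H$ minutes" into the bound
$W = \min(\lfloor \Delta t_H / \min_k \Delta t_k \rfloor,\; \min_k m_k - 4)$
— the floor because a partial sampling step cannot be inferred, the second
term because $W \le m - 4$ keeps 4 aligned samples in the shortest
dataset.

## Parameters at a glance

| parameter | meaning | default | range |
|---|---|---|---|
| `accuracy` | minimum rule score $\sigma$ | 0.75 | (0, 1] |
| `scp` | minimum covered fraction for one-sided types | 0.95 | (0, 1] |
| `rca` | minimum fraction of supporting datasets | 1 | (0, 1] |
| `max_delay` | largest delay $W$ in sampling steps | 0 | $0 \ldots m-4$ |
| `allow_self_loops` | self-regulation at $w \ge 1$ | `FALSE` | — |

## A worked run on synthetic data

The generator plants rules with known identity and thresholds:

```{r}
planted <- list(planted_rule("G01", "G02", 1, 1),
                planted_rule("G03", "G04", 2, -1))
st <- generate_synthetic(n_genes = 8, m_timepoints = 12, k_datasets = 3,
                         planted = planted, noise_sd = 0, seed = 7)
cons <- run_inference(st$datasets, accuracy = 0.75, scp = 0.95, rca = 1,
                      max_delay = 2)
cons
recovery_metrics(cons, st)
```

## What the generator emulates — and what it does not

Synthetic genes are *two-level* signals: each gene has a latent threshold
$\theta_g \sim U(-1, 1)$ and emits $\theta_g \pm \text{margin}$ according
to its $\pm1$ state, plus $N(0, \texttt{noise\_sd}^2)$ noise.  The margin
defaults to $\max(1, 4\,\texttt{noise\_sd})$, so states stay separable and
the TDT provably recovers $\theta_g$ (the split midpoint of two level
clusters); fixing `margin` while raising the noise is the supported way to
study degradation.  Two-level construction was chosen over sinusoids
precisely because it makes the planted TDT/RRT values analytically known
and keeps accidental TDT exclusions impossible: every state sequence is
drawn with at least two samples per state in every window used at the
planted delays.  Planted rules set the target's lagged states from the
regulator's per the rule type; `fidelity` < 1 corrupts each constrained
position independently, and `state_flip_prob` adds measurement-level state
flips to all genes after propagation.

Two consequences of the construction are worth stating:

* a delay-0 two-sided rule makes its mirror (target as regulator) literally
  true, so the truth table includes the mirror, flagged `implied`;
  otherwise no inference method could ever reach precision 1 against the
  planted truth.  Chains sharing a regulator would similarly imply derived
  rules, so a gene may be the target of at most one planted rule.
* real expression data are not two-level: levels drift, autocorrelation is
  strong, noise is heteroscedastic, and true regulation is combinatorial.
  Passing the recovery tests shows the inference machinery is correct, not
  that the method will reach any particular precision on microarray data.

## Numerical choices and degenerate inputs

* Population variance in the TDT objective; ties to the smallest split
  index; exclusion decided on the unconstrained optimum.
* RRT candidates are distinct observed values; empty-side candidates are
  skipped; entropy ties go to the smallest threshold; a constant regulator
  raises "no informative threshold" and becomes type 0 upstream.
* Discretization boundary: a value *equal* to the threshold is
  downregulated ($-1$); the state is $+1$ only strictly above.
* The support threshold $\lceil \mathrm{RCA}\cdot K\rceil$ and the delay
  ratio $\lfloor \Delta t_H / \min \Delta t \rfloor$ are computed with a
  $10^{-9}$ guard against binary-representation artifacts (e.g.
  $0.6 \times 10$).
* Score comparisons use a $10^{-12}$ tolerance so that exact ties are
  broken by the documented preference order rather than by rounding noise.
* Matrices with fewer than 5 time points are rejected outright; delays
  leaving fewer than 4 aligned samples are errors, not warnings.
* Missing values must be resolved before inference: `drop_gene` (default;
  conservative, never invents values that could steer a threshold search)
  or `row_mean`.  Non-equidistant time points are the caller's
  responsibility: the package never truncates or resamples silently.

## Evaluation conventions

Reference association sets carry neither direction nor delay, so inferred
rules are projected to unordered gene pairs before benchmarking
(`project_pairs()`), collapsing delays, directions and types — this also
prevents one reference match from validating several rules.  Metrics are
computed over the full pair universe $\binom{n}{2}$ of the analysis gene
list (`pair_metrics()`): precision, sensitivity, specificity, and the mean
reference score of the matched pairs.  The averaging population for the
score is genuinely ambiguous (matched pairs vs all predicted pairs), so
both are reported: `average_score` (matched only; its expectation under
random prediction is the reference-set mean) and `score_over_predicted`
(unmatched predictions count 0).  Under uniformly random prediction the
expected precision equals the reference density
$|\mathrm{ref}| / \binom{n}{2}$ — a useful floor any real run must clear.

## Problem sizes used in the tests

The shipped test-suite and reference computations run on deliberately small
instances: oracle-equivalence sweeps use 200 random instances of 4–50
samples against brute-force enumerations; recovery runs use 8–12 genes,
12–14 time points, up to 3 datasets and delays up to 3.  These sizes make
every optimum checkable by exhaustive search while exercising all code
paths; the algorithm itself scales as $O(K \cdot W \cdot m \cdot n^2)$ and
the implementation caches nothing across (dataset, delay) blocks, so larger
studies scale predictably.

## Known limitations

* Rules are pairwise; combinatorial (multi-regulator) logic is out of
  scope, as are probabilistic scores and any multiplicity control over the
  emitted rule set.
* A delay is one sampling step of whichever dataset produced the rule;
  consensus across differently-sampled datasets reads "before/at/after",
  not minutes.
* The two-state alphabet cannot represent graded or transient responses.
* Exclusion by TDT silently shrinks the searchable target set — the run
  log lists every exclusion per dataset and delay for exactly that reason.
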