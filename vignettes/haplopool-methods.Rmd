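---
title: "Estimating rare-variant haplotype distributions from pooled data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rare-variant haplotype distributions from pooled data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopool)
```

## Model and data

We consider $L$ bi-allelic loci and code each haplotype as a binary vector
$y \in \Omega = \{0,1\}^L$, with 1 the minor (variant) allele. Under
Hardy–Weinberg equilibrium the $2nk$ haplotypes of $n$ pools of $k$
individuals are i.i.d. draws from an unknown probability function $f$ on
$\Omega$. A pooled assay reports only the pool totals
$T_i = \sum_{j=1}^{2k} Y_{ij}$, a vector of per-locus minor-allele counts in
$0..2k$; the likelihood of a total is the $2k$-fold convolution of $f$,
which is what makes direct maximization intractable.

Collapsing each total locus-wise to $Z_{li} = I(T_{li} \ge 1)$ yields the
collapsed data, whose induced distribution $g$ over 0/1 patterns is central
to everything the package does. `collapsed_freq()` evaluates it by
inclusion–exclusion over the variant positions $\Lambda'(y)$ of a pattern:

$$g(y) = \sum_{S \subseteq \Lambda'(y)} (-1)^{|S|}\, f_0(\Lambda(y) \cup S)^{2k},$$

where $f_0(\Lambda)$ is the probability that a single haplotype is zero on
all loci in $\Lambda$. Two consequences drive the design:

* $g(\mathbf 0) = f(\mathbf 0)^{2k} < f(\mathbf 0)$: collapsing strips mass
  from the ancestral haplotype; and
* for non-ancestral $y$ with $f(y) > 0$, $g(y) > f(y)$ whenever
  $f(\mathbf 0) > (1/2k)^{1/(2k-1)}$ (`lemma1_threshold()`), because one copy
  of $y$ alongside $2k - 1$ ancestral haplotypes already produces the
  collapsed pattern $y$.

So for rare variants the distinct observed collapsed rows — the **CD
list** — capture each true haplotype with the amplified probability
$1 - (1-g(y))^n$ (`capture_prob()`; `min_pools_for_capture()` inverts the
Poisson form $n \ge -\log\varepsilon / g(y)$ for design).

## The collapsed-data MLE

`cdmle()` is the closed-form estimator obtained by Möbius inversion of the
empirical zero-pattern fractions $\hat g_0(\Lambda) = n_{Z0}(\Lambda)/n$:

$$\hat f_{CD}(y) = \sum_{S \subseteq \Lambda'(y)} (-1)^{|S|}
  \left(\frac{n_{Z0}(\Lambda(y) \cup S)}{n}\right)^{1/2k}.$$

Summed over all of $\Omega$ the raw values telescope to exactly 1, but
individual values can be negative under sampling noise; we clip them to zero
by default, count the clips in the `clipped` attribute, and report the
estimates *unnormalized* (a `renormalize` flag exists, off by default).
Estimates are positive only at observed collapsed rows, so the CD list is
the default target set. The reference tables we compare against do not say
whether negative values were clipped or simply absent; clipping plus
CD-list targeting is our documented reading, and it is immaterial for the
summary metrics because clipped values are numerically tiny. The
inclusion–exclusion has $2^m$ terms for a haplotype with $m$ variant
alleles; we refuse $m > 20$ with guidance rather than attempt it.

## EM restricted to a list, trimming, and the adaptive threshold

The E-step needs, for each pool, every multiset of $2k$ list members whose
componentwise sum equals the observed total. `enumerate_configurations()`
does this exactly by depth-first search over members ordered by decreasing
number of variant alleles, pruning a branch when a residual locus demand
exceeds the remaining slots or cannot be covered by the remaining members.
Identical totals are grouped with multiplicity weights, all configurations
are stacked into one matrix, and an EM iteration is then a single matrix
product followed by a grouped normalization — the results are
contract-identical to a naive per-pool loop (and tested against one). The
M-step is the closed-form multinomial update
$\hat f^{(t+1)}(y) = \hat m^{(t)}(y)/(2nk)$.

**Trimming.** `run_em_trimmed()` removes, after each M-step, members whose
current frequency falls below the threshold, renormalizes immediately, and
continues; it stops only when an iteration both converges and removes
nothing. Two protections apply (the reference method is silent here, so
these are the package's own choices, made to keep the likelihood finite and
$\hat f(\mathbf 0)$ always defined): the ancestral haplotype is never
trimmed, and a member is retained — highest-frequency candidates first —
if its removal would leave some observed pool total with no compatible
configuration.

**Adaptive threshold.** `em_adaptive()` re-runs the trimmed EM from scratch
for every threshold on a grid (default 0.0001 to 0.002 in steps of 0.0001,
the grid used in the reference study) and selects the fit whose
$\hat f(\mathbf 0)$ is closest to the benchmark $\hat f_{CD}(\mathbf 0)$,
breaking ties toward the smaller threshold (least aggressive trimming).
Re-running from scratch, rather than warm-starting across the grid, matches
the idea of trying thresholds independently; because the configuration
enumeration is shared across the grid, the sweep costs little more than one
run. `threshold_sweep()` exposes the complementary diagnostic: mean SSE as
a function of a *fixed* threshold, with the mean adaptively selected
threshold overlaid.

**Estimator roster.** `estimate_haplotypes()` dispatches EM-CDL (CD list),
EM-ACDL (augmented), EM-ATCDL (augmented + trimmed, the recommended
estimator), EM-TCDL (trimmed only), EM-PL (perfect list, a gold standard
usable only in simulation), and EM on an external list. Augmentation adds
the $\le L$ single-variant haplotypes — for rare variants these are the
likeliest true haplotypes missed by the CD list; adding pairs as well would
be possible but inflates the first iteration for little gain, since such
members are trimmed almost immediately.

## Numerical choices and degenerate inputs

* **Initialization**: uniform over the current list (the reference method
  does not specify one). A `cdmle` initialization is available, but uniform
  is the default: it is reproducible, list-agnostic, and reached the same
  fixed points in our checks.
* **Convergence**: maximum absolute frequency change $< 10^{-6}$, capped at
  2000 iterations; the per-iteration observed-data log-likelihood trace is
  retained and is non-decreasing within any fixed list (asserted in tests
  with $10^{-8}$ slack).
* **Zero frequencies**: members that appear in no configuration get
  frequency 0 after one iteration and stay there; log-frequencies are
  floored at $-10^6$ inside the E-step so such members never produce NaNs.
* **Infeasible pools**: a total no multiset of list members can produce
  makes the likelihood zero. `run_em()` errors by default, naming the
  pools. The estimator front-ends instead drop such pools from the
  likelihood with a warning and record them — with $k \ge 2$ the raw CD
  list regularly cannot express totals with entries $\ge 2$, and erroring
  would make EM-CDL unusable on realistic data.
* **Ancestral force-inclusion**: `cd_list()` appends the all-zero haplotype
  (tagged `protected`) even if no all-zero row was observed, because the
  adaptive rule needs $\hat f(\mathbf 0)$; for rare variants an all-zero
  pool is observed with probability near 1 anyway, and the flag
  `include_ancestral = FALSE` restores the literal list.
* **Ties and ordering**: lists are ordered ancestral-first then
  lexicographically, making every EM run deterministic; the adaptive rule
  breaks score ties toward the smaller threshold.
* **Rounded published tables**: frequency-table constructors renormalize
  sums within $10^{-3}$ of 1 (printed tables are rounded to four decimals);
  with renormalization off, the sum must be within $10^{-6}$.

## The simulator and what the studies show

`simulate_pools()` draws $2nk$ haplotypes i.i.d. from a given distribution
(multinomial resampling with replacement — the Hardy–Weinberg reading of
the study design) and sums them within pools; `collapse_pools()` applies
the indicator reduction. Replicate seeds in `run_study()` are
`seed + replicate`, so single replicates can be re-run exactly.

The two bundled distributions (`hap_example("mgll25")`: 22 haplotypes over
25 loci, ancestral frequency 0.7995; `hap_example("faah32")`: 32 haplotypes
over 32 loci, ancestral 0.7113) are haplotype distributions estimated from
re-sequenced rare-variant regions in an obesity cohort and serve as the
known truths of the simulation studies. The generator emulates exactly the
conditions those studies state — i.i.d. haplotypes, equal pool sizes,
error-free integer allele totals. It does **not** model sequencing
read-depth noise, pool-construction measurement error, genotyping error,
unequal pool sizes, multi-allelic loci, or linkage/recombination structure
beyond what the truth table itself encodes; passing tests therefore
demonstrate correctness of the estimators under the stated sampling model,
not robustness to assay artifacts.

`run_study()` scores each estimator per replicate by the full-support sum
of squared errors $\sum_{y}(\hat f(y) - f(y))^2$, the missed mass (total
true frequency of haplotypes absent from the final list — identical under
our trimming to "estimated zero", since trimmed members leave the list),
and the remaining mass (total estimate on haplotypes with $f(y) = 0$),
plus the final list length and $\hat f(\mathbf 0)$. The default is 100
replicates, matching the reference study; the package's test suite runs
its study-replication checks at 25 replicates with correspondingly doubled
Monte-Carlo tolerances, which keeps the whole suite under a couple of
minutes while the full 100-replicate runs live in `scripts/acceptance.R`.

## Known limitations

* Subset enumeration limits: inclusion–exclusion quantities are refused
  beyond 20 variant alleles per haplotype ($2^{20}$ subsets), and
  `collapsed_freq()` beyond 25; rare-variant haplotypes in practice carry
  far fewer.
* Configuration enumeration is exact, not approximate; for common variants
  (dense totals) or large $2k$ combined with long, diverse lists it will
  grow combinatorially. The method is aimed at rare variants, where totals
  are sparse and compatible member sets are small.
* Standard errors of the estimates are not provided; the study driver
  reports across-replicate variability instead.
* The collapsed-data benchmark assumes the ancestral haplotype dominates;
  for common variants (ancestral frequency below `lemma1_threshold(k)`)
  the CD list loses its amplification property and EM-ATCDL's advantage
  with it.
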