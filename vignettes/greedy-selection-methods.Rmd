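---
title: "Greedy RLS selection for GWAS: model, shortcuts and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy RLS selection for GWAS: model, shortcuts and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greedysnp)
```

## The model and why it admits shortcuts

The task is binary case-control classification from minor-allele counts: a
genotype matrix $X \in \{0,1,2\}^{n \times m}$ with one row per SNP and one
column per individual, and labels $y \in \{-1,+1\}^m$. For a selected index
set $S$ we fit the ridge (regularized least-squares) classifier

$$\min_{w} \; \lVert X_S^\top w - y \rVert^2 + \lambda\, w^\top w,$$

whose solution is available in two equivalent closed forms: a primal form
inverting an $|S|\times|S|$ matrix and a dual form inverting an $m\times m$
matrix, $w = X_S (X_S^\top X_S + \lambda I)^{-1} y = X_S\, a$. Squared loss
is what buys tractability — the hinge-loss SVM has no such closed form, so
every wrapper step would mean retraining from scratch.

Two classical facts about $G = (X_S^\top X_S + \lambda I)^{-1}$ drive the
whole package:

1. **Constant-time LOO.** With $a = Gy$ and $d = \mathrm{diag}(G)$, the
   leave-one-out prediction for sample $j$ is $y_j - a_j / d_j$. The LOO
   mean squared error, $\frac1m \sum_j (a_j/d_j)^2$, is therefore $O(m)$
   once $a$ and $d$ are known. With nothing selected, $a = \lambda^{-1} y$
   and $d = \lambda^{-1}\mathbf 1$, so the LOO-MSE of the empty model on
   $\pm 1$ labels is exactly 1 — a useful fixed point for tests.
2. **Rank-one feature addition.** Adding feature $i$ changes $G^{-1}$ by
   $X_i^\top X_i$; by the Sherman–Morrison–Woodbury identity, with the
   cache $C = G X^\top$ and $u = C_{:,i}(1 + X_i C_{:,i})^{-1}$, the
   updated dual quantities are $\tilde a = a - u (X_i a)$ and $\tilde d_j =
   d_j - u_j C_{j,i}$ — again $O(m)$ per candidate.

Greedy forward selection evaluates every remaining candidate by its
post-addition LOO-MSE, commits the argmin (ties broken toward the smallest
feature index, which makes all cross-implementation tests index-exact), and
updates $a$, $d$ and $C \leftarrow C - u (X_i C)$. Each of the $k$ steps
costs $O(mn)$, giving $O(kmn)$ overall.

`select_next()` evaluates all candidates in one vectorized pass over $m
\times n$ arrays rather than looping per candidate; this changes nothing
mathematically and is validated against the scalar `evaluate_candidate()`
path and the from-scratch dual state in the tests.

## The space-efficient variant

The cache matrix $C$ is $m \times n$ in doubles, which for genome-scale $n$
dominates memory (the genotype matrix itself is integer-valued and much
denser per byte). `greedy_rls_space_efficient()` never stores $C$: from the
economy-size SVD $X_S = U\Sigma V^\top$ (recomputed after every commit, $k$
SVDs in total, matching the variant's stated complexity), $G = V\Omega
V^\top + \lambda^{-1} I$ with diagonal $\Omega = (\Sigma^\top\Sigma +
\lambda I)^{-1} - \lambda^{-1} I$, and any cache column is reconstructed as
$c = V(\Omega(V^\top X_i^\top)) + \lambda^{-1} X_i^\top$ in $O(mr)$ time,
$r \le \min(m, |S|)$.

Candidates are processed in constant-width column blocks (default 128)
rather than one at a time: a per-column interpreted loop would dominate the
runtime, while a constant-width block keeps peak auxiliary floating-point
storage at $O(m\,(r + \text{block}))$ — never $O(mn)$. An internal
allocation tracker (`se_allocation_tracker()`) records the widest block a
run allocated so the memory contract is assertable in tests. Singular
values below $10^{-12}$ of the largest are dropped when forming $\Omega$,
which keeps the reconstruction stable when selected features are collinear
(e.g. duplicated SNPs).

In R the genotype matrix is held as an integer matrix — R's densest native
storage that can participate in arithmetic; all derived linear algebra is
double precision regardless.

## The naive oracle

`naive_wrapper()` is the textbook wrapper: per step and candidate it
retrains the ridge model from scratch and computes LOO either from a fresh
dual state or by $m$ literal retrainings (`loo = "explicit"`). It exists to
be slow and obviously correct; the test suite's central claim is the
three-way equivalence of cached, SVD-based and naive selection on random
instances. One subtlety surfaced by those tests: two *different* columns
can yield LOO-MSEs equal to the last floating-point digit (an exact
mathematical tie), and then which one an implementation calls the argmin
depends on arithmetic route. The equivalence assertions therefore require
index identity only where the criterion separates candidates beyond 1e-8;
at ties, either choice is accepted after verifying the tie from scratch.

## The intercept (bias) option

The closed forms above contain no intercept, and by default none is used —
the selection follows the equations exactly. On raw allele counts this has
a real statistical consequence: genotype rows have nonzero means, and in a
no-intercept model a feature weakly cross-correlated with an already
selected one can genuinely lower the LOO error by acting as a surrogate
intercept. In planted-signal simulations this diverts early picks to such
surrogate features regardless of how strong the causal effects are. The
standard remedy is to realize the intercept as an extra constant-valued
feature: with `bias = TRUE` the constant row is appended and committed
before selection starts (it is not counted among the $k$ reported picks),
after which the causal-recovery experiments behave as intended. The
recovery, null-control and polygenic experiments in the acceptance material
all run with `bias = TRUE`; the algebraic equivalence suites run both ways.

## Baselines

The p-value filter ranks SNPs by an exact conditional test on the 3×2
genotype-by-status table: all tables with the observed margins are
enumerated (two free cells, $O(\text{total}^2)$ probability evaluations in
log-gamma arithmetic) and the p-value is the total probability of tables no
more probable than the observed one, with a relative tolerance of 1e-7 on
that comparison. Above a configurable total (default 5,000) it falls back
to the chi-square test on the same table with a warning. When a genotype
row is empty the enumeration reduces exactly to the 2×2 Fisher test — the
worked value 34/70 for table (3,1 / 1,3 / 0,0) is asserted in the tests,
and random tables are cross-checked against both a plain-`choose()`
brute-force enumerator and `stats::fisher.test`.

The hybrid method keeps the 50 smallest-p SNPs and runs greedy RLS inside
that set. Its characteristic failure mode versus the full wrapper is
redundancy: the filter happily ranks a duplicated SNP right next to its
copy, while greedy selection never gains from the second copy and skips it
— the `redundant_pair` scenario tests exactly this contrast.

## Evaluation protocol

`nested_cv()` implements the nested cross-validation design: stratified
external folds (default 3), selection run only on each training 2/3, and
for every panel size $k$ a ridge model on the first $k$ selected features
scored by AUC (Mann–Whitney with midrank ties) on the held-out fold, then
averaged over folds. The internal LOO-MSE curves decrease essentially
monotonically — the criterion overfits as the candidate pool is huge, which
is precisely why the external fold exists, and why the reported "peak k" is
a read-out of the external curve, never fed back into selection. The
leakage contract is tested destructively: deleting a test fold from the
dataset and re-running selection must reproduce that fold's selection
exactly.

`permutation_control()` permutes labels once and reruns the identical
experiment; fold splits are computed from the original labels so data and
splits match the unpermuted run. Flat AUC-vs-k curves at 0.5 under
permutation, against a strong unpermuted contrast, are the package's
guard against information leaks.

Single-SNP discriminative power (`per_feature_auc()`) uses the raw allele
count as the score and reports `max(AUC, 1-AUC)` with a direction flag,
since the minor allele may be protective and raw-count orientation is
arbitrary.

## The simulator and what it does (not) emulate

`simulate_genotypes()` draws per-SNP MAF uniformly on [0.05, 0.5] and
genotypes i.i.d. Binomial(2, MAF) — Hardy–Weinberg proportions with no
linkage disequilibrium. Independence is deliberate: it keeps the
brute-force oracles interpretable (a noise SNP is really noise). Real GWAS
data have LD blocks, population structure and genotyping artefacts, none of
which are modelled; passing tests here demonstrate algorithmic correctness
and the selection/evaluation contracts, not field performance. The only
correlation mechanism is the explicit duplicate-pair used by the redundancy
scenario.

`simulate_phenotype()` uses a logistic liability: $\mathrm{logit}\,
P(\text{case}) = \beta_0 + \sum_c \beta_c X_c$, with $\beta_0$ solved
numerically so expected prevalence hits the target (default 0.5, the
balanced design RMSE-style criteria assume). A logistic rather than
threshold-Gaussian liability was chosen for closed-form effect-size
reasoning on the odds scale.

Preset study conditions, fixed once:

* `strong_signal` — 2,000 SNPs × 600 samples, 5 causal SNPs at evenly
  spaced positions with per-allele log-odds effects spread over
  [0.8, 1.5]. Under these conditions (with `bias = TRUE`) the first five
  greedy picks contain at least four causal SNPs in 20/20 calibration
  seeds.
* `null` — 1,000 SNPs × 600 samples, no causal SNPs; nested-CV AUC is
  statistically indistinguishable from 0.5.
* `redundant_pair` — one causal SNP (effect 1.5) duplicated as its
  neighbour.
* `weak_polygenic` — 2,000 SNPs × 1,000 samples, 50 causal SNPs with
  effect 0.7 each. Calibrated once so that the strongest single causal SNP
  stays below 0.65 AUC while the 30-feature nested-CV model exceeds 0.70 —
  individually near-random markers, jointly predictive. (Smaller effects at
  600 samples left the combined model unable to find its markers at all;
  the calibrated values were frozen before the test was written.)

Every scenario plus seed determines the dataset bit-for-bit; the simulator
restores the caller's RNG state.

## Numerical and degenerate-input policy

* $\lambda$ defaults to 1 and is never tuned internally; tuning belongs to
  the caller, and all reproductions here are property-based, so a fixed,
  reported $\lambda$ keeps runs deterministic.
* Diagonal entries of $G$ satisfy $0 < d_j \le \lambda^{-1}$; an updated
  $\tilde d_j \le 10^{-12}\lambda^{-1}$ raises a hard error rather than
  being clamped — with $\lambda > 0$ it signals numerical corruption, not a
  valid state.
* All-zero candidate features are legal; they never change the criterion
  and are never chosen while any candidate strictly improves it.
* QC order: samples filtered first (missing rate > 5%), then per-SNP
  statistics recomputed and SNPs dropped by HWE-in-controls (default
  chi-square, $p < 10^{-3}$; an exact mid-p variant is available), MAF
  < 1%, or missingness > 5%; each dropped item records the first rule that
  fired (hwe, then maf, then missing). Selection requires a dense matrix,
  so residual missing genotypes are imputed (per-SNP mode by default, ties
  toward the smaller genotype) after QC and before selection — a documented
  policy choice, since QC tolerates up to 5% missingness.
* Mode-imputation ties, filter p-value ties and selection ties all break
  toward the smaller index/genotype for determinism.

## Problem sizes used in the shipped checks

The equivalence and identity suites run at $n \le 40$, $m \le 30$, $k = 5$
over dozens of seeded instances — small enough for the explicit
$m \times m$ oracles, large enough to exercise every update path. The
statistical experiments run at their preset sizes above; the scaling probe
doubles $n$ from 5,000 to 10,000 at $m = 500$, $k = 10$ and reports the
wall-time ratio (expected near 2 under $O(kmn)$; it is logged rather than
asserted because shared-machine clocks are noisy).

## Known limitations

* No kernelization, no backward elimination or feature removal downdates,
  no hold-out shortcuts for folds larger than one sample.
* The PLINK reader accepts SNP-major mode-1 `.bed` files only and treats
  the `.bim` A1 allele as the counted allele.
* The exact 3×2 test's probability-ordering convention matches the common
  definition but other implementations offer mid-p and other variants, so
  small numeric differences from them are expected.
* Population structure, relatedness and LD-aware analysis are out of
  scope; on real cohorts the usual corrections must happen upstream.
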