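---
title: "Predicting adverse-drug-reaction profiles for new drugs: models, evaluation and design notes"
author: "vkradr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adverse-drug-reaction profiles for new drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkradr)
```

## The problem

Post-marketing adverse drug reactions (ADRs) are costly and sometimes fatal,
and clinical trials cannot surface all of them in advance. The computational
task addressed here is *cold-start ADR profile prediction*: given a binary
ADR-by-drug label matrix $Y \in \{0,1\}^{M \times N}$ for $N$ drugs with
known safety records, predict the full ADR column of a *new* drug for which
no ADR labels exist — only feature vectors, such as drug–gene interaction
(DGI) indicators or chemical-structure fingerprint bits.

Two properties make the task statistically awkward:

* **Extreme imbalance.** Only about 2.4% of (ADR, drug) cells are positive,
  so ranking metrics that ignore true negatives (AUPR) behave very
  differently from AUROC.
* **A strong trivial baseline.** Scoring every new drug with each ADR's
  prevalence among known drugs ("the naive model") achieves a high micro
  AUROC, because ADR prevalences span orders of magnitude. Any method worth
  deploying must beat this baseline, and many published methods do not.

## The models

All four predictors share one contract: fit on the known-drug matrix
`Y_known` (never seeing a new-drug label), then emit a real-valued score
matrix over (ADR, new drug) cells. Scores are ranking scores, not
probabilities; nothing in the package thresholds them.

**Naive.** $\hat y_{ij} = \frac{1}{N}\sum_k Y_{ik}$ — each ADR's prevalence,
constant across new drugs.

**KR (kernel ridge regression).** Drug similarity is measured by a Gaussian
RBF kernel on binary feature vectors,
$k(x_i, x_j) = \exp\!\left(-\lVert x_i - x_j\rVert^2 / 2\sigma^2\right)$,
and the transposed label matrix is regressed on the kernel by minimizing
$\lVert T - KW \rVert^2 + \lambda \lVert W \rVert^2$ with $T = Y^\top$.
New drugs are scored as $(K_{\mathrm{new}} W)^\top$.

**VKR.** The label matrix is first de-noised by non-negative matrix
factorization: $Y \approx UV^\top$ with $U \in \mathbb{R}_{\ge 0}^{M\times L}$
(ADR factor) and $V \in \mathbb{R}_{\ge 0}^{N\times L}$ (drug factor),
minimizing $\lVert Y - UV^\top \rVert^2$. The kernel regression is then run
*on the drug factor* ($T = V$), the factor is extrapolated to new drugs as
$V_{\mathrm{new}} = K_{\mathrm{new}} W$, and profiles are reconstructed as
$\hat Y_{\mathrm{new}} = U (K_{\mathrm{new}} W)^\top$. The factorization
pools information across the low-rank structure of $Y$, which is what lets
the regression work with far fewer targets ($L$ instead of $M$).

**MKR.** For two feature sources, one KR model per kernel and a convex blend
of the two score matrices,
$\mathrm{mix}\cdot s_1 + (1-\mathrm{mix})\cdot s_2$. KR and VKR instead
integrate sources by a weighted entrywise *kernel* combination
(`combine_kernels()`, weights normalized to sum to one so the unit diagonal
survives).

## Notational and numerical choices

Several choices had to be fixed where the printed formulas or the protocol
leave room; they are defaults, all overridable.

* **RBF sign.** The kernel is implemented with the standard negative
  exponent. A positive exponent is not a kernel (it diverges with distance)
  and contradicts the name "Gaussian RBF"; the package treats the positive
  form occasionally seen in print as a typographical slip.
* **Ridge form.** `kr_fit()` literally minimizes
  $\lVert T - KW\rVert^2 + \lambda\lVert W\rVert^2$, giving
  $W = (K^\top K + \lambda I)^{-1} K^\top T$ via a stable linear solve
  (never an explicit inverse). The classical RKHS variant
  $W = (K + \lambda I)^{-1} T$ is available behind `form = "rkhs"` for
  comparison; all defaults use the penalized-least-squares form.
* **Prediction identity.** The drug factor for new drugs is computed as
  $V_{\mathrm{new}} = K_{\mathrm{new}} W$. (The superficially simpler
  identity $V_{\mathrm{new}}^\top = K_{\mathrm{new}} V^\top$ is
  dimensionally inconsistent with $W$'s definition and is not used.)
* **NMF solver.** Lee–Seung multiplicative updates for the Frobenius
  objective: the classical scheme whose objective is non-increasing at
  every iteration. Initialization is uniform-random non-negative, rescaled
  so the initial reconstruction matches `mean(Y)`, and seeded; `1e-12` is
  added inside update denominators so zeros in sparse data cannot lock a
  factor entry at zero. Stopping: 500 sweeps or relative objective decrease
  below `1e-6`.
* **Component-count symbol.** A single symbol $L$ is used for the NMF rank
  everywhere (`L_values` in grids, `L` in `nmf_factorize()`).
* **Hold-out arithmetic.** `split_holdout()` reserves
  `round_half_up(fraction * N)` drugs; with 766 drugs and 25% that is
  exactly 192.
* **Tie-breaks in tuning.** Among hyperparameter combinations with equal
  mean validation AUPR, the harness prefers larger $\lambda$, then smaller
  $L$, then smaller $\sigma$ — stronger regularization and simpler models
  first, and fully deterministic.
* **Degenerate folds.** A validation fold whose pooled truth is
  single-class has undefined metrics; it is skipped with a warning rather
  than scored.

## Evaluation protocol

Metrics are **micro-pooled**: all (ADR, new-drug) cells of a fold are
flattened into one label/score pair and a single AUPR and AUROC are
computed per fold. Per-ADR macro averaging is deliberately not offered —
a constant-per-ADR predictor has undefined per-ADR AUROC, and the naive
baseline's characteristically high AUROC only exists under pooling.
AUPR uses the step-wise average-precision estimator (trapezoidal
interpolation over-estimates PR area); tied scores are handled as blocks,
so constant scores yield exactly the prevalence. AUROC is the
tie-corrected Mann–Whitney rank statistic.

Model selection runs only inside training data: the default protocol is
5×4 nested cross-validation (`nested_cv()`) — an outer 5-fold split for
evaluation, and within each outer-training set an inner 4-fold grid search
(`grid_search_cv()`) that selects hyperparameters by **mean validation
AUPR only**, the metric best suited to the imbalance. A hold-out path
(`holdout_evaluate()`) tunes by plain 5-fold CV on the known drugs and
scores the withheld 25% once.

Fold plans depend only on the seed and the drug ids, so two methods
evaluated under the same seed receive byte-identical folds. This pairing
is what justifies the fold-wise paired $t$-test (`paired_t_test()`,
two-sided, $n-1$ df). When every fold-wise difference is exactly zero the
methods are indistinguishable and $p = 1$ is returned; zero-variance
nonzero differences yield an infinite $t$ and $p = 0$.

Default tuning grids are $L \in \{5, 10, 15, 20, 25\}$ and
$\lambda, \sigma \in \{10^{-3}, \dots, 10^{3}\}$; an unbounded powers-of-ten
ladder had to be truncated somewhere, and seven log-spaced values cover the
regimes from interpolation to near-total shrinkage (and from a
near-identity to a flat kernel). For multi-source kernels a single shared
$\sigma$ is tuned and applied to every source kernel before combination:
tuning one width per source would square the grid, and the binary feature
spaces here have comparable distance scales. MKR's blend weight defaults
to 0.5 and can be added to the grid via `mix_values`.

## The synthetic benchmark

Real inputs (SIDER-style drug–ADR pair lists, DGIdb-style drug–gene pairs,
fingerprint tables) are licensing- and download-bound, so the package
carries a seeded generator that emulates their statistical shape without
any external data. `generate_synthetic()` draws:

* **Latent structure.** Non-negative factors $U^\*$ ($M \times L$),
  $V^\*$ ($N \times L$) with gamma(0.3) entries — strongly right-skewed, so
  each ADR and each drug loads mainly on one or two latent components
  ("mechanisms"), and row prevalences inherit a wide, realistic spread that
  makes the naive baseline genuinely strong (micro AUROC well above 0.6).
  The probability matrix $P = U^\* V^{\*\top}$ is rescaled to a mean of
  `target_density` (default 0.0244) and clipped to $[0,1]$; a warning
  reports the realized density if clipping moves it by more than 5%.
* **Labels.** $Y_{ij} \sim \mathrm{Bernoulli}(P_{ij})$, followed by
  class-conditional label noise: each positive drops out with probability
  `noise_flip_rate` (default 0.02) and negatives flip up at the rate
  $r\,d/(1-d)$ that preserves the expected density. This models ADR
  under-reporting; naive entrywise-symmetric flipping was rejected because
  at a 2.4% base rate even a 2% flip rate would either double the density
  or, if compensated, replace four of five positives with pure noise and
  reduce every method — including the baseline — to near-chance.
* **Features.** Each of $p$ binary features (default 300) is a marker of
  one latent component, like a substructure bit marking a chemotype or a
  gene marking a mechanism. A drug carries a marker with probability
  $\min(1,\ 1.5\,s_{ic})$ where $s_{ic}$ is its normalized load on the
  marker's component, blended with uniform background bits (density 0.1)
  in proportion `feature_informativeness` (default 0.8). Holding expected
  per-drug bit counts roughly constant matters: if latent *activity* drove
  bit *density*, RBF distances would track vector norms instead of latent
  direction and the kernel would carry anti-signal. At informativeness 0
  the kernel is uncorrelated with latent similarity; the correlation rises
  monotonically with the parameter (checked in the test suite).

`planted_benchmark()` wires the generator to the evaluation protocol:
25% of drugs are masked exactly as the harness masks validation drugs, and
the returned bundle exposes only what a model may legitimately see — the
ground-truth factors are deliberately absent from it.

What the generator does **not** emulate: MedDRA term hierarchies,
drug-class label correlations, realistic chemistry, identifier systems, or
the margins of any particular SIDER/DGIdb release. Passing the synthetic
benchmark therefore demonstrates that the pipeline recovers plantable
low-rank structure through feature kernels under realistic sparsity — not
that any particular real-data figure will be reproduced.

## Problem sizes and runtime posture

The package's own experiments run at desk scale, chosen so the full test
suite and the acceptance script each finish in minutes on one CPU:
$M = 200$ ADRs, $N = 150$ drugs ($112$ known / $38$ hold-out), $p = 300$
features, latent rank 5. The end-to-end experiment tunes over the reduced
powers-of-ten grid $L \in \{5,15,25\}$, $\lambda \in \{0.1,1,10\}$,
$\sigma \in \{1,10,100\}$ — the full default grids multiply runtime about
ninefold without changing the qualitative outcome. Unit fixtures are
smaller still (tens of drugs).

## Known limitations

* Micro-pooled AUROC is dominated by the cross-ADR prevalence ordering. At
  desk scale (about five positives per drug column) the naive baseline's
  empirical prevalences are a very low-variance estimate of that ordering,
  so VKR's AUROC advantage over the baseline is real but small (its AUPR
  advantage is large); at rank $L$ well below the ADR count the NMF row
  representation slightly distorts the prevalence ordering, which is why
  the tuned $L$ tends toward the top of its grid on the benchmark.
* Multiplicative NMF updates converge slowly near full rank; exact
  reconstruction tests budget thousands of sweeps.
* `kr_fit(form = "primal")` squares the kernel's condition number
  ($K^\top K$); for nearly-flat kernels ($\sigma \to \infty$) with
  $\lambda = 0$ the solve can fail and the error message advises
  $\lambda > 0$.
* The paired $t$-test across 5 folds has low power; the package reports
  p-values without multiplicity correction, mirroring the protocol it
  implements.
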