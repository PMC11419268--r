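---
title: "Phenotype-aware component analysis: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-aware component analysis: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paca)
```

## The problem

High-dimensional omics matrices measured on a case group and a control group
— the motivating application is whole-blood DNA methylation in disease
cohorts — are dominated by variation that has nothing to do with the disease:
cell-type composition, batch and technical effects, genetic ancestry. The
variation of clinical interest, heterogeneity *within* the cases, is
typically far more subtle. Ordinary PCA of the case matrix returns the
dominant shared axes; contrastive methods such as cPCA can suppress them but
require a contrastive hyperparameter with no principled default.

This package implements phenotype-aware component analysis (PACA): it
*learns* the case/control-shared axes with a canonical correlation analysis
carried out over the sample space, removes them from the cases by projection,
and takes principal components of what remains. The only structural choice is
`k`, the number of shared directions to remove, and that choice can be made
by a permutation test (`select_k()`); there is no contrastive tuning
parameter.

## The generative model

Let $X \in \mathbb{R}^{m \times n_1}$ (cases) and
$Y \in \mathbb{R}^{m \times n_0}$ (controls) be measurements of the same $m$
features, with $m > \max(n_0, n_1)$. The package's simulator and the
method's analysis both refer to the descriptive factor model

$$X = W_0 Z_X^0 + W_1 Z_X^1 + E_X, \qquad Y = W_0 Z_Y^0 + E_Y,$$

where $W_0 \in \mathbb{R}^{m \times k_0}$ spans the shared sources of
variation with per-individual activities $Z_X^0, Z_Y^0$;
$W_1 \in \mathbb{R}^{m \times k_1}$ spans case-only sources with activities
$Z_X^1$; and the noise is i.i.d. $\mathcal{N}(0, \sigma^2)$. The target of
inference is $Z_X^1$ up to an invertible linear map. Identifiability rests on
the *orthogonality assumption* $W_0 \perp W_1$: case-specific directions are
orthogonal to the shared ones. When that assumption is violated the removal
step takes part of the case-specific signal with it (or, depending on
geometry, under-corrects); the simulator exposes `orthogonal_w = FALSE`
precisely so this failure mode can be studied.

## The algorithm

`paca(X, Y, k, k1)` performs, in order:

1. **Centering.** Each column (sample) has its mean over features
   subtracted. This per-sample convention — rather than the per-feature
   centering usual in PCA — is deliberate: it makes the centering of any
   sample independent of every other sample, so a fitted model applies to a
   replication cohort as a pure matrix product, with no stored training
   means. A per-feature pre-centering pass is available as
   `center_features = TRUE` (off by default); when used, the case feature
   means are recorded in the model and replayed by `predict()`.
2. **Sample-space CCA.** Find $\hat a_r \in \mathbb{R}^{n_1}$,
   $\hat b_r \in \mathbb{R}^{n_0}$ maximizing
   $a^\top X'^\top Y' b$ subject to $\|X'a\|_2 = \|Y'b\|_2 = 1$ and
   orthogonality of each $X'\hat a_r$ (and $Y'\hat b_r$) to its
   predecessors. Because the combinations are over samples, each canonical
   variable $X'\hat a_r$ is a feature-space direction: the case-side
   representation of a source of variation that is also present in the
   controls, found without any contrastive weight.
3. **Removal.** $\hat U_0 = X'\hat A$ (orthonormal by construction);
   $\tilde X = X' - \hat U_0 \hat U_0^\top X'$.
4. **Residual PCA.** The top `k1` loadings $\hat U_1$ and scores of
   $\tilde X$ are returned; the scores are the patient-level case-specific
   components.

### Numerical realization

The CCA is solved jointly from the eigendecomposition of the regularized
product matrix
$(S_{XX}+\epsilon I)^{-1} S_{XY} (S_{YY}+\epsilon I)^{-1} S_{YX}$, where
$S_{XX} = X'^\top X'/m$ etc. are $n \times n$ sample-space covariances.
Rather than forming this nonsymmetric matrix, the implementation factorizes
$S_{XX}+\epsilon I = LL^\top$ and takes the symmetric eigendecomposition of
$L^{-1} S_{XY} (S_{YY}+\epsilon I)^{-1} S_{YX} L^{-\top}$ — the same
eigenproblem under a similarity transform, but symmetric, faster and
numerically better behaved. The canonical variables are then
re-orthonormalized by a Cholesky-based Gram–Schmidt pass in the
unregularized metric, which enforces the deflation constraints exactly. The
test suite cross-checks this solver against an independent whitening-SVD
CCA implementation (eigendecomposition inverse square roots on both sides
followed by an SVD) to $10^{-8}$ on correlations and $10^{-6}$ radians on
subspaces.

Degenerate inputs: zero-variance features are permitted (they contribute
nothing); a constant matrix, a rank-deficient covariance at `ridge = 0`, or
an identically zero residual are rejected with specific errors.

### Tunable quantities

| Parameter | Default | Meaning |
|---|---|---|
| `k` | — | shared canonical directions removed; `k = 0` reduces to PCA of the cases (exactly — this is a tested identity) |
| `k1` | 2 | residual components kept; the stratification score is one chosen column of the score matrix (in the motivating application, component 2) |
| `ridge` | `1e-8` | *relative* ridge: `ridge * trace(S)/n` is added to each sample covariance before inversion. A numerical stabilizer only — results are insensitive to it on well-conditioned data, and it scales with the data so all outputs are scale-equivariant |
| `center_features` | `FALSE` | optional per-feature pre-centering, recorded in the model |

### Conventions

Scores are defined as $X'^\top \hat U_1$ — unnormalized projections, not
unit-variance singular vectors — so that projecting new data is literally
"multiplying the coefficients by the same features". The fitted model's own
scores are computed by this same product (it equals $\tilde X^\top \hat U_1$
up to the numerical orthogonality of $\hat U_0$ and $\hat U_1$, at worst
$\sim 10^{-12}$ relative), which makes `predict(fit, X_training)` reproduce
the training scores exactly rather than to rounding. Each loading column's
sign is fixed by making its largest-magnitude entry positive (ties to the
lowest feature index), so runs and cohorts are comparable. Whether scores
should be variance-normalized before downstream association testing is left
to the analyst; the package deliberately returns the raw convention and
documents it.

## Choosing k by permutation

`select_k()` addresses the one structural choice. For each
$k = 0, \dots, k_{\max}$ it computes
$t(k) = \lambda_1(\tilde X_k) / \sum_j \lambda_j(\tilde X_k)$, the share of
residual case variance on the top residual component — the natural "is
there concentrated structure left?" statistic. Its null distribution comes
from pooling all samples and rerunning the *entire* pipeline on random
relabelings that preserve group sizes; this is exchangeable under the
no-case-specific-signal null, giving
$p(k) = (1 + \#\{t^\ast \ge t\})/(B + 1)$, with the usual resolution floor
$1/(B+1)$.

A large $t(k)$ alone does not prove the component is *case-specific*: at
small $k$ the top residual component may simply be shared variation that was
not yet removed. The procedure therefore also requires the variance of the
controls projected onto the top residual loading to be significantly
**small** against its own permutation null (lower-tail permutation p-value
$\le \alpha$). Under the null the relabeled "controls" contain true cases,
so a genuinely case-only component produces an observed control variance far
below its permutation distribution; a shared component does not. `chosen_k`
is the minimal $k$ passing both conditions — "minimal" because removing more
directions than necessary costs power.

Two design notes. First, one relabeling per permutation index is shared
across all $k$ (statistics for every $k$ are computed in a single pass per
relabeling, entirely in the pooled sample space from one Gram matrix — the
per-sample centering commutes with relabeling, which is what makes this
exact). This keeps a 200-replicate calibration study at
$m = 500, n = 100+100, B = 99, k_{\max} = 4$ to about three minutes on one
CPU, and guarantees that enlarging $k_{\max}$ never changes the results for
smaller $k$. Second, the two conditions are each tested at $\alpha$ with no
multiplicity adjustment across $k$; the selection is calibrated empirically
(the test suite measures the familywise rejection rate under the null at
3% for nominal $\alpha = 5\%$, comfortably within the accepted band) rather
than by a formal sequential-testing argument. The case-specificity condition
makes the procedure conservative; analysts who need strict familywise control
across many candidate `k` values should divide `alpha` accordingly.

## rPACA: more samples than features

Sample-space CCA is only defined for $m > \max(n_0, n_1)$; `fit_cca()` and
`select_k()` refuse otherwise and point to `rpaca()`. The randomized
extension restores the regime by subsampling: each of $R$ resamples draws
`subsample_size` case and control columns without replacement (equal group
sizes, to balance the CCA), fits PACA, and contributes its loadings.
Aggregation averages the projection operators
$U_1^{(r)} U_1^{(r)\top}$ and takes the top `k1` eigenvectors of the mean —
the canonical consensus subspace, immune to the sign/rotation ambiguity
that would corrupt a mean of raw loadings. With a single resample the
subsample's loadings are used directly, so the procedure reduces exactly to
one subsampled PACA fit projected to all cases (for `k1 > 1` the
eigenvectors of a single projector are defined only up to rotation, which
is why this case is special-cased). Everything is deterministic given
`seed`; the `consensus_stability` eigenvalues (in $[0,1]$) report how
consistently the resamples agree on the subspace.

## The simulator and what it does (not) emulate

`simulate_paca_data()` draws exactly from the factor model above: one
orthonormalized Gaussian basis split into $W_0$ and $W_1$ (guaranteeing
$W_0 \perp W_1$), Gaussian activities with per-factor standard deviations
`shared_scales` and `case_scales`, Gaussian noise. Since the $W$ columns
are unit-norm, "the shared variation dominates" is the single ratio
`shared_scales / case_scales`.

Default scales are `shared_scales = 70`, `case_scales = 7`, `sigma = 1` at
the default geometry $m = 1000$, $n_1 = n_0 = 200$. The rationale is
spiked-covariance detectability: a rank-one factor with activity standard
deviation $s$ on unit-norm loadings is recoverable from the sample
covariance only when $s^2/\sigma^2$ clears the Baik–Ben Arous–Péché
threshold $\sqrt{m/n} \approx 2.2$, and accurate recovery
($|r| \gtrsim 0.9$) needs a multiple of it; $s = 7$ gives
$s^2/\sigma^2 = 49$, i.e. a case factor carrying about 5% of the
per-feature noise variance — individually invisible, detectable in
aggregate — while the shared factors at $10\times$ that scale contribute
roughly $15\times$ the noise variance per feature and dominate every
leading PC, as cell composition does in whole-blood methylation. These
defaults were fixed from this reasoning, once, as the simulator's
definition of the regime of interest.

What the simulator does *not* attempt: bounded beta-value marginals (a
logistic `beta_squash` option exists but defaults off, since the model is
Gaussian), realistic probe-level variance heterogeneity, correlated probes,
cell-type reference structure, or ancestry admixture. Passing recovery and
calibration tests on these simulations therefore demonstrates correctness
of the algorithm under its own model assumptions — not performance on real
arrays, where feature pre-selection, normalization and the orthogonality
assumption all matter.

## Baselines and evaluation

`pca_baseline()` is PCA of the centered cases under identical conventions.
`cpca()` computes the top eigenvectors of $C_X - \alpha C_Y$; the package
uses it with an $\alpha$ grid ($\{0.1, 1, 10, 100\}$ is a reasonable
sweep) as the standing comparison for the cost of having a contrastive
hyperparameter: $\alpha \to 0$ collapses to PCA of the cases, very large
$\alpha$ chases the minimum-variance directions of the controls, and both
limits are verified against dense eigendecomposition oracles in the tests.
`recovery_score()` and `run_benchmark()` quantify recovery of simulated
ground truth (best $|r|$ per true factor, multiple $R^2$, principal
angles) and calibration rates, reproducibly from a master seed. A deep
generative baseline (contrastive VAE) is out of scope for this package.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run entirely on simulated data at
the sizes the package's own validation studies use: oracle equivalence at
$m = 200$, $n = 30 + 30$ over 20 draws; power at the simulator defaults
($m = 1000$, $n = 200 + 200$, 50 replicates); selection calibration on 200
null replicates at $m = 500$, $n = 100 + 100$ with 99 permutations and
$k_{\max} = 4$; rPACA at $m = 100$, $n = 400 + 400$ with 30 resamples of
60; cross-cohort transfer at the simulator defaults. The full suite
completes in a few minutes on a single CPU.

## Known limitations

- The orthogonality assumption is structural; correlated shared and
  case-specific directions bias the removal step.
- `select_k()`'s statistic and case-specificity condition are this
  package's operationalization of permutation-based rank selection for the
  removal step; other statistics (e.g. analytic Tracy–Widom rank tests)
  are deliberately out of scope.
- Inputs must be complete; there is no imputation and no array
  preprocessing. Matrices are expected already normalized on whatever scale
  (beta, M, expression) the analyst prefers.
- Scores are returned unnormalized; downstream regression layers (clinical
  interaction models, predictive models) are outside the package.
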