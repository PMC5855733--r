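---
title: "Predicting DNA methylation sites from sequence windows: models and methods"
author: "methylWave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA methylation sites from sequence windows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylWave)
```

## The problem

Cytosine methylation (5-methyl-cytosine) is strongly conditioned on the
local sequence context of the candidate site. methylWave predicts the
methylation state of a cytosine from a fixed-length DNA window centred on
it — 41 bp for database-derived benchmark windows, 201 bp for windows cut
around CpG sites called from single-cell bisulfite read counts. The model
is a binary kernel classifier over a hand-crafted 612-dimensional encoding
of the window.

## The encoding

Four extractors are concatenated, in a fixed order with stable feature
names, to encode a window of length $l+1$:

1. **k-gram counts (84)** — overlapping occurrence counts of every 1-, 2-
   and 3-mer, each block in lexicographic order. Counts are raw by default:
   all windows in one dataset share a length, so frequencies would only
   rescale columns, and the classifier standardizes columns anyway. A
   `normalize` flag exists for mixed-length corpora.

2. **Multivariate mutual information (30)** — tuple information over the
   10 canonical (sorted) 2-tuples and 20 canonical 3-tuples. A contiguous
   window of 2 or 3 bases contributes to the canonical tuple of its
   content, collapsing order; this is what yields exactly 10 + 20 tuple
   types. With $f$ the empirical frequencies over bases, adjacent
   2-windows and 3-windows respectively,
   $$I(N_1N_2)=f(N_1,N_2)\,\ln\frac{f(N_1,N_2)}{f(N_1)f(N_2)},$$
   $$I(N_1N_2N_3)=I(N_1N_2)
     +\frac{f(N_1,N_3)}{f(N_3)}\ln\frac{f(N_1,N_3)}{f(N_3)}
     -\frac{f(N_1,N_2,N_3)}{f(N_2,N_3)}\ln\frac{f(N_1,N_2,N_3)}{f(N_2,N_3)}.$$
   The three-way form is implemented exactly as defined here, although its
   second and third terms differ from the textbook interaction-information
   identity; the asymmetric roles of $N_1,N_2,N_3$ are resolved by always
   using the canonical sorted order. Natural logarithms are used, any term
   with a zero numerator or zero denominator contributes 0, and no
   pseudocounts are added by default (a `pseudocount` argument exists), so
   every feature is finite and exactly reproducible.

3. **Wavelet band statistics (312)** — each window is first mapped to its
   $l\times 6$ physicochemical matrix: row $i$ holds the six structural
   parameters (Twist, Tilt, Roll, Shift, Slide, Rise) of the dinucleotide
   at positions $(i, i+1)$, from a 16-row lookup that is
   reverse-complement symmetric. Each of the six property tracks is run
   through a 4-level discrete wavelet decomposition; per level the detail
   band contributes (max, min, mean, population sd), the approximation
   band the same four, plus the first five approximation coefficients —
   13 per level, 52 per track, 312 in total.

4. **Lagged autocovariance (186)** — for each track $PC_i$,
   $p_{i,\lambda}=\sum_{n=1}^{L-\lambda}(PC_i(n)-\overline{PC_i})
   (PC_i(n+\lambda)-\overline{PC_i})$ for $\lambda=0..30$, a raw sum with
   no $1/(L-\lambda)$ normalization. The upper limit is written $L-\lambda$
   so that the same 186 features are defined for 201-bp windows
   ($L = 200$); for the canonical 41-bp window ($L = 40$) this is exactly
   the defining formula. The lag-0 entry is $L$ times the population
   variance of the track.

### Numerical choices in the wavelet block

No wavelet family is inherent to the feature definition, so it is a
configuration key. The default is Haar (db1): its detail bands vanish
exactly on constant tracks, level-1 energy is conserved exactly on
dyadic-length signals, and every feature is homogeneous of degree one in
the signal — all of which make the block testable against closed forms.
Daubechies-4 is available as `wavelet = "db4"`. Boundary handling is
symmetric (whole-sample reflection by filter length − 1 on both sides),
the convolution is downsampled dyadically, and a length-$n$ band yields
$\lfloor (n + L_f - 1)/2\rfloor$ coefficients — a 40-value track gives
approximation lengths 20, 10, 5, 3 across the four levels. Approximation
bands shorter than five coefficients are zero-padded on the right, keeping
the dimensionality fixed at 312 for every window length. Standard
deviations are population ($1/n$) throughout.

## Dataset assembly

Windows can be supplied directly (FASTA with labels in the identifiers) or
cut from a reference genome around a site table (chromosome, 1-based
position, methylated reads, total reads). Sites with fewer than 4 reads
are discarded; a kept site is methylated iff methylated reads outnumber
unmethylated reads, and exact ties are discarded as ambiguous — the
majority rule defines neither label for them, so dropping is the
conservative reading. Windows must lie fully inside their chromosome and
(by default) have C at the centre; violations are skipped and reported.
Strand is assumed '+' throughout, since site tables in this dialect carry
no strand column.

Exact within-class duplicates are collapsed and any sequence appearing in
both classes is removed from both sides. Similarity-based redundancy
reduction (CD-HIT-style greedy clustering at a similarity threshold) is
deliberately out of scope: `deduplicateWindows()` accepts an externally
produced representative list instead.

Class imbalance is handled by SMOTE in feature space: each synthetic row
is $x + u\,(x_{nn}-x)$ with $u\sim U[0,1]$ and $x_{nn}$ one of the $k=5$
nearest minority neighbours by Euclidean distance. Interpolation of
discrete sequences is undefined, so synthetic rows carry no sequence or
coordinates; they are flagged `origin = "synthetic"`, which is what the
evaluation protocol keys on.

## The classifier

The core model is a sparse Bayesian kernel classifier (a relevance vector
machine with logistic likelihood): $P(y=1\mid x)=\sigma\!\big(b+\sum_m w_m
K(x, x_m)\big)$ over Gaussian kernel basis functions centred on training
rows, with an independent zero-mean Gaussian prior per weight. Each outer
iteration finds the posterior mode by Newton/IRLS (a Laplace
approximation), then re-estimates each prior precision as
$\alpha_m \leftarrow \gamma_m / w_m^2$ with
$\gamma_m = 1-\alpha_m\Sigma_{mm}$; basis functions whose precision
crosses $10^9$ are pruned. What survives — typically well under 20% of the
training rows — are the relevance vectors.

Implementation notes, all of them configuration keys or documented
behaviour:

* **Standardization.** Features are standardized to training-set mean and
  unit variance before the kernel (constant columns are mapped to zero).
  The four blocks live on wildly different natural scales — integer counts
  versus summed autocovariances of rise values — and a Gaussian kernel is
  scale-sensitive. The parameters are stored in the model and applied at
  prediction time.
* **Kernel width.** Default is the median pairwise Euclidean distance
  between standardized training rows, overridable with `sigma`.
* **Iteration budget.** The precision re-estimation is capped at 5000
  rounds (`maxIter`); convergence is declared when the largest log-change
  of surviving precisions falls below `tol = 1e-6`. Hitting the cap
  returns the current model with a warning recorded on it.
* **Stabilisation.** Plain $\gamma/w^2$ re-estimation can fall into
  period-two limit cycles. When progress stalls the update is damped in
  log space with a geometrically decreasing step, which collapses cycles
  onto their fixed point; diverging precisions are never damped, so
  pruning is not delayed. Basis functions that are numerically dead
  (precision above $10^4$ with $|w| < 10^{-4}$) are pruned early — on the
  MacKay update dynamics they cannot re-enter, and carrying them through
  the expensive early rounds only costs time. The bias column is never
  pruned; its precision is pinned at the pruning threshold instead of
  being allowed to diverge and reset.

`trainSVM()` wraps an e1071 (libsvm) Gaussian-kernel soft-margin SVM with
Platt-scaled probabilities behind the identical
standardize/train/predict contract — this stage is deliberately
non-bespoke — so the two model types are interchangeable in every
pipeline, including the evaluators and feature selection.

## Evaluation protocols

`confusionMetrics()` computes ACC, sensitivity, specificity and Matthews
correlation from the pooled confusion table, with MCC defined as 0 when
its denominator vanishes. `rocAuc()` sweeps all distinct score thresholds;
the trapezoidal area equals the Mann–Whitney statistic with ties counted
one half, so the AUC is stable under score permutations.

**Target-jackknife cross-validation** is leave-one-out restricted to real
samples: every real sample is held out once and predicted by a model
trained on the remaining rows, real and synthetic alike; SMOTE rows only
ever train. The number of train/predict rounds therefore equals the
number of real samples, and predictions are pooled into a single
confusion matrix (matching single-number reporting) rather than averaged
per round.

**Chromosome-parity holdout** routes samples on chromosomes 1, 3, 5, 7,
9, 11 into training and 2, 4, 6, 8, 10, 12 into testing; anything else
(chrX, chr13+, missing coordinates) is excluded and reported. This is the
affordable protocol for corpora too large to jackknife.

## Feature selection

`importanceScores()` trains one linear-kernel soft-margin SVM on the
standardized table and scores feature $j$ by $|w_j|$ from the primal
hyperplane — a single fit, not recursive elimination, matching a single
importance score per feature; constant columns score 0.
`incrementalSelection()` then evaluates nested prefixes of the ranking
with a cross-validated accuracy evaluator and returns the arg-max prefix
together with its per-block composition. The default evaluator is 5-fold
CV with the SVM; a target-jackknife evaluator can be injected where full
protocol fidelity matters and the corpus is small. By default every
dimension up to 200 is evaluated and a stride of 10 beyond — the region
where accuracy curves on this kind of encoding plateau and then decay —
with `dims` available for full resolution.

## The synthetic fixture generator

`simulateWindows()` emulates the two window classes so every stage is
testable without external data. Positives differ from negatives both
compositionally and physicochemically: a 6-mer consensus (`ACGCGT`)
planted immediately downstream of the central C with per-position match
probability 0.9, and a +0.10 shift in G+C fraction. The G+C shift moves
every dinucleotide property track, so all four feature blocks carry
signal — necessary for feature selection across blocks to be a meaningful
exercise. All windows are centred on C; class sizes default to 200 + 200, a corpus
small enough to jackknife with the sparse Bayes model in a few minutes.
The null configuration (`gcShift = 0, motifMatchProb = 0`) makes the
classes exchangeable by construction.

A note on verifying the null: the pooled target-jackknife AUC at the
200 + 200 scale is a noisy estimator under exchangeability — its
held-out scores come from 400 nearly identical models, and empirically
its seed-to-seed standard deviation is about 0.06, too wide to resolve a
±0.05 band around chance. The package's null calibration therefore
trains the same pipeline on the 200 + 200 null corpus and scores an
independent 1000 + 1000 null corpus, whose AUC standard error
(≈ 0.013) makes the chance band a test of systematic bias rather than
of seed luck. The planted-signal check keeps the jackknife protocol,
where the question is whether strong signal is recovered, not whether a
tight band is hit. `simulateMethylome()`
additionally emits a 12-chromosome toy genome with Poisson read depths
and latent per-site methylation states that round-trips through site
labeling, window extraction and the parity holdout.

What the generator does **not** emulate: bisulfite conversion errors,
read-mapping biases, CpG-island spatial structure, strand asymmetries and
the long-range dependence of real methylomes. Passing the planted-signal
and null checks therefore demonstrates that the pipeline recovers signal
that is present and reports chance when it is absent — not that any
particular accuracy will be attained on real data.

## Reproducing the published experiments

The corpora this kind of predictor is benchmarked on — methylation
databases yielding labeled 41-bp windows, and single-cell bisulfite
(scBS-seq) CpG calls against a reference genome yielding 201-bp windows —
are external and not redistributable here, so no benchmark accuracy on
them is asserted by this package's tests. Every experimental protocol a
benchmark would use — SMOTE to parity then target-jackknife with pooled
metrics; chromosome-parity holdout; SVM-weight ranking with incremental
selection and per-block composition reporting — is implemented and
exercised on synthetic stand-ins, so a user who supplies such data
reproduces the experiment designs directly, with `scripts/acceptance.R`
as a template.

## Known limitations

* Eq-style three-way MMI is kept exactly as defined (see above), so these
  30 features should be read as a fixed nonlinear functional of tuple
  frequencies rather than textbook interaction information.
* The RVM's Laplace/evidence iteration is a local optimisation; different
  kernel widths can yield different relevance-vector sets. Width and all
  thresholds are recorded in the model object.
* SMOTE in 612-D feature space produces rows without sequences; pipelines
  that need sequences for synthetic samples (e.g. motif inspection) must
  regenerate them by other means.
* Strand handling is minimal: '+' is assumed, with reverse-complementing
  left to dataset assembly if needed.
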