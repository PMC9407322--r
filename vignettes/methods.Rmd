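---
title: "Methods: spectral defect detection with oversampling and MRSA-tuned SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral defect detection with oversampling and MRSA-tuned SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdefect)
```

This vignette is the package's own account of its models and the design
choices behind them. The workflow it implements classifies dried fruit into
three states — normal (NM), starch-head (SH) and mildewed (MD) — from
Vis-NIR diffuse reflectance spectra, with four stages wrapped by
`run_experiment()`: scatter correction, minority oversampling, wavelength
selection, and SVM parameter search by a modified reptile search algorithm.

## The synthetic spectra generator

Real spectra of this kind are rarely deposited, so the package ships a
generator that reproduces the *statistical structure* the workflow has to
cope with rather than the physics of any instrument. Each sample of class
$c$ is

$$ x_i(\lambda) = (1 + a_i)\,b_i(\lambda) + o_i + \varepsilon_i(\lambda), $$

where $b_i(\lambda)$ is a per-sample base curve — a logistic "red edge" rise
over 600–750 nm on a low visible-range floor, minus Gaussian absorption dips
centred at 890 nm (C–H third overtone) and 990 nm (O–H second overtone,
moisture) — and $a_i \sim U(\pm 0.15)$, $o_i \sim U(\pm 0.02)$ are
multiplicative/additive scatter coefficients. Class structure enters through
the base curve: amplitude ordered NM (1.00) > SH (0.82) > MD (0.68), and
class-specific dip depths and red-edge positions drawn per sample from
centred-uniform distributions (`CLASS_SHAPE` in the source). Defaults are the
study conditions: 200/302/98 samples per class, 934 bands over 400–1100 nm,
and a 7:3 stratified split that yields 140/211/69 training and 60/91/29 test
samples.

Two generator decisions matter and were made once, on first principles:

* **Dip depths are not scaled with the class amplitude.** A purely
  amplitude-scaled template is an affine distortion of the shared shape, and
  MSC — the pipeline's own preprocessing — removes affine distortions
  exactly, which would leave the corrected classes indistinguishable. In real
  fruit the chemistry (relative water-band depth) survives scatter
  correction; the generator reproduces that by keeping dip depths absolute.
* **SH and MD dip-depth ranges overlap; NM is separated.** Starch-head fruit
  is the precursor of mildew, and their spectra overlap strongly, while
  normal fruit is comparatively distinct. The per-sample uniform jitter
  (widest for MD, which also gets double scatter range and the largest noise
  SD) reproduces exactly this: near-perfect NM recall, depressed MD recall
  under class imbalance, and a visible benefit from balancing the training
  set. These widths were fixed when the generator was written and are not
  tuned per experiment.

What the generator does **not** emulate: instrument noise spectra, detector
edge artefacts, wavelength-dependent noise, moisture/chemistry forward
models, or any radiative-transfer physics. Passing tests on synthetic data
therefore demonstrate that the pipeline's *mechanics* are correct (balancing
helps minority recall under overlap, CARS finds informative bands, MSC
removes scatter) — not that any particular accuracy will be reached on real
spectra.

## Preprocessing

`crop_wavelengths()` keeps a closed wavelength window (default 400–1100 nm;
detector edges are noisy). `msc_fit()` computes the MSC reference as the
column mean of the *training* reflectance only, and the same reference is
reused for the test set — the alternative (a reference over all samples)
leaks test information into preprocessing, so training-only is the default
even though either convention is common in practice. `msc_apply()` solves
the per-spectrum least squares $x = a + b\,r$ in closed form and returns
$(x - a)/b$; a spectrum with $|b| < 10^{-8}$ (essentially flat) is passed
through unchanged with a warning rather than amplified by a near-zero
division. MSC runs after cropping so the regression covers exactly the
modelled bands.

## Oversampling

All four methods balance each minority class up to the majority count,
treating the union of other classes as "majority" for neighbour
calculations, with Euclidean distances on the preprocessed features and
k = 5 neighbours throughout. Synthetic SMOTE-family points are
$x + \lambda(x_{nn} - x)$ with $\lambda \sim U[0, 1)$ and $x_{nn}$ one of
the k same-class nearest neighbours, so every synthetic point lies on a
segment between two real same-class points. Borderline-SMOTE implements the
*borderline-1* variant: a minority sample with $m'$ of its m all-class
neighbours in other classes is noise ($m' = m$), danger
($m/2 \le m' < m$) or safe; only danger samples seed interpolation, and the
partners still come from the same minority class. If a class has no danger
samples at all the implementation falls back to plain SMOTE seeds with a
warning (the alternative — generating nothing — would silently break the
balance contract). ADASYN allocates per-sample quotas
$g_i = \mathrm{round}(\hat r_i G)$ from normalized difficulty ratios, then
trims or pads the rounding slack so the class lands exactly on the majority
count, keeping all four methods size-comparable. Oversampling applies to the
training set only, after MSC and before wavelength selection; the selection
stage therefore sees the balanced design it will model.

## Wavelength selection

**CARS.** At Monte-Carlo run $i$ of $N$, a PLS model (one-hot class
indicators, coefficients decoded by argmax) is fitted on a random 80%
calibration subset restricted to the currently retained bands; bands are
weighted by summed absolute regression coefficients; the exponentially
decreasing function fixes the retention count ($a = (p/2)^{1/(N-1)}$,
$k = \ln(p/2)/(N-1)$, so run 1 keeps all $p$ bands and run $N$ keeps 2);
adaptive reweighted sampling then draws that count with replacement,
weight ∝ coefficient magnitude. Each run's subset is scored by 5-fold CV
misclassification of the PLS-DA decoder, with the component count chosen
inside the same CV pass (capped at min(10, bands − 1)); the minimal-error
subset wins, ties to the smaller subset. Because the task is classification
and PLS is a regression method, the one-hot/argmax encoding is a design
choice; it is the standard discriminant-analysis reading of PLS.

**SPA.** Forward chains of minimally collinear bands grow from candidate
start columns by successive orthogonal projections (a duplicated column has
zero residual norm and can never be selected twice). Scoring every
(start, cardinality) pair with the downstream SVM would cost thousands of
cross-validated fits, so scoring is split: chain prefixes are screened per
cardinality by a fast linear least-squares classifier CV, and only the
per-cardinality winners (cardinalities 5–20 by default) are scored with the
5-fold CV of the downstream RBF-SVM; ties go to fewer bands. Candidate
starts default to the 30 largest-norm columns — on highly collinear spectra
additional starts converge to near-identical chains.

## Optimizers

`rsa_minimize()` implements the canonical reptile search algorithm: the four
update strategies on the quarter-iteration schedule, box clipping, and
monotone best-so-far bookkeeping; `mrsa_minimize()` adds Tent chaotic
initialization and the Gaussian random walk and reduces *exactly* to RSA
when both are switched off (an equivalence the tests assert trace-for-trace).
Printed formulations of this algorithm family contain two ambiguities that
needed a decision:

* The evolutionary sense is sometimes printed as $2 r_3 (1 - 1/T)$ — a
  constant — while being described as decreasing over iterations. The
  default here is the behaviourally described $ES(t) = 2 r_3(1 - t/T)$;
  `es_variant = "printed"` gives the literal constant.
* $r_3$ described as a "random integer between −1, 1" would collapse ES onto
  three values; the default draws a continuous uniform on $[-1, 1]$, with
  `r3_integer = TRUE` for the literal reading.

Other numerical choices: out-of-box positions are clipped to the nearest
bound (preserves geometry relative to the best solution); the per-candidate
mean $M(x_i)$ is the mean over dimensions; the random-walk step scale
$\tau = (\log G / G)(x_i - \mathrm{Best})$ is read as a per-dimension
standard deviation with its sign discarded, and $\mathrm{Normal}(\mu, 0)$
degenerates to $\mu$ exactly (so at $G = 1$, where $\log 1 = 0$, the walk is
purely the deterministic attraction term). The walk's greedy acceptance runs
inside every iteration by default (`grw = "after_search"` restricts it to a
single post-loop application). Tent-map orbits hitting the absorbing values
{0, ½, 1} are re-seeded with a fresh uniform draw, since those orbits
collapse to 0 and would waste population slots. Non-finite objective values
become $+\infty$ with a warning. The GA baseline is real-coded (tournament
size 2, BLX-0.5 crossover at rate 0.9, per-gene Gaussian mutation at rate
0.1 with SD 10% of the range, elitism 1); PSO is global-best with inertia
0.9 → 0.4, $c_1 = c_2 = 2$ and velocities clamped to half the box range.
Defaults everywhere: population 20, iterations 50, $\alpha = \beta = 0.1$,
$\varepsilon = 10^{-10}$.

## SVM, tuning fitness, PLS-DA

The classifier is a one-vs-one RBF-SVM, $K(u, v) = e^{-g\|u - v\|^2}$, with
both the penalty $c$ and kernel width $g$ searched in $[2^{-2}, 2^{8}]$ and
$g$ used directly as the kernel coefficient. Features enter on their native
reflectance scale, *not* standardized: MSC already places spectra on a
common scale, and on standardized features the squared distances grow like
twice the feature count, which pushes the entire printed $g$ box into the
degenerate regime where the kernel matrix is effectively the identity and
every parameter choice reduces to majority voting. On raw MSC-corrected
spectra the box brackets the median-heuristic width ($g \approx$ 1/median
pairwise squared distance), so the search surface is informative. For the
same reason the pipeline's fixed-parameter default (`optimizer = "none"`) is
$c = 10$, $g = 16$.

The tuning fitness is mean held-out accuracy over seeded stratified 5-fold
CV. The fold assignment is created once per tuning run and shared across
every fitness evaluation, so (a) the fitness is deterministic, which the
optimizers' greedy steps require, and (b) different optimizers on the same
seed are compared on identical folds — a paired comparison with reduced
noise. The internal objective is $1 - \mathrm{accuracy}$ (all optimizers
minimize); reported traces convert back to accuracy. PLS-DA fits one-hot
responses, chooses the latent-variable count (≤ 15, capped at the feature
rank with a warning) by the same stratified CV, and decodes by argmax.

## Evaluation conventions

`report()` derives per-class recall (= per-class accuracy), precision and F1
from one-vs-rest marginals of the confusion matrix, with macro metrics as
unweighted class means. A class never predicted has undefined precision; it
is reported as 0 with a warning so macro means stay defined. Two kappas are
reported. `kappa_cohen()` is the standard row/column-marginal chance
correction. `kappa_paper()` takes the observed agreement to be the overall
accuracy and the chance agreement from the *pooled one-vs-rest marginals*,
which for K classes is the constant $(1 + (K-1)^2)/K^2$ — 5/9 for three
classes, giving $\kappa = (9 p_0 - 5)/4$. This convention is common in the
applied spectroscopy literature when binary formulas are applied per class
and pooled; reporting both makes results comparable in either direction.
Internally everything is kept at full precision; percentages are rounded
half-up to two decimals only at the printing boundary.
`total_from_per_class()` inverts per-class percentage tables into integer
correct counts (round half-up) before pooling, which is how per-class and
total accuracies reconcile in such tables.

## Pipeline and reproducibility

`run_experiment()` chains simulate/load → crop → stratified split → MSC
(reference from training rows) → oversample(train) → select(train) → tune →
train → evaluate(test); test rows are touched exactly once, by the final
prediction. The master seed derives a fixed per-stage sub-seed
(`derive_seed()`), so changing the oversampler cannot shift the simulated
data or the split — paired comparisons stay paired. Configurations are plain
R lists or YAML (`read_experiment_config()`), and unknown keys are errors
rather than silent typos.

## Problem sizes used by the test suite

The tests exercise every property at reduced scale chosen to keep the suite
fast while leaving each effect clearly measurable: optimizer benchmarks at
the default 20×50 budget over 20 seeds; CARS informative-band recovery on
120 × 30 designs over 20 seeds; the CARS-versus-full-spectrum comparison and
the oversampling-helps-minority-recall experiment on 300-sample, 100–150
band simulations over 10 paired seeds. The full study-scale configuration
(600 × 934, CARS 50 runs, MRSA 20 × 50) runs end to end in a few minutes
and is exercised through the README example rather than the unit tests.

## Known limitations

SPA's two-phase scoring is an approximation of exhaustive downstream-model
scoring; on data where the linear screen is badly misaligned with the SVM
ranking it can miss the best chain. CARS assumes the PLS coefficient
magnitude ranks band utility, which degrades under extreme collinearity
among informative bands. The borderline fallback means "borderline"-SMOTE
quietly behaves like SMOTE on well-separated classes (a warning is issued).
The generator's uniform jitter model produces box-shaped class overlap
rather than the smooth tails of real biological variation, so real-data
recall curves will differ in shape even when the qualitative ordering of
methods transfers.
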