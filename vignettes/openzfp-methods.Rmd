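---
title: "Predicting OPEN-targetable zinc finger sites: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting OPEN-targetable zinc finger sites: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openzfp)
```

## The problem

OPEN (Oligomerized Pool ENgineering) assembles three-finger C2H2 zinc
finger arrays from pre-built finger pools, one pool per 3-bp triplet
subsite of a 9-bp DNA target, and selects binders in a bacterial
two-hybrid reporter. Selection succeeds for some target sites and not
for others, and an attempt is weeks of bench work. The question this
package answers is: *given only the 9-bp sequence, how likely is an
OPEN selection against it to succeed?* A site is called **active** when
at least one selected array drives at least three-fold reporter
activation, **inactive** otherwise; those labels, attached to
experimentally attempted sites, are the training signal.

## The classifier

The core model is a categorical naive Bayes classifier. A site is
encoded in one of three ways:

* **sequence identity** — nine nominal attributes, the base at each
  position 5'→3' (arity 4 each);
* **base counts** — four attributes, the number of G, A, C and T in the
  site (treated as nominal with arity 10: values 0–9);
* **positional base counts** — twelve attributes, how many of the three
  triplets carry each base at their 1st, 2nd and 3rd internal position
  (nominal, arity 4: values 0–3).

With class prior \(P(c) = (n_c + \alpha)/(N + 2\alpha)\) and
conditionals \(P(v \mid c) = (n_{v,c} + \alpha)/(n_c + k\alpha)\)
(\(k\) the attribute arity), the active posterior is Bayes' rule over
the attribute product, accumulated in log space and renormalized.
Treating the count encodings as *nominal* rather than Gaussian-numeric
is a deliberate choice: the arities are tiny (≤ 10), a categorical
table needs no distributional assumption, and smoothing keeps every
probability positive. The pseudocount `alpha` defaults to 1 (add-one
smoothing, the common default for nominal attributes) and is exposed
because published accuracy figures for this kind of classifier are
sensitive to the smoothing convention; `alpha = 0` is allowed
explicitly for users who want unsmoothed maximum-likelihood tables.

A site with posterior ≥ 0.5 is called active (the tie sits on the
active side by definition of the decision rule). For ranking, the
posterior maps to a **confidence score**: `floor(|p − 0.5| / 0.05)`
capped at 9, so each 0.05 of posterior beyond the midpoint adds one
unit (0.75 → 5 on the active side, 0.25 → 5 on the inactive side). An
epsilon of 1e−9 inside the floor guards exact multiples of 0.05 against
binary floating-point representation (0.55 must score 1, not 0).

## The SVM protocol

As a cross-check on the naive Bayes model, the package wraps an
RBF-kernel support vector machine (the `e1071`/libsvm solver with Platt
probability calibration — the solver is deliberately an external
dependency; the protocol around it is the package's). Because site
collections are typically imbalanced (roughly four active sites per
inactive one), each prediction averages calibrated probabilities from
`k = 10` class-balanced training subsets: every subset keeps all
minority-class sites plus an equal-size uniform draw of majority sites.
Hyperparameters come from a grid search (defaults
cost \(2^{-5}..2^{15}\), gamma \(2^{-15}..2^3\), step \(2^2\), standard
libsvm-guide practice; 5 stratified internal folds) maximizing the
Matthews correlation coefficient of pooled fold predictions; folds that
degenerate to one class are skipped. Ties break toward smaller cost,
then smaller gamma. All randomness — subset draws, fold assignment, the
solver's internal calibration CV — flows from explicit integer seeds,
and the calibration RNG is reset per subset so identical subsets give
identical estimates.

## Evaluation

Leave-one-out cross-validation refits on \(N-1\) sites for each
held-out site (for naive Bayes this is done by decrementing the count
tables, which is arithmetically identical to refitting and is verified
against literal refits in the test suite). The pooled held-out
posteriors give a single ROC curve and AUC per run — pooling is the
only construction that yields one curve from a leave-one-out design.
AUC is computed in the tie-aware Mann–Whitney form (ties count half);
the trapezoidal area under the ROC points serves as an independent
oracle in the tests, not as the implementation. Reported measures are
accuracy, Matthews correlation (CC), specificity+ (precision),
sensitivity+ (recall), FPR and TPR; degenerate 0/0 denominators are
reported as `NA`, never coerced to 0 or 1, because silent coercion
inflates scores on small strata.

Two threshold policies are provided, because "optimized for correlation
coefficient" can mean either: the default fixed θ = 0.5, and
`optimize_cc = TRUE`, which scans midpoints between adjacent distinct
pooled posteriors (plus 0 and 1) and takes the smallest θ maximizing
CC. The optimized θ is an in-sample choice on the same pooled
posteriors and is therefore optimistic; hold-out evaluation
(`evaluate_holdout()`) defaults to the fixed rule. Hold-out evaluation
refuses overlapping train/test sequences and can stratify its report by
confidence score (at or above a cutoff versus below), the intended
usage pattern: act on high-confidence calls first.

## Target space and scanning

The targetable 9-mer space is the Cartesian product of the three pool
lists. The shipped default configuration has the published pool *sizes*
— 26, 21 and 23 triplets, hence 26·21·23 = 12,558 enumerable sites —
with all 16 GNN triplets plus provisional TNN placeholders for the
unpublished remainder (clearly marked in the file; replace it with a
real inventory for production scanning). Sites containing a dam (GATC)
or dcm (CCAGG/CCTGG) motif are excluded as untargetable in the
bacterial selection host; the motif set is closed under reverse
complement, so a forward-strand substring search covers both strands.
The filter is applied within the 9-bp half-site by default — pool-space
counts must be context-free — with an option to extend it across the
full scanned window including the spacer.

A ZFN site is two 9-bp half-sites in inverted orientation around a
5–7 bp spacer. In forward-strand coordinates a full site is
`left(9) + spacer + right(9)`; the two array targets are
`reverse_complement(left)` and `right`, pointing 5'-ends-inward so the
FokI fusions dimerize over the spacer. This construction is
strand-closed — scanning a sequence and its reverse complement yields
the same unordered half-site pairs — so the scanner reads one strand
only (a property the test suite asserts on random sequences). Pair
counts are reported as ordered pairs (\(n^2\) for \(n\) usable
half-sites), matching the convention under which 12,143 half-sites give
147,452,449 nuclease sites; the square-root-free unordered count is
implied and not separately tabulated. Coordinates are 0-based
internally and 1-based (first base of the full site) in reports.
Windows containing `N` are skipped. When a classifier and
`min_confidence` are supplied, a hit is kept only if *both* half-sites
are predicted active (posterior ≥ 0.5) with confidence at or above the
cutoff — an inactive call with high confidence is a confident *failure*
prediction and would be perverse to keep.

## The synthetic generator

`simulate_sites()` draws sites uniformly (with replacement, as genomic
candidate lists repeat) from the pool product and labels them by a
logistic model: \(P(\text{active}) = \text{logistic}(\beta_0 + \beta_T
\cdot \#T + \text{positional bonus})\). This is the simplest generative
family consistent with the dominant empirical signal — thymine content
depresses success at every triplet position — and it is synthetic: it
makes no claim about OPEN chemistry. Defaults are chosen once to mirror
realistic study conditions: `beta_t = -0.5` (a mild penalty), an
expected active fraction of 0.79 matching the class balance of real
validated collections (the intercept is solved by bisection so the
*expected* fraction over the drawn sites hits the target), and the
shipped pool configuration. `generate_benchmark()` produces
sequence-disjoint train/test pairs from one model, mirroring a
cross-validation set plus an independent test set.

What passing tests on synthetic data do and do not show: they verify
direction recovery (fitted posteriors decrease with thymine count),
chance-level AUC under a null generator, and AUC approaching the
model's ceiling under strong signal — but real OPEN outcomes carry
position-specific and triplet-identity structure the one-parameter
thymine model does not, so synthetic performance says nothing
quantitative about accuracy on laboratory data.

One quantitative note on attainable discrimination: under the logistic
thymine-count model the Bayes-optimal classifier is a monotone function
of thymine count alone, and its AUC is fixed by the T-count
distribution of the pool space (standard deviation 1.10 under the
shipped pools). Computed exactly over the enumeration, the ceiling is
0.758 at \(\beta_T = -0.5\)…\(-1.0\) spans 0.645–0.758 and only reaches
≈ 0.88 at \(\beta_T = -2\). Cross-validated classifiers on finite
samples sit a few points below the ceiling. The package's property
tests therefore probe the strong-signal regime at \(\beta_T = -2\).

## Numerical and scale choices

Posterior products are accumulated in log space with a max-shift before
renormalization. Model files store integer sufficient statistics, not
probabilities, so a reloaded model reproduces posteriors bit-identically
through the same smoothing arithmetic. Test-suite problem sizes —
leave-one-out at n = 200–500, ten seeds per stochastic property, 100
planted-site constructions, 1000 fuzzed score sets for the AUC
equivalence — were chosen to keep the full suite under two minutes on a
laptop-class single core while leaving comfortable statistical margins.

## Known limitations

* The shipped pool file's TNN identities are placeholders; pool-content
  dependent counts (methylation-excluded sites, predicted-active
  fractions of the target space) are only meaningful with a real
  inventory.
* The classifiers see only the 9-bp site: no chromatin, no flanking
  context, no spacer sequence effects.
* Confidence scores inherit the classifier's calibration; naive Bayes
  posteriors are typically overconfident, so scores order sites well
  but are not frequency-calibrated success probabilities.
* Transcript/exon bookkeeping for genome-wide scans is out of scope;
  the scanner works on whatever FASTA records it is given.
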