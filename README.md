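# openzfp

Deciding which DNA sites are worth attempting with **OPEN** (Oligomerized
Pool ENgineering) of C2H2 zinc finger arrays.

A three-finger zinc finger protein (ZFP) recognizes a 9-bp DNA site, one
finger per 3-bp triplet subsite. OPEN builds such arrays combinatorially
from pre-constructed finger pools and selects binders in a bacterial
two-hybrid reporter — but selection does not always succeed, and each
attempt is expensive. Sequence composition of the 9-bp site carries most
of the predictable signal: thymine-rich sites fail far more often.
`openzfp` provides, for experimentalists planning OPEN selections and
zinc finger nuclease (ZFN) designs:

* a **categorical naive Bayes classifier** over three site encodings
  (sequence identity `p1..p9`; base counts of G,A,C,T; positional base
  counts per triplet-internal position), trained on labeled 9-bp sites
  and returning `P(active | site)` via Bayes' rule with Laplace
  smoothing (`alpha = 1` by default):
  `P(c | x) ∝ P(c) · Π_j P(x_j | c)`;
* a **0–9 confidence score**: one unit per 0.05 of posterior beyond the
  0.5 decision midpoint (posterior 0.75 → active with confidence 5,
  0.25 → inactive with confidence 5), for ranking candidate sites;
* a **balanced-resampling RBF SVM protocol** (class-balanced training
  subsets, calibrated probabilities averaged over subsets) for
  imbalanced site collections, with CC-driven grid search;
* **evaluation drivers**: leave-one-out cross-validation, independent
  hold-out evaluation with confidence stratification, accuracy /
  Matthews correlation / specificity+ / sensitivity+ / FPR / TPR,
  tie-aware Mann–Whitney ROC AUC;
* **target-space combinatorics**: enumeration of the pool-product 9-mer
  space, dam/dcm methylation exclusion (GATC, CCAGG/CCTGG), and ordered
  ZFN pair counts;
* a **ZFN scanner** that finds inverted half-site pairs around 5–7 bp
  spacers in FASTA sequences and scores both half-sites;
* a **synthetic site generator** (logistic thymine-penalty activity
  model) so the whole pipeline is testable without laboratory data.

Everything is tidyverse-native: site tables are tibbles, results have
`tidy()` / `glance()` methods and ggplot2 `autoplot()`.

## Worked example

```r
library(openzfp)

# a synthetic benchmark: 135 training and 140 disjoint test sites from
# the logistic thymine-penalty model
bench <- generate_benchmark(135, 140, seed = 20, beta_t = -2)

loocv_nb(bench$train, encoding = "identity")
#> <zf_eval> 135 sites, theta = 0.5 (fixed)
#>   accuracy 0.830 | cc 0.364 | specificity+ 0.846 | sensitivity+ 0.963
#>   AUC 0.842 | TP 104 FP 19 TN 8 FN 4

predict(nb_fit(bench$train), zf_sites(c("GAAGGGGCC", "TTTGTTTAT")))
#> # A tibble: 2 × 5
#>   sequence  id    posterior_active predicted confidence
#> 1 GAAGGGGCC <NA>            0.986  active             9
#> 2 TTTGTTTAT <NA>            0.0788 inactive           8

summarize_target_space(default_pool_config(), model = nb_fit(bench$train))
#> # A tibble: 1 × 6
#>   n_enumerable n_methylation_excluded n_targetable n_predicted_active …
#> 1        12558                    124        12434              10940
```

Reading the output: leave-one-out accuracy 0.830 means 83% of held-out
sites were classified correctly at the 0.5 threshold; AUC 0.842 is the
probability a random active site outscores a random inactive one. The
two predicted sites illustrate the thymine effect — the G-rich site is
called active with the top confidence score, the T-rich site inactive.
The target-space summary enumerates the 26×21×23 = 12,558 sites
reachable with current pool sizes, removes dam/dcm-methylated ones, and
counts how many the classifier expects to work. (The shipped pool file
reproduces the published pool *sizes*; its TNN triplet identities are
placeholders, documented in the file, so the methylation-excluded count
depends on the true pool lists.)

Real training data are loaded with `read_sites("sites.tsv")` — a
headered TSV/CSV with `sequence` and `label` (active/inactive) columns.

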