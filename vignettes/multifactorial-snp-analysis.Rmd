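---
title: "Multifactorial gene-gene interaction analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactorial gene-gene interaction analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxgtools)
```

## The problem

Candidate-gene case-control studies genotype a modest panel of biallelic
SNPs — here, 18 tag SNPs in four DNA damage-repair genes (*BLM*, *WRN*,
*ERCC6*, *OGG1*) in 789 age-related cataract cases and 531 controls — and
ask two questions: does any single locus shift disease risk, and do
combinations of loci interact in ways that single-locus tests miss?
Individual variants of complex diseases typically carry weak marginal
effects (per-allele odds ratios of 1.1–1.5), so the package pairs a
conventional single-locus scan with three multifactorial methods that
trade parametric structure for the ability to see joint effects:
multifactor dimensionality reduction (MDR), classification-and-regression
-tree (CART) risk partitioning, and an unweighted genetic risk score
(GRS). A synthetic genotype generator makes every stage testable without
individual-level study data.

## Data model

Genotypes are coded as minor-allele counts (0/1/2, `NA` missing); the
manifest — not observed frequency — fixes which allele is minor, so a
case-enriched allele can never flip orientation between groups. Cases may
carry a cataract-subtype label (cortical, nuclear, posterior subcapsular,
mixed); subtype strata always compare one subtype's cases against the full
control group. Missing genotypes are excluded pairwise per statistic — the
simplest defensible rule for a panel with sparse missingness; no
imputation is attempted.

Quality control is the usual control-group Hardy-Weinberg screen: a 1-df
chi-square goodness-of-fit test of the control genotype counts against the
proportions implied by the sample allele frequency, at $\alpha = 0.05$.
Controls only, because a genuine association legitimately distorts HWE in
cases. The chi-square flavour (rather than the exact test) with
$\alpha = 0.05$ reproduces the study's published screening outcome — one
SNP excluded, seventeen retained; the exact conditional test is available
via `hwe_test(..., exact = TRUE)` for small samples, where the chi-square
approximation is anticonservative.

## Single-locus statistics

For each SNP the allele table is collapsed from genotype counts
(minor $= h + 2\,m$, major $= 2\,M + h$). The odds ratio is the
cross-product ratio oriented as case minor-allele odds over control
minor-allele odds, with the Woolf confidence interval

$$\exp\!\left(\ln \widehat{OR} \pm z_{1-\alpha/2}
 \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

Zero cells either leave the estimate undefined (the table convention of
printing a dash) or, with `correction = "haldane"`, add 0.5 to every cell.
Tests are Pearson chi-square without continuity correction, switching to
Fisher's exact test on 2×2 tables when any expected count falls below 5
(Cochran's criterion; the source analyses state the chi-square/Fisher pair
without a threshold). Dominant (carrier vs non-carrier) and recessive
(minor homozygote vs rest) binarisations reuse the same machinery.
Bonferroni correction defaults to $m =$ the number of *designed* SNPs
(18), not the post-QC panel (17): the study's own adjusted headline value
($0.003 \times 18 = 0.054$) pins that choice.

Two published values resisted exact reproduction and are treated as
rounding/provenance noise rather than targets: the headline allelic
p-value printed as 0.003 (the uncorrected chi-square on the same counts
gives 0.0010, Yates 0.0013 — the original SPSS output evidently used yet
another variant), and the dominant CI printed as 1.19–2.01 where the
Woolf interval is 1.185–2.018. The ORs themselves, and every CI the
acceptance tests assert, match the print to two decimals.

Power for the design is the normal-approximation power of the two-sided
two-proportion z-test at the observed allele numbers, converting the
target odds ratio to a second-group frequency on the odds scale. At 1062
control vs 1578 case alleles, baseline minor-allele frequency 0.105 and
OR 1.5, the panel has 92% power at $\alpha = 0.05$.

## MDR

MDR reduces a k-locus genotype space ($3^k$ cells) to one binary
attribute: a cell is *high risk* when its within-cell case:control ratio
reaches a threshold $T$, *low risk* otherwise. The package's conventions,
each chosen once for determinism and stated here because the method's
literature varies:

* **Threshold**: $T$ is the case:control ratio of the training fold — the
  standard adaptive choice for unbalanced designs. A cell whose ratio
  exactly equals $T$ is high.
* **Empty cells** (unoccupied in training) predict low — the conservative
  convention; switchable to high via `empty_cells`.
* **Search**: for each order $k$, *all* $\binom{m}{k}$ subsets are scored
  in each of 10 phenotype-stratified CV folds by training balanced
  accuracy; the per-fold winner takes the first index on exact ties. The
  reported model is the modal winner; its CVC is the number of folds won;
  its testing balanced accuracy (TBA) is its mean held-out
  (sensitivity + specificity)/2. CVC ties break by higher TBA, then by
  enumeration order; across orders, the best model is the highest CVC,
  then TBA, then the smaller $k$ (parsimony).
* **Missingness**: individuals missing any locus of a subset are dropped
  for that subset only.
* **Significance**: phenotype-label permutation, re-running the entire
  order-$k$ search per permutation;
  $p = (1 + \#\{TBA_{null} \ge TBA_{obs}\}) / (B + 1)$. The conventional
  $B = 1000$ is the package default in `MDRSearchConfig` terms; tests and
  the acceptance script use $B = 99$, whose floor $p = 0.01$ is already
  decisive for the simulated effect sizes while keeping a full run under
  a few seconds.
* **Effect size**: the final model's high/low classification, rebuilt on
  the full data, is cross-tabulated against phenotype for a high-risk
  group odds ratio with Woolf CI.

With a fixed seed the search is reproducible bit-for-bit. Because the
published per-SNP counts determine only marginals, the study's multi-locus
accuracies (e.g. a five-locus TBA of 0.6273) cannot be recomputed without
the individual-level deposit; the machinery is instead validated by
simulation recovery (below) and by exact agreement with an independent
exhaustive oracle on small instances.

## CART

The partitioner is authored in-package so that every convention is pinned:

* Splits divide one SNP's observed genotype categories into two non-empty
  groups; **all** bipartitions are candidates ({AA} vs {AG, GG}, {AG} vs
  {AA, GG}, {GG} vs {AA, AG}), because published node tables show both
  dominant- and non-dominant-style groupings. The dominant-coding remark
  in the source methods is read as applying to regression/GRS coding, not
  to tree splits.
* Split quality is the decrease in Gini impurity; ties break by manifest
  SNP order, then bipartition enumeration order.
* Growth honours `min_split = 20`, `min_bucket = 7`, `max_depth`, and an
  rpart-style complexity gate: a split is kept only when its
  sample-share-weighted impurity decrease is at least `cp` (default 0.01)
  times the root impurity. These are the rpart defaults; the original
  analysis names the rpart algorithm without parameters, so re-grown tree
  *shapes* are qualitative, not exact, targets.
* Missing genotypes at a split go with the majority side; no surrogate
  splits.
* Pruning is weakest-link cost-complexity pruning on misclassification
  risk: either at a fixed threshold (`prune = "cp"`; links costing
  exactly the threshold are kept, so cp = 0 is the identity) or by the
  one-standard-error rule under 10-fold CV (`prune = "one-se"`, default),
  with the binomial approximation $se = \sqrt{R(1-R)/n}$ for the CV risk.
* Reporting orders terminal nodes by case fraction, takes the lowest as
  the reference, computes node-vs-reference odds ratios, and runs a
  Cochran-Armitage trend test with node rank as score.

A structural caveat the acceptance script makes visible: greedy
partitioning cannot enter a *purely* epistatic (XOR-type) interaction,
because no first split improves impurity; the reported
`cart_terminal_nodes_pure_xor = 1` is the honest outcome, and it is why
MDR — which searches subsets jointly — is the method of choice for such
patterns.

## GRS

The risk allele at each SNP is the minor allele when its allelic OR is
$\ge 1$, else the major allele; each individual scores 0/1/2 risk alleles
per SNP, summed over the panel. The orientation is computed from the
analysis data itself, as such studies do; this is optimistic (on pure
noise the case mean exceeds the control mean in expectation — a property
the test suite verifies), so between-cohort comparisons should fix the
orientation externally. Group contrasts use the equal-variance two-sample
t-test, which reproduces the published statistic's form. Binned risk uses
width-2 bins from the observed minimum with the top bins pooled from
score 19 — the published text is internally inconsistent about both the
number of groups ("13 groups" vs 12 width-2 bins over 3–26) and the bin
containing score 19 ("GRS > 19" vs "(19–26)"); the package follows the
explicit range, placing 19 in the top bin, and leaves both knobs
configurable.

The published group means reproduce from marginal information alone
(means of sums depend only on per-SNP counts): 12.12 vs printed 12.08 in
cases, 11.45 vs 11.46 in controls — which also indicates the published
score summed the 17 post-QC SNPs despite the text's "all 18". Score SDs,
the t statistic and the bin occupancies depend on between-SNP covariance
(the panel's tag SNPs retain LD up to $r^2 = 0.8$), which marginal counts
do not determine; on the independence surrogate the SDs come out near 2.6
against the published 4.1, exactly as a positively correlated panel
predicts.

## The synthetic generator

`simulate_case_control()` defines the package's generative contract,
recorded in the output's `truth` attribute: genotypes HWE at configured
MAFs, disease odds composed multiplicatively as
$\text{odds} = \text{odds}(\pi(g_{loci})) \cdot \prod_j OR_j^{g_j}$,
status by Bernoulli draw, rejection sampling until both quotas fill.
Supplying only a penetrance table $\pi$ reproduces it exactly; supplying
only marginal ORs gives a main-effects logistic model. Baseline
prevalence defaults to 0.3, keeping acceptance rates practical for
case-control quotas at study scale. The stress-test condition used
throughout is the two-locus XOR penetrance (0.45/0.05 at MAF 0.3,
750 + 750 individuals, four noise SNPs): near-null marginals
(allelic ORs within ±log 1.4) with a strong joint signal that the k = 2
search recovers at CVC 10/10 and TBA ≈ 0.75. `marginal_matched_dataset()`
reconstructs a cohort whose per-SNP counts equal a published count table
exactly (columns filled independently within group); single-locus
statistics are then *exactly* the published ones, while any multi-locus
result on it reflects the null joint structure — a feature the
documentation flags wherever such a surrogate is used.

What the generator does not emulate: linkage disequilibrium (the studied
panel was LD-pruned upstream, but residual correlation is why surrogate
GRS variances undershoot), covariates (age/sex — the published tables are
unadjusted), genotyping error, and population structure. Passing tests
therefore demonstrate correctness of the machinery under the stated
model, not robustness to those real-data features.

## Numerical choices and problem sizes

Ties and degeneracies are resolved deterministically everywhere (they are
listed per method above); all randomness flows through a single seed per
entry point, with `with_seed` scoping so package calls never disturb the
caller's RNG state. Tolerances in comparisons are $10^{-9}$–$10^{-12}$
scale guards on floating-point equalities, not statistical fudge factors.
The test suite and acceptance script size their simulations to run in
seconds on one core: n = 1500 for the epistasis recovery with 99
permutations, n = 10^5 for distribution-convergence checks, n ≤ 200 with
≤ 6 SNPs for the exact oracle equivalences. The full exhaustive search
scales to the study panel (order 5 over 17 SNPs ≈ 6200 subsets × 10
folds) in well under a minute, but no test depends on that.

## Known limitations

* MDR permutation testing re-runs the full search and is the only
  genuinely expensive operation at $B = 1000$.
* The CART one-SE rule can prune informative but weak structure at
  moderate sample sizes; `prune = "cp"` with a small `cp` keeps it.
* The GRS orientation-from-own-data optimism is documented but not
  corrected (no split-sample orientation option).
* No covariate adjustment anywhere, by design — matching the unadjusted
  published tables.
* The VCF importer handles plain biallelic GT fields only; it is a
  convenience adapter, not a variant-QC tool.
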