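---
title: "Phosphosite differential analysis and kinase activity inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite differential analysis and kinase activity inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphokin)
```

# The experimental design this package models

phosphokin analyses pooled two-group TMT phosphoproteomics. Equal protein
amounts from every sample of a group are pooled before labelling, so after
the spectral search each phosphosite (a phosphorylated serine, threonine
or tyrosine at a specific position of a protein) carries exactly **one**
disease/control abundance ratio. There are no per-patient replicate
columns; everything downstream must work from a single ratio per site plus
the site's local sequence context, the 13-mer window spanning positions
-6..+6 around the phosphosite (padded with `_` at protein termini).

This constraint drives three design decisions that recur below: regulation
is called by fold-change thresholds rather than per-site tests; the GSEA
null is a set-membership permutation rather than a phenotype permutation;
and kinase-site "correlation" in the network is represented structurally
(direction concordance along an edge) because no per-sample correlation
can exist.

# Quality filters

`readSiteTable()` applies the search-engine filters up front: the
modified-peptide score filter is **strict** (`score > 40` by default, so a
score of exactly 40 is excluded) and the localization-probability filter
keeps class-I sites (`loc_prob >= 0.75`). The 0.75 cutoff is the field
convention for confidently localized sites; it is exposed as an argument
because some studies apply none. Duplicate (protein, position) rows are
collapsed keeping the highest localization probability. An empty result
after filtering is a warning, not an error: an empty table is a legitimate
outcome on heavily filtered inputs.

# Differential calling and composition summaries

`callRegulation()` classifies each site by its ratio with strict
inequalities: up when ratio > 1.3, down when ratio < 0.77, otherwise
unchanged. Boundary values are unchanged. The thresholds are arguments;
their defaults are the conventional ~1.3-fold cut used with pooled TMT
ratios, where moderated per-site statistics are unavailable.

`residueBreakdown()` reports counts and nearest-integer percentages over
S/T/Y for one regulation status. `sitesPerProtein()` bins proteins with at
least one regulated site by multiplicity (1 / 2 / >=3); a protein with
sites of both statuses contributes to both rows, since the rows are
per-status summaries. `chi2Constitution()` compares the two rows with
Pearson's chi-squared statistic, df = 2, no continuity correction. A bin
that is empty in **both** rows contributes its limiting value 0 to the
statistic (the 0/0 limit) rather than erroring, so concentrated tables
remain testable; a zero row margin is an error because no comparison
exists.

# Flanking-motif enrichment

`buildMotifProfile()` compares foreground windows (for example the
upregulated sites) with background windows at each flanking position and
each of the 20 amino acids:

* **Background choice.** The background is *all* identified sites with the
  same central residue, not only unchanged ones. This isolates
  regulation-associated composition from the global phosphoproteome
  composition; it also means the foreground is a subset of the background,
  which makes the binomial test slightly conservative.
* **Statistic.** Per cell, log2 enrichment `log2((f/F)/(b/B))` with a 0.5
  pseudocount on all four counts (avoiding infinities without affecting
  the test), and a one-sided binomial upper tail `P(X >= f)` with
  `X ~ Binomial(F, b/B)`. Depletion is reported only through the sign of
  the enrichment. Padding characters are excluded from both counts and
  column totals, so positions near protein termini are tested on their
  effective sample size.
* **Multiplicity.** Benjamini-Hochberg across all tested cells (up to 12
  positions x 20 residues). BH q-values tie heavily by construction;
  "the top motif" should therefore be read from the sorted summary, not
  from a unique minimum.
* **Small n.** Below 10 foreground windows a warning is issued; tyrosine
  profiles are typically in this regime.

Single-pass positional enrichment is deliberate; iterative motif-x-style
residue fixing is out of scope.

# Kinase-substrate prediction

`scoreSite()` scores a candidate window against a kinase as the **mean
BLOSUM62 similarity** to the kinase's known substrate windows: for each
known window, the sum over the 13 aligned positions of the substitution
value, with any pair involving `_` contributing 0; then the mean over
known windows. BLOSUM62 is a fixed, documented choice - per-kinase trained
matrices are a refinement out of scope here.

`calibrateThreshold()` turns the score into a decision rule with a
controlled background false-positive rate: the threshold is the k-th
largest score of a background window collection, `k = ceiling(fpr * n)`,
and candidate sites scoring **at or above** the threshold are emitted. The
stringency presets high/medium/low map to FPR 2%/6%/10%; the default is
the medium 6%. `fpr = 0` degenerates to the maximum background score and
`fpr = 1` to the minimum. At least 200 background windows are recommended
(warning below); in the pipeline the background is the dataset's own S/T
windows.

`predictKsrs()` additionally enforces **residue compatibility** (an S/T
kinase never scores tyrosine sites; mismatching sites are skipped) and the
**interaction filter**: an edge needs protein-level interaction evidence
between kinase and substrate protein, or the substrate must be the
kinase's own protein (autophosphorylation). The filter operates at the
protein level because interaction databases record protein pairs, not
site pairs. `require_ppi = FALSE` yields a superset of the filtered edges
with the evidence still annotated.

# Kinase activity by permutation GSEA

`rankSites()` orders sites by log2 ratio (descending), breaking ties
lexicographically on the item key so the ranking is fully deterministic.
`enrichmentScore()` is the weighted Kolmogorov-Smirnov running sum: hits
increment by `|value|^p / sum(|value|^p over hits)`, misses decrement by
`1/(N - Nh)`; the score is the extremum of the running sum. When the
positive and negative extrema tie exactly, the negative one wins (the
fgsea convention). `p = 1` (classic weighted GSEA) is the default;
`p = 0` gives the unweighted statistic used in the analytic checks. If
all hit values are exactly zero at `p > 0`, hits fall back to uniform
weights.

`runGsea()` builds the null by **set-membership permutation**: `n_perm`
random same-size item sets drawn from the ranked universe (the null for
one size is shared by every set of that size). Phenotype permutation is
impossible in a one-ratio-per-site design - there are no sample columns
to permute. From the null:

* nominal p: one-sided among same-sign null scores with the continuity
  correction `(b + 1) / (n_same_sign + 1)`;
* `NES = ES / mean(|null ES of the same sign|)` - the kinase activity
  score when the sets are predicted substrate sets;
* FDR q: the pooled-null NES ratio, positive and negative sides
  separately. For `NES* > 0`:
  `q = [#(null NES >= NES*) / #(null NES > 0)] / [#(obs NES >= NES*) / #(obs NES > 0)]`,
  capped at 1 (mirrored for the negative side).

`classifyKinases()` calls a kinase positive when `NES > 0` and nominal
`p < 0.05`, negative in the mirror case, otherwise not significant. The
permutation count (1000), weight exponent (1) and cutoff (0.05) are
defaults, not claims: all are arguments. `runOra()` complements GSEA with
the one-sided hypergeometric over-representation test and BH correction
for unranked hit lists. Sets with fewer than 3 or more than 500 in-universe
members are skipped.

# The regulatory network

`buildNetwork()` intersects three results: kinases classified positive or
negative, sites called up or down, and predicted kinase-substrate edges.
Edges are directed kinase-to-site and weighted by the prediction score
(not by any NES product); nodes left isolated are dropped; the projection
never invents edges. `correlateKinaseSite()` reports, for a target site,
the adjacent kinases whose activity direction matches the site's status -
the structural reading of "kinase positively correlated with site" that a
pooled design supports. Exports are a flat TSV edge list and attributed
GraphML.

# The synthetic-data generator

`simulateDataset()` exists so that every stage is testable against known
ground truth without any external download. It emulates:

* a random proteome (default 200 proteins, lengths 200-600, Swiss-Prot-like
  amino-acid composition recorded in the output metadata);
* planted kinases, each with a consensus constraint - a required residue
  at a fixed offset; kinase 1 is always proline-directed (P at +1), the
  dominant motif class in phosphoproteomes - whose substrate windows are
  rewritten into the protein sequences (20 per kinase by default). Each
  kinase's *annotation profile* is an independent draw of 30 windows from
  the same motif model, so prediction is tested non-circularly;
* within-kinase similarity carried by a per-kinase **residue class**
  (hydrophobic, small, acidic/amide, basic) preferred with probability 1/2
  at unconstrained positions, with class frequencies renormalised from the
  background. Spreading the preference over a class and over all positions
  keeps windows of one kinase mutually similar under BLOSUM62 without
  planting any secondary single-cell motif that could rival the consensus
  constraint;
* quantification: `log2 ratio = shift + N(0, 0.1) + N(0, 0.5)`, where the
  shift is +1 for substrates of the active kinase, -1 for the inactive
  one, 0 otherwise. The baseline spread (0.1) is deliberately small - the
  pooled design averages out biological spread - while the measurement
  noise (0.5) dominates, which reproduces a realistic ~20% up-call rate
  under the default 1.3 threshold. Localization probabilities follow
  Beta(9, 1) (mode at 1, ~93% of sites class I) and search scores
  Gamma(5, rate 0.04), so a small tail falls below the score filter.
  These distributions are stipulated: only their threshold behaviour
  matters downstream;
* site density: ~2.5 quantified sites per protein (Poisson), matching the
  sites-to-proteins ratio typical of tissue phosphoproteomes; the residue
  class of each background site is drawn from the S:T:Y mix
  0.84:0.14:0.02;
* interaction evidence covering every kinase-substrate protein pair plus
  200 random decoy edges.

Everything is deterministic given the config seed (the proteome, planting
and quantification stages use `seed`, `seed + 1`, `seed + 2` internally).

**What the generator does not emulate:** raw spectra, TMT reporter
channels and isotope impurity, missing values, per-patient replicates,
protein-level abundance changes, and correlated multi-site regulation
within a protein. Passing the recovery checks therefore demonstrates that
the chain of methods is implemented correctly and is well calibrated under
its own assumptions - not that it would reach the same sensitivity on
real tissue data, where background motif composition is non-uniform and
substrate annotations are incomplete.

# Numerical choices and degenerate inputs

* Strict inequalities at both regulation thresholds and at the score
  filter; at-threshold values are unchanged/excluded respectively.
* All orderings use radix sort with explicit lexicographic tie-breaks, so
  results are independent of locale and platform.
* Percentages in the residue breakdown are rounded to the nearest integer
  for reporting; full precision is kept internally.
* Candidate edges scoring exactly at the calibrated threshold are emitted
  (the comparison is `>=`).
* Empty results (no regulated site, no significant motif cell, no edge
  surviving the PPI filter) are warnings or empty tables, never errors;
  genuinely malformed inputs (missing columns, duplicate identifiers,
  inverted thresholds, uncalibrated profiles) fail fast with named
  messages.

# Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 200-protein datasets (~500 sites) for the recovery replicates,
a 150-protein null dataset with 400 random sets for the p-value
calibration, 1,000 random instances (lists up to 50 items) for the
running-sum oracle, and every hypergeometric table with a universe of at
most 12 for the ORA oracle. These sizes keep a full run in a few minutes
while leaving the binomial confidence intervals tight enough to detect
real miscalibration.

# Known limitations

* BLOSUM62 is shared across kinases; kinase families whose specificity is
  not capturable by a symmetric substitution model will be predicted
  poorly.
* The FDR of the permutation GSEA relies on the pooled-null approximation;
  with very few sets the q-values are coarse.
* The motif module reports single-position enrichment only; cooperative
  multi-position motifs are visible only through their marginal effects.
* With a single ratio per site, no uncertainty is attached to individual
  regulation calls; they are threshold classifications, not tests.

# A worked demo

```{r demo, eval = FALSE}
res <- runDemo(seed = 1)
res$activities          # NES-as-activity with direction calls
res$summary$residue_up  # S/T/Y counts and percentages of up sites
networkEdges(res$network)
```
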