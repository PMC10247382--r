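---
title: "Methods: stepwise-fraction ancient DNA analysis with adnafrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stepwise-fraction ancient DNA analysis with adnafrac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnafrac)
```

## The problem

Osseous artefacts — pendants, awls, retouchers — can retain DNA of the
animal they were made from and of the humans who handled them. A
non-destructive, stepwise extraction releases that DNA in a series of
fractions (attached sediment, a sediment pellet, then repeated
phosphate-buffer incubations at 21, 37, 60 and 90 °C), and each fraction
is sequenced separately. `adnafrac` implements the downstream analysis
of such an experiment: deciding which mammalian families are present in
each fraction, which of those signals are ancient rather than modern
contamination, whether the human component traces back to a single
individual, what that individual's genetic sex and population affinities
are, and how old the DNA is under a molecular clock. Every step can be
exercised end to end on simulated data with known ground truth.

## Damage model and authentication

Post-mortem cytosine deamination converts C to U, read as T, and is
concentrated at fragment ends. For single-stranded library preparations
both molecule ends show C→T; the simulator's per-offset conversion
probability is

p(i, j) = baseline + d_max · exp(−λ·i) + d_max · exp(−λ·j), capped at 1,

for a cytosine at offsets i and j from the 5′ and 3′ ends. The additive
form makes the expected terminal rate exactly `baseline + d_max` (the
far-end term is negligible at typical fragment lengths), which is the
closed form the tests check against. A `double_stranded` flag switches
to the C→T-at-5′ / G→A-at-3′ signature of double-stranded libraries.
Sequencing error substitutes any base with a uniformly chosen different
base at rate ε, so the observed terminal rate is
`p·(1−ε) + (1−p)·ε/3`.

Defaults — d_max = 0.4, λ = 0.3, baseline = 0.01, ε = 0.001, geometric
fragment lengths with mean 55 nt and minimum 30 nt — are typical of
deeply degraded Pleistocene material; the source study reports no
per-offset magnitudes for its specimen, so these are package choices,
stated once here and not revisited.

Authentication of a (fraction, family) bin asks whether the terminal
C→T frequency is *significantly* above 10% at **both** molecule ends,
operationalised as: the lower bound of the exact (Clopper–Pearson) 95%
binomial interval exceeds 0.10 at each end, with no multiplicity
correction. Clopper–Pearson was chosen because the small-count
intervals printed in the motivating study (e.g. 7/9 → 40.0–97.2%) match
it exactly; Wilson or Jeffreys intervals do not reproduce those values.
At the 10% boundary this test's per-end false-positive rate is at most
2.5% (one side of the exact interval), and its power at a true rate of
0.3 with 100 informative terminals per end exceeds 95% — both properties
are verified by simulation in the test suite.

## Taxonomic binning

Fragments are assigned to families by competitive best-hit search
against the full reference panel (both strands), replacing the
BLAST+MEGAN metagenomic pipeline of the original study: with a small,
family-divergent panel the behaviours coincide at family level, and a
tie in best mismatch count across families leaves the fragment
unassigned, mirroring a lowest-common-ancestor fallback. Detected
families must pass three filters before any ancient/other decision: at
least 3 unique fragments, jointly covering at least 105 reference
positions, and making up at least 1% of all taxonomically assigned
unique fragments. "Unique" is defined by the alignment key (reference,
start, end, strand), so damage and error variants of one molecule
collapse; the 1% rule is evaluated after deduplication (the original
description does not say which; this is configurable). All filters are
computed from the same unfiltered counts, making them idempotent and
order-independent.

## Consensus, diagnostic positions, contamination

The mitochondrial consensus calls a base where coverage is ≥ 10 and a
single base carries ≥ 75% of reads; everything else is N. The coverage
floor follows the study; the 75% majority is this package's choice,
deliberately conservative against contamination and residual damage. A
*diagnostic position* is a called position whose allele is absent from
a comparison panel (frequency threshold configurable). Differences that
deamination can mimic (C↔T, G↔A) are flagged and excluded from support
calculations by default.

Per-fraction support counts one observation per fragment-site overlap
with a non-N read base (a fragment spanning two diagnostic sites counts
twice; per-fragment counting is available) and reports the matching
fraction with its exact binomial interval; below 5 observations the
verdict is *indeterminate*. The diagnostic contamination estimate is
defined as the exact complement of support on the same observations —
with unambiguous biallelic sites and low error these are precisely the
contaminant-allele matches, and the two estimates sum to one by
construction.

The second, orthogonal contamination estimator needs no diagnostic
sites. Writing r_all for the terminal C→T rate over all fragments and
r_cond for the rate among fragments that already carry a C→T at the
*opposite* terminal (a subset heavily enriched for endogenous,
deaminated molecules), a two-component mixture gives
ĉ = 1 − r_all / r_cond, clipped to [0, 1], with a percentile bootstrap
over fragments for the interval. This deliberately simple conditional
estimator stands in for full damage-pattern mixture modelling
(AuthentiCT-style), which is an external published tool; both
estimators are labelled by method in their results. The conditional
estimator is consistent but noisy when the conditioning subset is small
— intervals at a few thousand fragments are wide, and the test suite
checks calibration (≈90% coverage of truth at c = 0.3, n = 20,000)
rather than tightness.

## Population-genetic statistics

Allele counts live in a sites × groups matrix (EIGENSTRAT triplets are
read and written losslessly; genotype codes are taken as ALT-allele
counts). f3(C; A, B) is the per-site mean of (c−a)(c−b), left
*unnormalised* — no target-heterozygosity denominator — because only
rankings among outgroup-f3 values are used, and those are unaffected; a
normalised variant can be added trivially downstream. D(W, X; Y, Z) is
Σ(w−x)(y−z) / Σ(w+x−2wx)(y+z−2yz). Standard errors come from a
weighted block jackknife over contiguous equal-count site blocks
(default 20): synthetic data carries no genetic map, so genetic-distance
blocks are out of scope and the block count is configurable. The
weighted (Busing) formula reduces exactly to the textbook delete-1
jackknife for equal blocks, which is how the tests validate it. No
small-sample bias correction is applied for pseudo-haploid groups by
default.

The drift simulator draws ancestral frequencies from Uniform(0.05,
0.95) and transforms them along each branch by a Balding–Nichols Beta
draw with branch-specific F; one optional admixture edge mixes a leaf's
frequency with another node's. Under a symmetric four-population tree
D is centred on zero; a 10% admixture edge produces a strongly positive
D at 100,000 sites — both are acceptance properties.

PCA projects a partially missing sample by least squares onto
components computed from complete reference individuals (sites centred
by 2p and scaled by √(p(1−p))). Projection shrinkage is *not*
corrected; coordinates of low-coverage samples are biased towards the
origin exactly as with lsqproject-style projection, and the tests only
assert relative placement (an admixed sample lands between its source
populations), never absolute coordinates.

Genetic sex uses R = nX/(nX + nAut) over X and autosomal SNP sites with
an exact binomial interval. Expectations are R_XX = sX/(sX+sA) and
R_XY = sX/(sX+2sA). The reported interval is 95%, matching the error
bars one would plot; the karyotype *call* tests membership of the
expectations in a stricter 99.9% interval. The distinction matters: at
capture-scale counts the 95% interval excludes the true expectation in
about 5% of datasets, which would leave one dataset in twenty
*indeterminate* even though the two hypotheses are separated by dozens
of interval widths; the 0.999 calling level reduces that failure mode
below 1% without ever choosing between hypotheses that are genuinely
close (those remain indeterminate at any level).

## Molecular clock dating

Bayesian tip dating of the original study is replaced by root-to-tip
regression: distances from each tip to a designated outgroup (pairwise
Hamming on unambiguous columns, Jukes–Cantor corrected by default) are
regressed on tip age, distance = a − r·age; the query's age is
(a − d_query)/r. Requirements: at least three dated tips, positive age
spread, and a positive fitted rate (otherwise the data are flagged
unclocklike). The interval is a percentile bootstrap over alignment
columns, widened if necessary to contain the point estimate, and
negative ages are truncated at zero with a flag. Jukes–Cantor is the
only correction offered — adequate at intra-species mtDNA divergences
and simple enough to verify against a closed form. On noise-free data
the estimator is exact and shifts by exactly c when all tip ages shift
by c; on simulated strict-clock data the 95% bootstrap interval covers
a 20,000-year truth in ≈90% of replicates, which is the calibration the
acceptance suite checks. The published point ages of the motivating
study are not reproducible here: they depend on real alignments,
Bayesian tree priors and an external tool, which is why dating enters
the acceptance criteria only as this coverage property.

## What the simulations do and do not establish

The generators emulate: per-fraction mixtures of family-level sources
with and without terminal damage; a human endogenous/contaminant
haplotype pair differing at a small set of well-spaced diagnostic
positions (default 7); Balding–Nichols drift with one admixture edge;
Poisson X/autosome fragment counts; and Poisson substitution counts
under a strict clock. They deliberately omit PCR duplication structure,
capture bias, index hopping, length-biased damage, reference bias and
within-family sequence diversity. A green test therefore establishes
the correctness and calibration of the *statistics* under their stated
models, not robustness to every artefact of real capture data. Truth
tables are emitted alongside every simulated dataset and no analysis
function reads them.

## Numerical and degenerate-input choices

* Exact binomial intervals use Beta quantiles; k = 0 and k = n pin the
  respective bound to 0 or 1.
* Ends with zero informative terminals can never be called ancient and
  carry an explicit flag.
* Consensus ties (no base reaching the majority) give N, never an
  arbitrary winner.
* The conditional contamination estimator returns an indeterminate
  flag when the conditioning subset is empty or undamaged.
* f3/D on a single usable site return the point value with NA standard
  error rather than failing.
* Fragments spanning the circular origin are stored with end > L and
  resolved modulo the reference length at every access.
* One global seed drives each simulator; all stochastic estimators
  (bootstraps, pseudo-haploid draws) take explicit seeds.

## Configuration

All thresholds (mismatch fraction 0.1, detection filters 3/105/1%,
damage threshold 0.10, CI level 0.95, coverage floor 10, majority 0.75,
support floor 5, jackknife blocks 20) live in a single JSON
configuration read by `read_config()`; the YAML variant was dropped
because the deployment environment provides no YAML parser, and JSON
covers the same need.
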