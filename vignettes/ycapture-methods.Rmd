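---
title: "Models and methods behind ycapture"
author: "ycapture authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ycapture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ycapture)
```

# The problem

Ancient skeletal samples typically yield sequencing libraries in which only a
tiny fraction of molecules (often well under 1%) derives from the host; the
rest is environmental (mostly microbial) DNA. Because each cell carries a
single Y chromosome, recovering enough Y-DNA to determine a paternal lineage
from shotgun sequencing alone is usually hopeless. In-solution
capture-enrichment hybridizes biotinylated probes to library molecules from
selected Y-chromosome regions and washes the rest away, raising the on-target
fraction of what is sequenced by orders of magnitude.

`ycapture` implements the complete analytical layer of an evaluation of such
an experiment: a truth-labeled simulator of libraries and capture rounds; the
read accounting that turns mapped reads into per-library metrics
(deduplication, on/off-target classification, seeded down-sampling
replicates, confidence intervals); fold-enrichment grids between
experimental conditions; library-complexity extrapolation into yield and
enrichment curves; genetic sex determination from sex-chromosome read
counts; and Y-haplogroup assignment by a most-derived-SNP tree search.

The four experimental conditions modelled throughout are: `pre` (shotgun
sequencing of the untouched library), `YCC` (one Y-target capture round),
`WGC` (one whole-genome capture round, i.e. all endogenous molecules are
"on-target"), and `WGC+YCC` (whole-genome capture followed by Y capture, two
sequential capture rounds).

# The simulator

## Finite molecule pools

A library is a finite pool of `poolSize` distinct template molecules
(`simulateMoleculePool()`). Each template gets:

* an **origin label** drawn from the profile's proportions — endogenous Y
  (`endogenousFraction * yFraction`), endogenous non-Y, or exogenous.
  Exogenous templates are placed on a pseudo-reference named `unmapped` and
  never count as mapped reads downstream;
* a **fragment length** from a normal distribution truncated below at
  `minLength`. Published length distributions of ancient libraries are
  unimodal with means between roughly 60 and 110 bp, which a truncated
  normal reproduces with the fewest parameters;
* uniform **coordinates** and strand on its assigned reference. Endogenous
  non-Y templates are spread over the non-Y references proportionally to
  reference length.

Sequencing (`amplifyAndSequence()`) samples templates uniformly with
replacement: PCR duplicates arise naturally from the finite pool, and the
expected number of distinct templates seen after `n` reads is the occupancy
expectation `P(1 - (1 - 1/P)^n)` — the closed-form oracle used throughout
the tests. Amplification-efficiency and GC biases are deliberately not
modelled: the analyses under test consume duplicate *counts*, not the
mechanism that produced them.

## Capture

One capture round (`simulateCapture()`) retains each template independently
with probability `classProbability * lengthBias(length)`:

* `pOnTarget` (default 0.8) for templates overlapping a target region by at
  least 1 bp,
* `pOffTargetY` (default 0.05) for Y-chromosome templates outside the
  targets — off-target Y molecules are recovered at a low but non-zero rate,
  consistent with the observed off-target increase after capture. No
  published estimate of this probability exists, so the default is
  calibrated only loosely (an order of magnitude below on-target retention)
  and is a free parameter;
* `pBackground` (default 0.002) for everything else, including exogenous
  molecules.

The **length bias** is a logistic multiplier
`plogis((length - midpoint)/scale)` centred at the 105-bp probe length
(`scale` 15 bp, disabled with `lengthBiasScale = NA`). Capture experiments
show a shift toward longer fragments, most plausibly because fragments much
shorter than the probes hybridize poorly; the logistic form is the simplest
monotone, bounded choice — nothing downstream depends on its exact shape,
only on monotonicity.

Capture-after-capture is expressed by calling `simulateCapture()` twice;
since retention is a thinning, a second round can only lose complexity,
which is exactly the mechanism behind the sharp clonality increase observed
after consecutive captures.

## What the simulator does not emulate

No base sequences, sequencing errors in read bodies, adapters, alignment or
mapping ambiguity; no post-mortem C-to-T deamination damage; no taxonomic
structure in the exogenous fraction. Reads copy their template's
coordinates exactly, so coordinate-based deduplication is exact by
construction. Tests passing on these simulations therefore validate the
*analytical* layer — accounting, extrapolation, tree search — not the
upstream mapping pipeline a real study would run.

# Accounting conventions

* **Duplicate key**: (reference, start, end, strand) — both fragment ends
  plus orientation. A 5'-only key would merge distinct templates that share
  a start; the stricter key never does. The representative read of a class
  is the one with the smallest `read_id`, a deterministic tie-break.
* **On-target**: overlap of at least one base with a target interval,
  half-open at file boundaries (a read ending where a region starts does
  not overlap).
* **Down-sampling**: replicates (10 by default) are uniform samples without
  replacement, replicate `r` seeded with `baseSeed + r` so any single
  replicate is reproducible in isolation. Raw reads are down-sampled first
  and deduplicated after, matching the order of operations of the
  processing pipeline the accounting mirrors (duplicates are a property of
  what was sequenced, so they must survive into the subsample).
* **Confidence intervals**: Wilson score intervals. The source procedure
  says only "binomial proportion confidence intervals"; Wilson behaves well
  at the tiny counts involved (0-digit successes are common), and the
  choice is isolated in `binomialCI()` so a Clopper-Pearson variant could
  be swapped in for comparison.
* **Display rounding**: percentages of sequenced reads with two decimals,
  percentages of chrY reads as whole percents, fold-enrichments with one
  decimal — all half-up (`roundHalfUp()`), because published values like
  963.8 from 963.75 are inconsistent with round-half-even. Internal values
  keep full precision; rounding exists only in `formatMetrics()` and the
  `fold_display` column.
* **Missing values**: zero-denominator ratios are `NA`, printed as "-";
  they are never coerced to 0 or infinity.

# Fold-enrichment

`foldEnrichment(m1, m2)` is the ratio of mean unique on-target reads at
matched effort. When the baseline mean is zero, the numerator itself is
assigned. Two conventions circulate for this degenerate case — assigning
the numerator, or dividing by the maximum replicate count of the baseline
library — and they disagree in general; the numerator rule is implemented
as primary because it exactly reproduces the published degenerate cells
(e.g. a fold of 12.0 for a library whose baseline had no on-target reads),
while the max-baseline variant remains available via
`zeroRule = "baseline"`. Whether published ratios used rounded or
full-precision means is immaterial here: full-precision means reproduce
every printed cell after one-decimal half-up rounding.

# Complexity extrapolation

## Model

`fitYieldModel()` treats the per-template read count as negative binomial
with mean `mu` and dispersion `k`; unobserved templates are the zero class,
so the duplicate histogram is a zero-truncated sample. The fit is maximum
likelihood via EM:

1. **E-step**: with current `(k, mu)`, the expected number of unseen
   templates is `n0 = D * p0 / (1 - p0)` where `D` is the observed distinct
   count and `p0 = (k / (k + mu))^k`.
2. **M-step**: on the completed histogram, `mu` has the closed form
   `S / (D + n0)` (`S` = total reads) and `k` is found by one-dimensional
   likelihood maximisation over `log k` in `[log 1e-3, log 1e6]`.

Iteration stops at relative change `1e-8` or 200 iterations. The library
size is `L = D / (1 - p0)`, which makes the expected yield
`L (1 - p0(t))`, with `p0(t) = (k / (k + mu t))^k` at effort multiplier
`t`, interpolate the observed distinct count exactly at `t = 1`. This is
the same empirical-Bayes model family as the established complexity
package for sequencing libraries; it was chosen over rational-function
(Good-Toulmin) accelerations because it is numerically stable at the very
small on-target counts typical of captured ancient libraries, and it sits
behind the `expectedYield()` generic so an alternative extrapolator can be
added without touching callers.

A histogram with no class of multiplicity 2 or more carries no information
about saturation; `fitYieldModel()` signals this (condition class
`ycaptureNoDuplicates`) and `linearFallback()` supplies
`yield(n) = n * uniqueOnTarget / totalReads` instead.

## Effort correction and units

Yield curves are expressed against *total sequenced reads*. Only a fraction
of sequenced reads is on target, so `extrapolateYield()` multiplies the
grid by `onTargetFraction` before evaluating a histogram-based model (the
histogram lives in on-target read units). The linear fallback's slope is
already per total sequenced read and receives no correction. Effort grids
default to 50 log-spaced points spanning 1e2 to 1e7 reads — wide enough to
show both the pre-saturation regime and the plateau for every library size
the package simulates.

## Bootstrap

`bootstrapYield()` resamples the observed *reads* multinomially over the
observed template classes (resampling sequencing effort, not templates),
refits, and re-extrapolates; per grid point the median and variance across
replicates (100 by default) are reported, and replicates whose resampled
histogram is duplicate-free propagate the linear fallback. Enrichment
curves (`enrichmentCurve()`) are pointwise ratios of bootstrap medians;
grid points with zero denominator median are missing. A denominator
library with no duplicates *and* no on-target reads has an identically
zero curve and produces an all-missing enrichment curve — the
zero-denominator numerator rule applies only to the condition-table point
estimates, not to curves.

# Sex and haplogroups

* `ryStatistic()` computes `Ry = nY / (nX + nY)` with the
  normal-approximation interval `Ry ± z sqrt(Ry(1-Ry)/n)` clipped to
  [0, 1] — the interval of the published screening script, deliberately
  not the Wilson interval used elsewhere in the package, to stay faithful
  to the cited procedure. The assignment is XY-consistent only when the
  whole interval exceeds the threshold (0.075, configurable), mirrors to
  not-consistent below, and is otherwise indeterminate; `Ry` exactly at
  the threshold is always indeterminate.
* `callHaploidGenotypes()` discards bases below Phred 13 (inclusive floor:
  quality 13 survives) and samples one surviving base uniformly per site.
  All bases observed at a site are pooled before sampling, regardless of
  which experiment produced them — the merging step is not further
  specified in the source procedure, and pooling is the least-informative
  choice that uses all data.
* `assignHaplogroup()` scores calls against the tree's defining SNPs and
  returns the deepest node whose *own branch* carries a derived call.
  Requiring direct branch support means the caller never names a node it
  has no evidence for; derived calls off the chosen path are returned as
  conflicts, never silently resolved. Ties across equally deep siblings
  (possible only with conflicting data) are broken by the number of
  derived calls on the root path; remaining ties are reported unresolved
  with both candidates listed, and a call set with no derived call
  anywhere is unresolved ("-"). An unresolved real-world sample could
  reflect either situation; the call object distinguishes them via its
  `candidates` and `conflicts` slots.

# Pipeline and reproducibility

`runPipeline()` wires the stages together from a YAML/list configuration.
WGC is a capture with a whole-genome target (every endogenous template
on-target); WGC+YCC is two sequential captures. Every stage seed is derived
deterministically from the top-level seed (fixed offsets per sample and
stage), so a rerun is byte-identical — reruns recompute rather than resume
from cached stage outputs, since at the problem sizes involved recomputing
is cheaper than cache invalidation. Stage failures abort with the failing
stage and sample named. Outputs are plain TSV/BED/JSON with seeds recorded,
plus a manifest listing each file's checksum and the configuration hash.

# Problem sizes and numerical choices in the test-suite

The suite validates statistical behaviour on deliberately small problems:
occupancy and parameter-recovery checks use pools of 1e2--1e4 templates and
20--50 seeds with 3-standard-error (or 10--15% on medians) acceptance
bands; the exhaustive tree-search oracle enumerates all 2^7 call patterns
of a 7-branch tree; end-to-end lineage recovery uses a 50-node random tree
at mean depth 12 with error-free bases. These sizes give stable statistics
while keeping the whole suite under a minute of simulation time. Monotone
non-decrease and concavity of yield curves are asserted through divided
differences, since the default grid is log-spaced.

One scale caveat: per-read endogenous fractions and absolute pool sizes
cannot both match the real experiments in a miniature simulation. A
million-template pool at 1.54% endogenous content holds only a few hundred
Y molecules at this package's reduced genome scale, so demonstration
configurations raise the Y share of endogenous molecules (to ~10%) to keep
on-target counts informative; conclusions about *relative* enrichment
between conditions are unaffected.

# Known limitations

* The ZTNB extrapolator assumes exchangeable templates within the fitted
  class structure; strong capture-induced heterogeneity in amplification
  efficiency would be absorbed into `k` rather than modelled.
* The sex statistic ignores mismapping between X and Y homologous regions
  (the simulator produces none).
* Haplogroup assignment takes SNP alleles as reference-forward and attempts
  no strand flipping; a real SNP panel must be oriented before loading.
* The simulator's exogenous fraction is a single undifferentiated pool; it
  cannot be used to study microbial composition effects on capture.
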