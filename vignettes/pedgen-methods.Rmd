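---
title: "Kinship, inbreeding and marker-panel design with pedgen"
author: "pedgen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship, inbreeding and marker-panel design with pedgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedgen)
```

# Scope and intended use

pedgen supports the genetic management of semi-captive and other
intensively recorded animal populations — the motivating system is a
large semi-captive Asian elephant workforce in which maternity is logged
but matings are unsupervised, so paternity is unknown and gene flow with
wild bulls is routine. From a matrix of biallelic SNP dosages plus a
sample register (sex, birth year, origin, camp, recorded dam), the
package estimates pairwise kinship, classifies relationships, enhances
the matrilineal pedigree with inferred fathers, quantifies inbreeding
through runs of homozygosity, partitions each genome into age-resolved
autozygosity classes, and designs reduced marker panels for cheap
routine relatedness monitoring.

Every stage is validated on a built-in pedigree–genotype simulator, so
the package's statistical claims are reproducible without access to any
particular data set.

# Data model

`GenotypeData` extends `RangedSummarizedExperiment`: one integer assay
`"dosage"` (markers × samples, alternate-allele count 0/1/2, `NA` for a
missing call, never imputed), marker coordinates and ref/alt labels as
`rowRanges`, chromosome lengths in the `seqinfo` (the genome layout used
as the denominator of marker density and F~ROH~), and the sample
register as `colData`. Positions are 1-based and intervals closed, as in
VCF. Markers on sex chromosomes are dropped on load, because every
downstream analysis assumes autosomal data.

Quality control retains markers with minor allele frequency strictly
above the cutoff (default 0.05) and missingness at most the cutoff
(default 10%): a marker exactly at the MAF cutoff fails, a marker
exactly at the missingness cutoff passes. LD pruning removes, from every
within-window pair (default 50 kb) whose squared dosage correlation
(composite LD on pairwise-complete samples — genotypes are unphased)
exceeds the threshold, exactly one member: the one with more missing
data, then the lower MAF, then the larger position. Pairs are resolved
in a fixed (chromosome, left, right) order, so the survivor set is fully
deterministic and — deliberately, unlike step-based heuristics — does
not depend on the `stepSnps` batching argument.

# KING-robust kinship and degree classification

For a sample pair the kinship coefficient is estimated from counts over
pairwise-complete markers,

$$\hat\phi \;=\; \frac{N_{\mathrm{het,het}} - 2\,N_{\mathrm{opp\,hom}}}
{N_{\mathrm{het}}^{(a)} + N_{\mathrm{het}}^{(b)}},$$

the KING-robust moment estimator, which stays unbiased under population
structure and requires no allele-frequency estimates. Relatedness is
$r = 2\phi$. Degree bins operate on the $r$ scale — $r > 0.45$ first
degree, $0.25 \le r \le 0.45$ second, $0.125 \le r < 0.25$ third/fourth,
below that unrelated — while the unrelated-subset cutoff (0.08) operates
on the $\phi$ scale, where second-degree pairs sit near 0.125. This is
the only reading under which both sets of conventional thresholds select
the intended relative classes; the bin labels follow field usage rather
than strict genealogical-degree nomenclature (the 0.125–0.25 bin is
conventionally labelled with first cousins, whose expected $r$ is at the
bin's lower edge). Pairs whose estimate is undefined (no heterozygote in
either member across shared markers) are flagged rather than classified.
The spanning boundary case $r = 0.45$ is assigned to second degree so
the classification is total.

The unrelated subset is built greedily: among samples joined by a
$\phi \ge 0.08$ edge, repeatedly delete the highest-degree vertex, ties
broken towards the sample whose camp is most represented among current
survivors (preserving geographic coverage), then lexicographically. The
output is re-verified pair-free on every call.

# Father–offspring inference

In a matrilineal register, a first-degree pair that cannot be a
mother–offspring or full-sib pair is, in practice, a father–offspring
pair. The rule: the pair is classified first degree; the older member is
male; the birth-year gap strictly exceeds 18 years (whole years only —
the register carries no months; approximate birth years propagate a
flag); and the register records no relatedness between the two. The
last exclusion is implemented as *no shared recorded ancestor and no
recorded ancestor–descendant path of any length*: collateral matrilineal
kin — for instance the dam's maternal half-brother, expected kinship
0.1875 — can realise an estimate above the first-degree boundary on a
finite marker panel, and any pair already connected in the register is
not an "unknown father" candidate in the first place. The per-sire
offspring counts are reported alongside (the prolific-bull report),
since reproductive skew is exactly what such populations need to
monitor.

No likelihood-based parentage assignment is attempted: the rule is
threshold-based by design and is validated by simulation (sensitivity
above 95% with zero false positives at 2,000 markers and 0.5%
genotyping error under the default study conditions).

# Runs of homozygosity and F~ROH~

A reported ROH is a marker interval satisfying five criteria: (i) no
heterozygous call, (ii) at most one missing call, (iii) at least 20
markers, (iv) marker density at least the dataset-wide density (total
markers over total genome length, computed after all filters), and (v)
span at least 100 kb — and not contained in any longer interval that
also satisfies them. These are exact maximal-run semantics, chosen over
scanning-window heuristics because they are deterministic and directly
testable against brute-force enumeration of every sub-interval; counts
can therefore differ slightly from windowed tools on the same data.
Segment endpoints are the first and last marker positions (no extension
into flanking gaps — conservative and reproducible). "Fewer than two
missing genotypes" is read as at most one missing call inside the run.

$F_{\mathrm{ROH}}$ is the union length of a sample's segments divided by
the total genome length. Group differences (wild- versus captive-born;
birth decades) use the Wilcoxon rank-sum test with normal approximation
and tie correction, and the one-way fixed-effects ANOVA F test. A
configuration preset with different ROH thresholds can be passed through
`rohParams()` for dense (whole-genome) data; its defaults here are this
package's choice, documented, not imported from any particular study.

# The multi-class HBD model

Autozygosity is partitioned by a hidden Markov model with nine
homozygous-by-descent classes and one non-HBD class. Class $k$ has
exponential segment lengths with rate $R_k$ per Morgan, defaults
$2, 4, \ldots, 512$, corresponding to common ancestors roughly $R_k/2$
generations back — long segments are recent inbreeding, short segments
old bottlenecks. The non-HBD rate is tied to the largest HBD rate (512),
the layered-model convention. Between adjacent markers at genetic
distance $d$ (1 cM/Mb, the mammalian default) the chain stays with
probability $e^{-R_k d}$, otherwise re-enters class $j$ with probability
$M_j$; segment-class membership probabilities $M$ are the per-sample
mixing proportions. Emissions: non-HBD sites emit Hardy–Weinberg
proportions; HBD sites emit $(1-\varepsilon)(p, 0, q) +
\varepsilon(p^2, 2pq, q^2)$ with $\varepsilon = 0.001$ by default — the
emission law and $\varepsilon$ are this package's concrete choices.
Missing calls emit 1. Chromosomes are independent chains.

Inference is exact scaled forward–backward, implemented in C++ and
cross-checked in the tests against a pure-R reference implementation and
against exhaustive path enumeration. Mixing proportions are fitted per
sample by EM — the M-step is the expected class membership of segment
starts in closed form, so the likelihood is monotone by construction —
with a safeguarded SQUAREM extrapolation each cycle, accepted only when
it does not decrease the likelihood. The likelihood ridge between
adjacent rate classes is extremely flat, and plain EM can need thousands
of iterations there; the accelerated fit converges one to two orders of
magnitude faster to the same optimum (verified against direct simplex
optimisation). Initialisation is moment-matched: the posterior class
occupancy under the model's own mixing, rescaled by class rate.

Two identifiability limits are worth knowing. First, all HBD classes
share one emission law, so classes are distinguished *only* by segment
length; a mixing vector that puts nearly all mass on HBD classes makes
the genome almost entirely autozygous, transitions between same-class
segments become unobservable, and the class rate is unidentifiable in
principle. Recovery experiments therefore balance the class of interest
against non-HBD background. Second, a class whose expected segment
length falls at or below the marker spacing (the 256 and 512 classes at
RAD-like densities) cannot be resolved regardless of inference quality —
the reason sparse reduced-representation data shift apparent
autozygosity towards middle classes relative to dense data. The
dominant-class recovery check accordingly draws its target from classes
1–6 and uses a 0.4 cM mean spacing over a 40-Morgan genome; the
genome-fraction recovery check runs at the 5,000-marker scale of the
sparse-data regime. "Dominant class" is always assessed on fitted
per-class genome fractions (the quantity the stacked-bar partition
displays), not on raw mixing weights, which are segment *counts* and
weight long-segment classes down.

Per-class genome fractions are unweighted marker averages of the
posterior (inter-marker span weighting would be an easy swap, one line
in `partitionAutozygosity()`).

# RIM panels and the resampling null

Relatedness-informative marker (RIM) panels are built by a cascade:
missingness at most 5% ("call rate below 5%" in common usage is read as
missingness above 5%; the literal reading — markers genotyped in under
5% of samples — is available behind `callRateLiteral` and is a near
no-op after QC), LD pruning at $r^2 > 0.2$ with the same 50 kb window
machinery as QC (the window for this step is a package choice), then a
MAF floor, inclusive so that a 0.45 threshold keeps markers at exactly
0.45. Because the floor is applied last, panels at 0.35 / 0.40 / 0.45
are nested by construction. High-MAF markers maximise expected
heterozygosity and hence the information the KING counts carry.

Validation opposes each panel's kinship estimates to the full-set
estimates (Pearson correlation over pairs defined in both; computed on
$\phi$, which is equivalent up to the affine scale change to $r$) and to
a null of 100 random panels of matched size drawn without replacement.
The report carries the RIM − null gap together with the null standard
deviation so the "designed beats random" claim can be inspected, not
asserted.

# The simulator: what it emulates and what it does not

The simulator is the package's test bed and defines its default study
conditions: 261 genotyped samples — 54 wild-captured founders (30
females, 24 males) plus captive-born descendants — with a handful of
unsampled wild bulls also siring; 13,000 markers on 10 chromosomes of
300 Mb (an elephant-scale ~3 Gb genome); founder alternate-allele
frequencies Uniform(0.05, 0.5), mimicking a post-QC RAD-like frequency
spectrum; genotyping error 0.005 and missingness 0.03. Founders are
drawn in Hardy–Weinberg and linkage equilibrium — LD then arises from
pedigree transmission, which is the LD that pruning and panel selection
need to see. Gametes carry Poisson crossovers at 1 cM/Mb with uniform
positions. Genotyping noise is a symmetric uniform mis-call plus
independent dropout: simple and severity-controllable.

Breeding is scheduled on a calendar rather than in discrete
generations — captive birth years are drawn over 1965–2010, dams
uniformly among females aged 15–50, sires among males at least 20 years
older than the offspring — which yields the overlapping generations and
wide age gaps the paternity rule relies on. Sires are drawn with
probability proportional to a latent weight raised to the `sireSkew`
power (default 4), concentrating paternity on a few bulls. Matings
between pairs with pedigree kinship at or above 0.125 are avoided by
default (`mateAvoidanceKinship`), emulating the behavioural close-kin
avoidance and chemosensory kin recognition documented in elephants;
without it, close-kin matings produce double-grandfather pairs with true
kinship 0.25 that no threshold rule can separate from fathers — a limit
of threshold-based paternity calling worth remembering with real data
from populations where close inbreeding does occur. Only the dam is
written into the visible register; true sires live in a separate truth
table, mirroring matrilineal record-keeping.

What the simulator does *not* emulate: allele dropout that correlates
with locus GC or depth, batch effects, genotyping error that clusters
along the genome, pedigree errors in the register, population structure
among founders, and selection. Passing tests therefore demonstrate the
estimators' correctness and calibration under clean assumptions, not
robustness to every artefact of real reduced-representation data.

# Numerical and design notes

* Forward–backward uses per-marker scaling; posteriors are renormalised
  per marker and must sum to 1 within 1e-10, class fractions within
  1e-8. A zero emission column (an observed genotype impossible under
  the supplied frequency) raises an explicit error rather than
  propagating `NaN`.
* The EM trace of accepted states is non-decreasing by construction;
  fits stop when a sample's log-likelihood improves by less than `tol`
  (default 1e-6) in a cycle, and converged samples drop out of the
  batched computation.
* LD pruning and ROH detection are exactly reproducible: no ties are
  broken by randomness anywhere in the package.
* `unrelatedSubset` ties: camp representativeness first, then remove the
  lexicographically greatest identifier.
* Group tests at very small samples: with the normal-approximation
  rank-sum test, two groups of three cannot reach p < 0.01 even under
  complete separation; the calibration tests therefore use larger
  groups.
* The pipeline fans a single seed out to per-stage seeds by hashing the
  stage name, so enabling or disabling one stage never changes another
  stage's draws; two runs with one seed are checksum-identical.
* Test and validation problem sizes (5,000-marker calibration panels,
  200 full-sib replicates, 100-sample HBD recovery, 20-seed panel
  comparisons) were chosen as the smallest sizes at which the expected
  statistical fluctuations sit comfortably inside the asserted bounds.
  Paternity-rule sensitivity in particular is estimated by pooling true
  pairs across replicate pedigrees: one 261-sample pedigree carries only
  ~170 detectable father–offspring pairs, and a rate estimated from a
  single draw has a standard error of about two percentage points —
  too coarse to check a 95% bound.

# Known limitations

Threshold-based paternity calling cannot separate a father from any
other relationship whose realised kinship exceeds the first-degree
boundary (double grandfathers under close inbreeding being the
canonical case). Exact maximal-run ROH semantics can split runs that
scanning tools join, so absolute segment counts are tool-specific even
when F~ROH~ agrees. HBD classes beyond the marker density's resolution
limit are reported but not meaningfully estimated on sparse data. The
RIM panels are only as transferable as the reference population's
diversity; panels designed on one population should be revalidated
before use elsewhere.
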