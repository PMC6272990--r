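---
title: "Dominant-marker diversity analysis with bandpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker diversity analysis with bandpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandpop)
```

## The data model

Dominant marker systems — SSR fingerprints scored as anonymous bands,
IT-ISJ, RAPD, ISSR, AFLP — yield, after gel scoring, a binary matrix:
individuals in rows, band positions ("loci") in columns, 1 for presence and
0 for absence.  A band's presence cannot distinguish a homozygous carrier
from a heterozygote, which shapes every statistic downstream.  `bandpop`
wraps this matrix, a band-to-primer map and a primer-to-marker-system map in
the `band_matrix` class, and all analyses run off it:

* **marker efficiency** — per-primer polymorphism counts (TNB, NPB, PPB) and
  polymorphic information content, per-system average band informativeness
  (Ibav), effective multiplex ratio (EMR) and marker index (MI = Ibav × EMR);
* **diversity** — per-group Na, Ne, Nei's gene diversity He and Shannon's
  index I under Hardy–Weinberg equilibrium, with the intra/inter partition
  It, Is, Is/It and S′ = (It − Is)/It;
* **distance and phylogeny** — Dice similarity between individual
  fingerprints, group-averaged similarity, unweighted neighbor joining with
  band-bootstrap clade support;
* **AMOVA** — one-way analysis of molecular variance on squared Euclidean
  distances, with a permutation test.

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` run the five stages against a simulated study-shaped dataset
and write the standard report tables; `run_pipeline()` does the same in one
call.

## Two readings of a primer's PIC

For one locus with allele frequencies \(P_j\),
\(\mathrm{PIC} = 1 - \sum_j P_j^2\).  For a multiband primer, what counts as
"the locus" is genuinely ambiguous, and the two readings differ sharply:

* `mode = "band"` treats every band as a biallelic dominant locus with
  phenotype spectrum \(\{p, 1-p\}\); each band's PIC is then at most 0.5,
  and the primer PIC is the mean over its polymorphic bands.
* `mode = "pattern"` (the default) treats each distinct multiband
  fingerprint of the primer across individuals as one allele of a single
  multiallelic locus.  With many individuals and several bands per primer,
  fingerprints are nearly unique and PIC approaches 1.

Published per-primer PIC values for fingerprint panels routinely exceed
0.9 — for an 11-band primer that is far above the \(1 - 1/k\) ceiling any
per-band or k-allele reading allows — so only the pattern reading can
reproduce their magnitude.  Both modes are exposed, and
`efficiency_report()` records which one was used.

## Allele frequencies from dominant data

Under HWE the null (band-absent) genotype has frequency \(q^2\), so from a
band-absence proportion \(x\) the default estimator is \(\hat q = \sqrt x\),
\(\hat p = 1 - \hat q\) (`method = "sqrt"`, the convention of the classic
POPGENE dominant-data model).  A bias-corrected option
(`method = "lynch_milligan"`) divides \(\sqrt x\) by \(1 - s/(8x)\) with
\(s = x(1-x)/n\), clamping to \([0,1]\); it matters only for small samples
and rare null phenotypes, and the package default deliberately stays with
the uncorrected square root so grouped results match the common
POPGENE-style reports.

Per band, the report computes Na (observed band states in the group: 2 when
both presence and absence occur, else 1 — this, averaged over loci,
reproduces the 1.4–2.0 range typical of published tables), Ne
\(= 1/(p^2+q^2)\), He \(= 1 - p^2 - q^2 \le 0.5\) and Shannon's
\(I = -(p\ln p + q\ln q) \le \ln 2\), with \(0\ln 0 = 0\).  Group rows are
means over *all* bands of the matrix, not only those polymorphic in the
group, so groups are comparable.  The Total row pools all samples rather
than averaging group rows — pooling is what makes total diversity exceed
the mean of the groups, which is exactly the It − Is gap the partition
measures.  `Is` averages group values unweighted by default (a `weighted`
switch exists); sample-size weighting is not what published Mean rows of
this kind use, and with near-equal group sizes the difference is in the
third decimal.

## Distances, the tree, and its support values

Individual similarity uses the Dice coefficient \(2a/(2a+b+c)\) — the
natural choice for dominant data because joint band absence carries no
information about shared ancestry and is excluded.  A pair of all-zero
profiles has no defined similarity and is treated as a data error.
`nj_tree()` is a from-scratch canonical Saitou–Nei neighbor joining with
the plain-average ("unweighted") distance update; it is exact on additive
distances (the tests verify every 4- and 5-leaf topology).  Two numerical
policies make it deterministic and well-behaved on noisy data: ties in the
Q-criterion are resolved to the lowest index pair, and a negative branch
length is clamped to zero with the deficit moved to its sister edge so the
cherry's total length is preserved.  Bootstrap support resamples band
columns with replacement (bands are the scored characters; a primer-block
option exists for users who consider bands within a primer non-independent),
rebuilds the tree per replicate, and writes each internal bipartition's
replicate percentage onto the original tree.

## AMOVA

The one-way AMOVA operates on squared Euclidean distances of the raw 0/1
profiles — for binary data, the Hamming count — which is the convention of
the classical band-data AMOVA formulation; Dice enters only the tree, never
the variance decomposition.  Sums of squares come from the standard
distance identities
\(SS_T = \frac1N\sum_{i<j}d^2_{ij}\),
\(SS_W = \sum_g \frac1{n_g}\sum_{i<j\in g}d^2_{ij}\), with
\(\sigma^2_{among} = (MS_A - MS_W)/n_0\),
\(n_0 = (N - \sum_g n_g^2/N)/(G-1)\).  These equal the ANOVA identity on
raw profiles to numerical precision, which the tests assert at 1e-9.  The
permutation test permutes the sample-to-group assignment and uses the
+1-corrected p-value \((1 + \#\{\sigma^2_{among,perm} \ge obs\})/(B+1)\),
so p is never 0; with the default B = 999 a result can be reported as
p ≤ 0.001.  A negative among-group component is legitimate under weak
structure; it is reported as-is with the variance proportions floored at
zero and a flag set.  Only the among component gets a p-value: a within-row
permutation p has no standard analogue in the one-way design.

## The simulator

`simulate_band_matrix()` provides ground truth for every estimator.  Its
defaults are the study conditions the workflow emulates: 20 accessions of
the published *Dactylis glomerata* panel (9 subspecies, 14 countries), 196
diploids in per-accession groups of 9–10 (published design: 6–10 plants per
accession, exact counts unpublished), 21 SSR and 15 IT-ISJ primers with
3–13 bands each, ancestral band-allele frequencies uniform on
\([0.05, 0.95]\) (every published band was polymorphic, so panels should
not be quasi-monomorphic), and Balding–Nichols divergence \(F = 0.2\),
chosen to match the ≈19% among-accession variance share of the published
AMOVA.  Per band, populations draw their dominant-allele frequency \(p\)
from \(\mathrm{Beta}\big(p_0(1-F)/F,\,(1-p_0)(1-F)/F\big)\) — mean
\(p_0\), variance \(F\,p_0(1-p_0)\) — and each diploid shows the band with
probability \(1-(1-p)^2\).

What the simulator does *not* emulate: linkage between bands (all bands are
independent), scoring error and band co-migration, mutation, and polyploid
dosage (the tetraploid accessions of real panels are scored as phenotypes
anyway).  Passing parameter-recovery tests therefore show the statistics
are computed correctly under the model's assumptions, not that those
assumptions hold for any particular gel dataset.

```{r example}
sim <- simulate_band_matrix(sim_config(seed = 1))
sim
div <- group_diversity(sim$matrix,
                       setNames(sim$metadata$subspecies,
                                sim$metadata$sample_id))
round(div$partition, 3)
am <- amova_oneway(squared_euclidean(sim$matrix),
                   setNames(sim$metadata$accession, sim$metadata$sample_id),
                   n_perm = 199, seed = 2)
am
```

At \(F = 0.2\) the realized among-accession share sits near 25% rather
than at the allele-level \(F\): dominance and the band-level distance
metric transform the variance scale, and the permutation test, not the raw
share, carries the inference.

## Problem sizes and numerical choices

The test suite and the acceptance script keep simulations at sizes chosen
to make Monte-Carlo noise negligible relative to the asserted tolerances:
500 diploids per population for estimator-recovery checks (RMSE bound
0.03), 200 replicates for the permutation-calibration and
bootstrap-support suites, 20 replicates per divergence level for the S′
monotonicity check.  Tolerances: frequency sums are validated at 1e-9;
AMOVA sums-of-squares identities at 1e-9; NJ exactness at 1e-8 (branch
lengths pass through decimal serialization).  Degenerate inputs are policy,
not accidents: monomorphic bands contribute zero to He/I and PIC; a group
with fewer than two samples is an error for diversity and AMOVA; an
all-zero fingerprint is an error for Dice; missing cells are rejected at
load (the published panels report none, and silent imputation would bias
every frequency).

## Limitations

Group assignments are taken as given — there is no admixture or clustering
inference here, and tree "groups" are annotations for the user to draw.
The AMOVA is strictly one-way (among/within); hierarchical designs are out
of scope.  He confidence intervals are not computed.  All statistics treat
bands as independent characters; for tightly linked bands the bootstrap
and the permutation tests are anticonservative, which is the main caveat
when reading support values on real fingerprint data.
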