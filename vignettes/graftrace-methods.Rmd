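---
title: "Tracing donor-derived malignancy from variant profiles: models and methods"
author: "graftrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing donor-derived malignancy from variant profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftrace)
```

## The problem

When an organ recipient develops an aggressive neoplasm shortly after
transplantation, the central question is whether the tumor grew from the
recipient's own cells or from malignant cells carried in the graft.
Histology can be ambiguous: a donor-derived tumor growing in a new host may
lose the marker expression that characterized the donor lesion. Genomics
resolves the question because a tumor's variant profile records *whose*
genome it grew from. A tumor carries (i) the germline of the individual it
originated in — common population polymorphisms plus rare or private
variants — and (ii) the somatic mutations acquired during tumor evolution.
If a recipient's tumor, after subtraction of the *recipient's* germline,
still contains another person's germline in bulk, and that residue matches
the donor, the tumor came from the donor.

`graftrace` implements this argument as a reusable pipeline over per-sample
variant sets (VCF or annotated TSV), together with a purity model, an MLPA
copy-number caller, and a synthetic cohort simulator that makes every stage
testable without access to protected patient data.

## The inference chain

1. **Germline subtraction** (`subtract_germline`). Pure identity-key set
   difference on (chrom, pos, ref, alt). Genotype and zygosity are
   deliberately ignored: the method compares variant *lists*, and any
   het/hom bookkeeping would change the arithmetic the decision rests on.
2. **Common-polymorphism filtering** (`filter_common`). A variant is a
   common polymorphism when its allele frequency is present and at least
   `af_threshold` (default 0.001) in at least `min_databases` (default 2)
   of the consulted catalogs (1000 Genomes, HapMap, dbSNP, ExAC, gnomAD) —
   "at least 0.001 in more than one database", read literally. A frequency
   absent from a database is *not* zero and does not meet the threshold;
   absence in all catalogs is itself informative (see classification
   below). Both partitions are kept: the removed "common" set carries the
   donor-overlap signal, the retained set is the enriched somatic profile.
3. **Overlap with the donor tumor** (`overlap_with_donor`). Key-membership
   counts of the putative somatic profile (and of its common subset)
   against the donor tumor. For a donor-derived lesion the post-subtraction
   profile overlaps the donor tumor massively, because it still contains
   the donor's germline.
4. **Sex discordance** (`count_sex_discordant`). With a female recipient
   and a male donor, any chrY variant in the lesion's putative somatic
   profile is physical evidence of donor DNA.
5. **Shared-variant tri-classification** (`classify_shared_coding`). Coding
   variants shared by all lesions are partitioned by precedence:
   ExAC absent or at most 9.4e-5 → *probably somatic*; ExAC in
   [1e-4, 9e-4] → *probably rare donor germline*; donor-tumor allelic
   fraction in [0.49, 0.51] → *probably heterozygous donor germline*;
   otherwise unclassified. The two germline tiers are population evidence
   and AF evidence for the same conclusion — variants inherited from the
   donor rather than acquired by the tumor.
6. **Decision** (`decide_transmission`). Transmission is called when any of
   three rules fires: profile overlap with the donor tumor at or above 80%;
   at least 5 sex-discordant chrY variants; or at least 2 probably-somatic
   *driver* genes (default list BRAF, PIK3CA, SDHC, DDR2, FANCD2) shared by
   all lesions. A lesion is called *not transmitted* when its profile is
   clean — at most 5% overlap — and no rule fired; anything else is
   *indeterminate*. The three decision thresholds are package defaults
   exposed in `transmission_thresholds()`, chosen so that evidence of the
   strength the method is designed to detect (overlap well above 80%,
   dozens of chrY markers, multiple shared driver hotspots) passes
   decisively, while a genuinely clean profile (sub-percent overlap) is
   called clean with margin. They are screening defaults, not estimated
   quantities.

### Which profile does each rule look at?

The overlap rule uses the *post-subtraction* profile when a matched blood
sample exists for the recipient: that is the profile in which a
donor-derived tumor retains the donor germline wholesale. When no germline
is available for a recipient, raw overlap is uninformative — any two
humans share most common polymorphisms — so the pipeline evaluates overlap
on the common-filtered retained profile, and the transmitted call for such
lesions rests mainly on the shared-driver rule.

The *clean* rule always uses the common-filtered profile. Subtraction alone
leaves a residue of common polymorphisms (variants missed in the blood
sample by capture dropout), which overlaps the donor tumor at the
population sharing rate; judging cleanliness after filtering removes this
nuisance term. This is the point of the filtering step: the cleaner
somatic profile is the object whose uniqueness is assessed.

## Purity and clonality

Under a diploid, copy-neutral model, a heterozygous truncal driver is
present on one of two alleles in every tumor cell, so its allelic fraction
is purity/2 and `estimate_purity` reports `round(200 * af)` percent
(half away from zero), clamped to 100 with a `capped` flag when AF exceeds
0.5 — AFs above 0.5 indicate copy-number events the model does not attempt
to interpret. No CNV/LOH correction is applied; this matches the method
being implemented and is a stated limitation. With a read depth, a 95%
Wilson interval on the AF (preferred over Wald because depths are moderate
and AFs can sit near 0) is propagated through the same ×200 map.

A single driver at mean depth 200 carries irreducible binomial noise: the
standard deviation of the purity estimate is
`200 * sqrt(af (1 - af) / 200)` ≈ 6–7 percentage points for mid-range
purities. Point estimates from one site should therefore be read with the
reported interval, not as exact percentages; recovering purity to within a
few points with high confidence requires either deeper coverage or
averaging over many truncal variants.

`clonal_ratio` compares a subclonal driver's AF to the truncal driver's in
the same sample; the ratio approximates the fraction of tumor cells
carrying the subclone (`near_clonal` at ≥ 0.85, `minor_subclone` at ≤ 0.5).
`detectable` encodes assay floors: 1% AF for LNA-PCR enrichment, 5% for
conventional exome calling.

## MLPA copy-number calling

`normalize_probes` first divides each sample's peaks by the mean of its
designated reference probes (intra-normalization; the arithmetic mean is
used — the commercial analysis software's exact algorithm is proprietary),
which makes ratios invariant to overall signal scale, then divides by the
mean intra-normalized value across reference individuals. With two or more
reference samples a 95% t-interval on the reference mean is propagated to
the ratio. Calls use strict borders — loss below 0.7, gain above 1.3, a
ratio exactly at a border is normal — and `call_region` applies a majority
rule over in-region probes with an exact tie resolved toward the abnormal
call (a screening context favors sensitivity; configurable). The default
region is the chr9 CDKN2A/CDKN2B deletion span 9:21,948,801–22,163,300.
In mixed tissue a homozygous loss does not reach ratio 0: residual normal
cells contribute signal, so the expected in-region ratio is `1 - purity`.

## The synthetic cohort simulator

The simulator exists so that every downstream stage can be validated
against known truth. It emulates, under one seed-deterministic generative
model:

- a **population catalog** (`simulate_catalog`): common-tier entries with
  sampling frequency uniform on [0.05, 0.5] and listed at ≥ 0.001 in at
  least two databases (so the common filter removes carried common
  variants by construction), plus rare-tier entries listed, when present,
  at frequencies uniform on [1e-6, 9e-4];
- **germlines** (`simulate_germline`): common variants carried under
  Hardy–Weinberg sampling at the catalog frequency (het AF 0.5, hom AF 1);
  1,500 private rare variants per individual by default, generated as
  fresh keys carrying rare-tier database frequencies — drawing them from a
  shared pool would make unrelated individuals share rare variants at the
  pool sampling rate, orders of magnitude above the sub-0.001 sharing of
  real rare variation; 20 hemizygous chrY variants for a male germline and
  none for a female one. The default catalog size (350,000 common entries)
  yields germlines of roughly 1.3–2.0 × 10^5 variants, the scale of a
  deeply sequenced exome call set;
- a **donor tumor** (`simulate_tumor_truth`): a truncal clone (fraction 1)
  carrying BRAF V600E plus three further drivers and 150 private
  mutations, and a minor subclone (fraction 0.3) carrying PIK3CA E545K — a
  pure-tumor AF of 0.5 × fraction per heterozygous somatic variant; a
  truncal homozygous CDKN2A/B deletion that silences somatic variants of
  its carrier clone inside the span (planting a driver inside its own loss
  is a configuration error);
- **observed samples** (`render_observed_sample`): donor-origin expected
  AF is diluted by purity; host-germline AF is not; key collisions keep
  the larger expected AF with a merged origin note; depth is
  Poisson(mean 200), alt reads Binomial(depth, expected AF); a variant
  with zero alt reads is not emitted (the caller detection model), and a
  uniform 2% capture-dropout is applied per sample. Sample purities
  default to 0.5 (donor tumor fragment), 0.97, 0.78 and 0.78 (the three
  lesions); each lesion also acquires 150 post-transplant private
  mutations;
- **MLPA tables** (`simulate_mlpa`): expected in-region ratio `1 - purity`
  for a homozygous loss, Gaussian ratio noise (SD 0.03 by default), and
  reference probes at ratio 1.

Ground truth (per-variant origin labels, purities, clone fractions, CNV
spans) is carried on every rendered profile and in the cohort's
`truth.json`. Recipient-origin comparison cohorts replace the planted
driver hotspots with private random mutations of equal count — an
independent tumor would not carry the same driver keys.

What the simulator does **not** model: read-level artifacts (no
FASTQ/BAM), sequencing error as false-positive calls, capture-region
structure (dropout is uniform rather than region-correlated, so the real
"off-target" depletion pattern is only approximated), linkage between
catalog variants, CNV-induced AF distortion outside configured events, and
tumor-in-normal contamination. Passing recovery tests therefore
demonstrates the correctness of the pipeline's logic under its stated
model, not robustness to every artifact of real exome data.

## Numerical and interface conventions

- Variant identity is (chrom, pos, ref, alt) after stripping a leading
  `chr` and upper-casing alleles; no indel left-normalization is attempted
  (inputs are assumed caller-normalized), because silent identity mismatch
  would corrupt the set arithmetic the verdict depends on.
- Coordinates are 1-based fully closed, per VCF convention; contigs
  outside 1–22, X, Y are dropped with a logged count so that
  chromosome-level logic operates on a closed universe.
- Percentages round half away from zero: one decimal for profile overlap,
  nearest integer for the common-subset overlap and for purity percent.
- In the tri-classification, the ExAC germline band takes precedence over
  the donor-AF band when both apply, keeping the tier counts disjoint; a
  variant reaching the AF rule without a donor AF is unclassified with a
  warning.
- Multi-allelic VCF records are split into one observed variant per ALT
  allele; AF is alt-supporting reads over total depth and is undefined
  (NA, not 0) at zero depth.

## Problem sizes used by the test suite

The validation suite exercises the full pipeline on scaled cohorts
(catalog of 2,000 common entries, 200 rare variants per individual, 60/20
clone-private mutations, 40 post-transplant mutations) so that a complete
simulate-plus-infer round stays well under a second; verdict recovery runs
100 such cohorts (half transmitted, half recipient-origin) and purity
recovery 100 seeds at three purities. Statistical recovery checks
(germline sharing rates, mean AF of truncal variants, purity recovery) use
moment-based oracles with 3-standard-error bands. The case-study count
arithmetic (subtraction, filtering, overlap rounding) is checked at full
scale — profiles of 1.5–2.0 × 10^5 variants — where the operations are
vectorized set arithmetic and take well under a second each.

## Known limitations

- Purity from a single driver site inherits binomial noise of ~6–7 points
  SD at 200× and is uncorrected for copy number; drivers with AF > 0.5 are
  reported capped rather than interpreted.
- The common filter treats database absence as "not meeting the threshold"
  in that database; a variant genuinely common in a population absent from
  all five catalogs would evade it.
- The decision rules are screening heuristics with configurable
  thresholds, not calibrated probabilities; the indeterminate verdict is
  the designed outcome for evidence between the transmitted and clean
  regimes.
- Variant merging across callers, annotation (consequence calling), and
  driver-database lookup are upstream of this package: each input sample
  is assumed to be one pre-merged, annotated variant set.
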