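---
title: "Detecting enhancer occlusion transcripts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting enhancer occlusion transcripts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Enhancers are clusters of transcription-factor binding sites (TFBSs) whose
activity is read out in H3K27ac/H3K9ac acetylation, p300 binding and eRNA
transcription. A distinct class of long non-protein-coding RNAs — here
called *enhancer occlusion transcripts* (EOTrs) — runs **across** enhancer
domains: capped (CAGE-supported), polyadenylated, carrying an H3K4me3
promoter and an H3K36me3-marked body. Where such a transcript covers a
TFBS, the elongating polymerase competes with the factor for the DNA, a
form of transcriptional interference: relative TF binding drops, the
enhancer's acetylation falls, polymerase pauses over the occluded site,
and the enhancer participates in fewer chromatin loops. `eotrscan`
implements the detection cascade for these transcripts and the battery of
statistics that quantify the interference, together with a seeded
simulator that plants every effect so that each stage can be validated
against ground truth.

## Coordinate and container conventions

All intervals are 0-based half-open; abutting intervals do not overlap.
GTF input (1-based inclusive) is converted on read. Internally interval
sets are `GRanges`, coverage tracks are run-length lists (`RleList`),
transcripts an S3 `transcript_set` (a metadata table plus a
`GRangesList` of exons). Strand `"."` is treated as `"+"` only when a
flank is requested without strand; the cascade always passes transcript
strand.

## Chromatin states

Candidate enhancers are the merged base-pair intersection of H3K4me1 and
p300 footprints; overlap with H3K27ac or H3K9ac makes them *active*,
otherwise *poised*. Active promoters require H3K4me3 + H3K4me2 + H3K27ac
+ RNAPII jointly; H3K4me3 ∩ H3K27me3 is *poised*, and poised dominates
when both rules fire (the repressive mark is the discriminating
signature). eRNA domains are enhancer candidates additionally carrying
both acetylation marks and **lacking** H3K36me3 and H3K4me3; their
direction is the majority strand of intersecting transcripts and CAGE
clusters, `"."` on ties. "Overlap" means ≥ 1 bp unless a fraction is
configured — the source definitions state mark combinations, not overlap
fractions. Replicate consensus is per-base voting (a base qualifies when
≥ `min_support` replicates cover it); the DiffBind consensus heuristics
are deliberately not reproduced.

An open choice: acetylation overlap could be tested against the
H3K4me1∩p300 footprint or against fixed windows around p300 summits. The
footprint is the default because it needs no summit information;
`min_frac` covers the stricter reading.

## The filtering cascade

Stages, in order, with per-stage survivor counts split intronic vs
intergenic:

1. **Unknown function** — transcripts with any exon overlapping an
   annotated exon are excluded; remaining transcripts are *intronic* when
   the majority of their span lies inside gene bodies, else *intergenic*
   (a contig gets exactly one category, hence the majority rule).
2. **Non-coding** — a logistic coding-potential model over four features
   (longest-ORF length, ORF coverage, Fickett TESTCODE score, hexamer
   log-likelihood ratio); CP ≥ 0.364 is coding, boundary inclusive. This
   is a simplified stand-in for CPAT, trained per dataset; its cutoff is
   kept at the published operating point. The coding filter is applied
   before the chromatin filters (the source leaves the order of the first
   two filters open; it is configurable here).
3. **Chromatin signature** — the 200 bp strand-aware *upstream* flank of
   the 3′ terminus must overlap H3K36me3 and the 1 kb upstream-of-TSS
   proximal promoter region (PPR) must overlap H3K4me3. The downstream
   200 bp flank is evaluated only as the control side of a reported
   Jaccard pair (case/control framing).
4. **Enhancer overlap** — the transcript span must intersect an enhancer
   state call.
5. **CAGE + polyA** — a CAGE cluster with IDR score ≥ 0.77 must place its
   representative peak inside the PPR (representative = highest score,
   ties to the peak nearest the TSS), and the transcript must be
   polyadenylated.
6. **TFBS intersection** — the span must cover ≥ 1 TFBS of a TF with
   ChIP count data.
7. **Occlusion** — the final EOTr call requires at least one intersected
   TFBS whose fitted binding parameter is unfavorable (below).

Survivor counts are non-increasing by construction.

## Affinity model

A PWM scores windows as log2 odds against a uniform background.
`max_binding_wts` rescales the best window on either strand to [0, 100]
between the worst and best achievable site scores; the upstream tools do
not document their scaling, so these values are directional, not
exact-match quantities. Mismatch energies E = β(S_best − S) with
β = 1/0.7 feed the occupancy p = R0·e^(−E)/(1 + R0·e^(−E)) with
ln R0 = 0.584·L − 5.66 (the constants of the affinity-prediction tool the
field uses for display). The binding parameter γ is fitted by predicting
region occupancy N_r(γ) = Σ_i γa_i/(1 + γa_i) (a_i = e^(−E_i), single TF,
no cooperativity) and searching log10 γ ∈ [−6, 6] (coarse grid plus
local refinement). γ > 1 is a favorable interaction, γ < 1 unfavorable;
the Pearson correlation at the optimum is reported as `exp_ratios`. Any
such fit is *relative*: only the shape of occupancy across regions
identifies γ, which is why both the simulator and any informative
dataset need sites of heterogeneous strength. The default objective is
the Poisson deviance between intensities and c·N_r(γ) with the scale c
profiled out in closed form. An SSE on z-scores (available as
`objective = "zsse"`) was the original design, but it is ill-behaved in
the weak-binding regime: for small γ the occupancy is nearly
proportional to site content, a scale-free SSE cannot see a
proportionality change, and fitted values drift by orders of magnitude
under counting noise. The profiled-deviance fit keeps the scale-free
contract while weighting low-count regions properly; its fitted medians
land on planted values.

The expression threshold for effective occlusion is a decision stump on
log2 CPM minimizing misclassification of favorable vs unfavorable calls,
ties broken toward the minimum expression among unfavorable-associated
transcripts (the reading "minimum required to occlude").

## Association statistics

The genomic Jaccard index is base pairs of intersection over union. Its
null distribution approximates the Genome Structure Correction by
stratified circular rotation: within each analysis domain (datasets are
split into intronic and intergenic blocks) the second feature set is
rotated by an independent uniform offset, preserving lengths and
spacings; p = (1 + #{null ≥ observed})/(n_perm + 1), and the TRUE/FALSE
direction reports whether the observed overlap is below the null median.
The original tool's block-bootstrap internals are undocumented; the
rotation null is a documented stand-in with the correct invariances.
Relative distances (nearest-b-midpoint distance over flanking-midpoint
distance) are tested against Uniform(0, 0.5) by a one-sample KS test.
χ² on 2×2 peak-count tables is Pearson without continuity correction
(counts are large in the served comparisons; a Yates option exists). PWM
divergence is the symmetrized per-position KL in bits after pseudocount
renormalization, aligned at the offset maximizing column-wise
correlation; the source does not state base or symmetrization, so these
values are comparative only.

## Pausing

The pausing index is mean signal over a feature divided by mean signal
over the whole transcribed domain. Partial end bins are length-weighted,
which makes the binned mean equal the plain per-base mean — so the index
is invariant to bin size on piecewise-constant tracks and to global track
rescaling, and a length-weighted aggregate over a tiling of the domain
is exactly 1. The default domain is the transcript span; per-locus
indices are summarized by the median (the pooled alternative is a
one-liner on the returned means).

## Allelic analysis and loops

Allelic imbalance at an SNV uses the exact two-sided binomial test at
p = 0.5 (summing all outcomes whose point mass does not exceed the
observed one); RNA-editing sites must be masked upstream and are an
error here. Allelic enhancer-activity contrasts reuse the differential
machinery with `scale = FALSE` and equal library sizes, because allele
layers come from a single library and a genuine genome-wide activity
shift between alleles must not be normalized away. Loops with one anchor
in an enhancer classify the distal anchor as promoter (H3K4me3),
insulator (CTCF without H3K4me3) or other; the rule is symmetric under
anchor swap, and the intra:inter chromosomal contact ratio reports an
infinity flag when no inter-chromosomal contact exists.

## Differential calls

CPM uses median-of-ratios size factors on top of library sizes. The
dispersion (BCV²) is a pooled method-of-moments estimate,
φ = Σ(v − m)/Σm² over replicated features. Fold-change classes are
{−1, 0, +1} with |L2FC| > 1.5 **and** BH-adjusted q < 0.05 (pseudocount
0.5 on CPM means). P-values come from label permutation of a
variance-moderated statistic **pooled across features**: with three
replicates per side only 20 distinct label assignments exist, so a
per-feature permutation p can never fall below 0.05 and no q could pass
0.05; pooling (with the identity and complement assignments excluded
from the null) restores resolution at the cost of assuming approximately
exchangeable null features. This replaces the GLM machinery of the
published analysis deliberately — direction and threshold logic are
preserved, numerical q-values are not comparable.

## The simulator: what it emulates

`sim_config()` defaults *are* the stated world: 60 planted EOTrs among
300 candidate transcripts; EOTr expression log2 CPM 3–6 versus eRNA
0.42–1.70 (the published HepG2 threshold bands); pausing ratio 5;
acetylation attenuation 0.4 at EOTr enhancers; allelic reference
fraction 0.8; 4 loops per active versus 1 per occluded enhancer with the
intra:inter ratio cycled to 5:2; negative-binomial dispersion 0.1;
Poisson coverage at 50 per 10 bp bin. Where the sources give no value
(TSS peak fold 4, ChIP depth, locus geometry) a single realistic choice
was made and is not tuned. Two design points deserve emphasis:

* The TFBS emission rate is solved from the piecewise-constant
  expectation profile so that the *quotient itself* equals the configured
  pausing ratio — planting the rate naively would bias the recovered
  index low because the feature and the TSS peak are part of the domain.
* TF ChIP intensities are drawn from the occupancy model at a planted γ
  per class (occluded γ = `chip_tf_attenuation` × `gamma_active`),
  with planted sites mixing exact-consensus and one-mismatch motifs.
  A pure intensity scaling would be invisible to the scale-free fit;
  planting a weaker binding parameter is also precisely the claimed
  biology. PWM content is identical between occluded and control sites,
  mirroring the observation that PWM scores match while occupancy
  differs.

What the simulator does **not** model: read-level sequencing, mappability
and GC bias, replicate-specific batch effects, overlapping loci, more
than one TF motif family, and genuine haplotype sequence divergence
(alleles are count layers over shared coordinates with SNVs every
~500 bp). A green planted-truth test therefore establishes correctness of
the *computations*, not robustness to every artefact of real ENCODE
data; the published full-data numbers (pausing 4.8/4.2 vs 1.2/0.9 and
0.12/0.20, Jaccard 0.87, contact ratio 5:2) are reachable only with the
original accessions.

## Numerical choices and degenerate inputs

Empty-union Jaccard, zero-signal pausing domains, single-class threshold
input, constant ChIP intensities, unreplicated BCV and masked ASE sites
are errors, not silent values. Flanks clip at the chromosome start (the
one documented clamp). Permutation seeds are explicit arguments; every
simulator draw flows from `config$seed`, and reruns are byte-identical.
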