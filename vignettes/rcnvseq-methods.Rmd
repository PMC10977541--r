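---
title: "Copy-number analysis of low-pass prenatal sequencing: models, parameters and design choices"
author: "rcnvseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of low-pass prenatal sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnvseq)
```

## The measurement and its statistical model

A rapid, PCR-free low-pass whole-genome sequencing screen for prenatal
diagnosis produces on the order of five million single-end 45-bp reads
per sample; after removal of the adapter portion the 36-bp genomic
sequence is aligned, and roughly 2.8--3.2 million reads map uniquely —
about 0.06x genome coverage. At that depth individual positions carry
no information, but *dosage* does: a region present in three copies
instead of two receives, in expectation, 1.5 times the reads.

`rcnvseq` models the uniquely mapped read count of 20-kb bin $i$ as

$$X_i \sim \mathrm{Poisson}\!\left(m \cdot w_i \cdot \frac{c_i}{2}
\cdot g(\mathrm{GC}_i)\right),$$

where $c_i$ is the local dosage on the diploid scale ($c_i = 2$ for a
normal autosomal bin), $w_i$ the bin's width share (terminal bins are
truncated at the chromosome end), $g$ a GC-dependent efficiency, and
$m$ a sample-level scale absorbing the read budget. Poisson shot noise
is the appropriate default at $\lambda \approx 19$ reads per bin; a
negative-binomial option (`seq_config(noise = "nb")`) represents
overdispersed libraries, and multinomial allocation
(`noise = "multinomial"`) conserves the mapped total exactly.

Mosaicism and, in cell-free DNA, the fetal fraction, act through the
same mixture relation: a cell line at integer copy number $k$ present
at fraction $f$ shifts the observed dosage to

$$c = 2 + f\,(k - 2),$$

so a trisomic line at $f = 0.5$ yields $c = 2.5$ and the inverse
$f = |c - 2|$ recovers the fraction for single-copy events
(`mosaic_fraction()`).

### Classification thresholds

Calls are classified on the diploid CN scale with the five-state
thresholds used in clinical low-pass CNV screening: duplication above
2.8, deletion below 1.2, disomy between 1.8 and 2.2, and the mosaic
ranges in between. The published inequalities are strict on both sides,
leaving the four boundary values unassigned; `cn_thresholds()` closes
the disomy interval at 1.8 and 2.2 (a boundary value is conservatively
called normal) and assigns 2.8 to mosaic trisomy and 1.2 to mosaic
monosomy, so `classify_cn()` is a total deterministic partition of
$[0, \infty)$ — a property the test suite checks on a dense grid.

Note a tension these thresholds inherit: a mosaic becomes *classifiable*
only once $|c - 2| > 0.2$, i.e. $f > 0.2$ for single-copy events, even
though chromosome-level dosage at 0.06x is measurable far below that
(the standard error of a whole-chromosome mean CN is below 0.01). The
package classifies as the thresholds dictate — a whole-chromosome
profile at $c = 2.1$ is disomy — and leaves the discrepancy with more
optimistic mosaic-sensitivity claims visible rather than recalibrating.

## Normalization choices

**Baseline.** Per-bin CN is $2\,r_i/b$ with $r_i$ the width-corrected
rate and $b$ a robust centre of the *autosomal* rates. The default is a
10% trimmed mean rather than the median: at $\lambda \approx 19$ the
integer-valued median (19) differs from the mean (~19.4) by about 2%,
which would bias the whole CN scale by the same amount — right at the
edge of the $\pm 2\%$ dosage accuracy the pipeline otherwise achieves.
The trimmed mean is smooth in the data yet still ignores the bins of a
whole-chromosome trisomy (at most ~2% of autosomal bins on the full
grid, all in the trimmed tail). `baseline = "median"`, `"mean"`, or a
numeric reference-panel rate are available.

**GC correction.** `gc_correct()` equalizes per-stratum rates
(strata of width 0.02 in GC fraction). Factor estimation first masks
autosomes whose chromosome-level depth deviates more than 10% from
diploid — otherwise a trisomy contaminates the strata its bins occupy —
and then uses plain stratum means: stratum *medians* of integer counts
jump in steps of $1/\lambda \approx 5\%$ and would randomly attenuate
or inflate entire strata, measurably hurting both bias removal and
detection power. Classical unmasked `"median"`/`"trimmed"` estimators
remain available for comparison. With bias disabled in the simulator
the correction is an identity up to noise (exactly so when all bins
share a stratum).

**Sex chromosomes.** Constitutional sex is inferred from chrY mean CN
(threshold 0.5); expected dosage is then X/Y = 2/0 (XX) or 1/1 (XY),
and classification on the sex chromosomes uses the dosage-relative
scale $2c/e$, so a normal male X is disomy ("normal for sex") and an
extra X in a male background is a duplication. Karyotype-style labels
(45,X; 47,XXY; 47,XYY; 47,XXX; 48,XYYY) come from the rounded X+Y copy
map at triage.

## Segmentation: a deterministic multi-scale scan

Per-bin classification is meaningless at this depth — a single bin's CN
has standard deviation $2/\sqrt{\lambda} \approx 0.46$, so bin-level
states are noise, and merging runs of identical bin states cannot
detect even the designed 100-kb floor. Instead `segment_profile()`
scans each chromosome with Poisson z-scores

$$z = \frac{S_\mathrm{obs} - S_\mathrm{exp}}{\sqrt{S_\mathrm{exp}}}$$

over sliding windows at dyadic sizes from `min_bins` (default 5 bins =
100 kb) up to the whole chromosome. Windows with $|z| \ge$ `z_cut`
become seeds; each seed is refined to the same-direction sub-interval
(at least `min_bins` long) maximizing $|z|$ in a bounded
neighbourhood; refined segments are accepted strongest-first without
overlap, dropped if they classify as normal dosage, re-averaged, and
classified with the five-state thresholds. The procedure is fully
deterministic and auditable — there is no permutation step and no
hidden state — which is why it was preferred over circular binary
segmentation or hidden-Markov smoothing; breakpoints are never refined
below bin resolution.

Whole-chromosome events need no special casing: the largest window *is*
the chromosome, so a trisomy (even at mixture fraction 0.3, where
$z \approx 32$ on chr21) produces a single chromosome-spanning segment
that suppresses its own sub-windows.

### Detection stringency and the 100-kb floor

The floor event — a 100-kb heterozygous duplication, 5 bins at
$c = 3$ — carries a signal of

$$z_\mathrm{sig} = \left(\tfrac{c}{2} - 1\right)\sqrt{w\,\lambda}
= 0.5 \sqrt{5 \times 19.4} \approx 4.9$$

standard deviations, while a 20-kb-binned genome offers ~150,000
window positions at the smallest scale. Those two numbers do not leave
room for both high sensitivity and family-wise error control: a
genome-wide 5%-FWER threshold (~4.5σ) detects the floor event with
probability ~0.6, whereas the default `z_cut = 3.2` puts detection
near $\Phi((4.9 - 3.2)/1.2) \approx 0.92$ at the cost of, in
expectation, a few hundred short mosaic-grade false candidates per
genome under the null (about 0.1--0.2% of windows). The default is
therefore *sensitivity-first*, matching the screen's purpose: the
reportable units — whole-chromosome dosage, known pathogenic regions,
large CNVs — are unaffected by the candidate load, and a confirmatory
profile is one parameter away (`z_cut = 4.5` or higher). Raising
coverage, not the threshold, is the only way to move the floor itself.

Two consequences are worth knowing. First, a sub-floor event (e.g. a
strong 60-kb duplication) is never reported at its true size — no
segment shorter than `min_bins` exists — but can surface as an
attenuated, mosaic-grade 100-kb candidate, exactly as in CBS-style
pipelines. Second, a noisy disomic genome does *not* produce a clean
segment list at the default stringency; the invariant the pipeline
guarantees on such genomes is dosage accuracy (autosomal mean CN within
2% of 2), not an empty call list.

## Annotation and triage

Calls are reported in the field's vocabulary: an ISCN-like region
string `dup(21)(q11.2q22.3)` (with a `(mos)` suffix for mosaics) from
cytoband lookup of the endpoints, an HGVS-like genomic coordinate
string `chr21:g.14300000_48129895dup` (1-based inclusive throughout;
fragment size is `end - start + 1`, rendered in Mb to two decimals),
and a per-case triage category with precedence

multi-chromosome > common aneuploidy (21, 18, 13) > sex-chromosome
aneuploidy > rare autosomal aneuploidy > pathogenic CNV > CNV of
uncertain significance > normal,

where "multi-chromosome" requires whole-chromosome-level events
(≥ 90% of a chromosome's bins) on at least two chromosomes. Because no
formal pathogenicity criteria accompany the screen, the default rule is
deliberately minimal and configurable: membership in a packaged
recurrent-region list — seeded with the Xp22.31 deletion covering the
steroid sulfatase (*STS*) gene, the dominant pathogenic CNV class in
this setting — or size at least 1 Mb; ACMG-style scoring is out of
scope.

The packaged cytoband table is a *condensed, synthetic* reconstruction
of the hg19 ideogram (1-based inclusive; `read_cytoband()` also
converts genuine UCSC 0-based files): sub-band resolution is kept on
chr7/13/15/18/21/X/Y where the packaged reports need it, major bands
elsewhere. One genuine ambiguity is pinned down explicitly: the
chr21 q11.1/q11.2 boundary is drawn so that position 14,300,000 lies in
q11.2, the dominant convention for reporting the trisomy-21 region;
source reports print both `q11.2q22.3` and `q11.1q22.3` for identical
coordinates, and the reconstruction reproduces the former
deterministically, flagging the latter as an internal inconsistency
rather than guessing intent. (A related cosmetic conflict — the
trisomy-18 region described as `q22.1q23` in prose but printed as
`p11.32q23` in the report table — is likewise left visible.)

## The karyotype parser and cohort summaries

`parse_karyotype()` covers the notation of clinical G-banding reports:
modal number, sex complement (`X0`/`XO` normalized to `X`),
whole-chromosome gains/losses, Robertsonian and reciprocal
translocations, inversions, satellite/heterochromatin polymorphisms
(`14ps+`, `1qh+`), markers, `dup`/`del` tags, and mosaic cell lines
with optional cell counts (an empty `[]` is a mosaic of unknown
proportions). Formatting is normalization-stable: re-parsing a
formatted string reproduces identical fields.

`reconstructed_cohort()` packages a 424-case table rebuilt from the
published aggregate report of a high-risk prenatal cohort (region/zone
counts, two karyotype tables, age and gestational-age strata, and the
follow-up narrative). It is a synthetic reconstruction, not deposited
data: where only aggregates were published, rows carry category-level
labels, and within-stratum ages are deterministic symmetric grids that
hit each stratum's published mean exactly (the spread is capped by the
stratum bounds, so stratum SDs are conservative). Conventions worth
noting:

* Percentages use round-half-up to two decimals, the convention of the
  source report — which itself occasionally truncates (203/424 is
  printed as 47.87 where round-half-up gives 47.88); summaries here
  always compute round-half-up.
* The karyotyped subgroup counts as published (156 + 68 + 1 + 21) sum
  to 246 over a denominator of 245; the reconstruction resolves this to
  245 karyotyped cases and reproduces the three subgroup rates that are
  internally consistent (63.67%, 27.76%, 0.41%), leaving the "other
  abnormal" rate unreproducible by arithmetic.
* One Y-dosage case carries a 48,XYYY karyotype; sequencing dosage
  labels it 47,XYY, and concordance is category-level, so the pair is
  concordant.
* Tetraploidy (92,XXXX) is invisible to read-depth ratios;
  `concordance()` returns `not_compared` with subtype
  `ploidy_invisible` for whole-genome ploidy multiples, leaving exactly
  one discordant fetus — a sub-5-Mb pathogenic CNV facing a normal
  karyotype, flagged with subtype `expected` because G-banding cannot
  resolve events below ~5 Mb.
* Follow-up outcomes not fixed by the published narrative are filled
  with deterministic conventions (and only narrated rows are asserted
  by tests).

## What the simulator does and does not emulate

`simulate_case()` reproduces the *statistical* structure of the screen:
the read budget and unique-mapping yield, 20-kb binning with truncated
terminal bins, X/Y dosage baselines for either sex, whole-chromosome
and segmental events under the mixture model, a monotone quadratic
GC-bias curve (disabled by default, so the correction stage has
something real to remove when enabled), and the three noise models.
The packaged GC track is a smooth synthetic isochore-like oscillation,
not sequence-derived GC.

It does not emulate: mappability gaps and unmappable acrocentric
p-arms (every bin is observable, so simulated whole-chromosome calls
span the full chromosome where real ones start at the first mappable
band), PCR or optical duplicates (the assay is PCR-free; no
deduplication stage exists), alignment errors, base-level sequence, or
an explicit maternal-plasma model — the thresholds are stated on the
pure-sample CN scale, so the simulator exposes the mixture fraction
`f` as the single knob covering both mosaicism and fetal fraction and
leaves the cfDNA interpretation to the analyst. Passing tests
therefore demonstrate correctness of the dosage model, the estimators
and the reporting logic under the designed noise, not robustness to
artefacts absent from the generative model.

## Problem sizes and numerical conventions in the test suite

Unit tests run on a scaled toy genome (24 chromosomes of 2--5 Mb,
~4,300 bins) where a simulate-fit cycle takes well under a second;
recovery and detection properties run on the full hg19 grid (154,794
bins) at 3.0 million mapped reads, with 20 seeds for the disomic-dosage
and 100-kb detection checks and three seeds per mixture fraction for
mosaic recovery. Dosage recovery on disomic genomes is evaluated over
autosomes: in an XX simulation chrY sits at CN 0 by design and would
mechanically drag an all-chromosome mean to ~1.96 regardless of
calibration. Other conventions: coordinates are 1-based inclusive
everywhere (a read on a bin boundary belongs to the lower bin; BED
input is converted on read with an explicit dialect flag); read
assignment uses the leftmost mapped position; uniqueness is a MAPQ
threshold (default 30) when reading SAM; overlap ties in segmentation
are broken strongest-|z|-first; degenerate inputs (empty chromosomes,
zero baselines, all-non-unique read sets, unknown outcome strings)
fail loudly rather than silently.

## Known limitations

* The sensitivity-first default stringency trades specificity for the
  100-kb floor, as quantified above; candidate lists on real data need
  downstream filtering (recurrence, known-region matching) that is out
  of scope here.
* Breakpoints are bin-quantized; no sub-bin refinement is attempted.
* The pathogenicity rule is a size floor plus one packaged region; it
  is a placeholder for curated region lists, not a clinical classifier.
* The cytoband table is condensed; band strings for chromosomes other
  than 7/13/15/18/21/X/Y are major-band approximations.
* Tetraploidy and balanced rearrangements are invisible in principle to
  depth-ratio methods and are handled only at the concordance layer.
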