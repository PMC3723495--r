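---
title: "Methods: single-molecule and bulk analysis of gene resilencing"
author: "resilencer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule and bulk analysis of gene resilencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilencer)
```

## Scope and model

`resilencer` analyses amplicon-scale epigenetic time courses of the kind
used to dissect gene resilencing after hypomethylating-agent withdrawal:
a promoter CpG island is assayed by NOMe-seq / allelic bisulfite clone
sequencing (single molecules), and by qPCR-based bulk assays (expression,
MNase nucleosome levels, ChIP enrichment), pyrosequencing and LC-MS/MS
(global methylation). The package's job is the analytic layer: context
annotation, clone alignment, dual methylation/accessibility calling,
footprint and molecule classification, ΔΔCt-family arithmetic, and
event-ordering statistics. Wet-lab steps (culture, dosing, cloning
chemistry, raw pyrograms and mass spectra) are out of scope; the package
consumes sequences, Ct tables and per-site percentages.

## Coordinates and cytosine contexts

All coordinates are 0-based, half-open; a CpG or GpC site is identified
by the coordinate of its C on the top strand. Only the top
(bisulfite-converted sense) strand is modeled: amplicon clone analysis is
strand-resolved at the wet-lab stage, so nothing analytic is lost.

Each cytosine is assigned one context:

* **cpg** (HCG): C followed by G, not preceded by G — reads endogenous
  methylation.
* **gpc** (GCH): C preceded by G, not followed by G — reads M.CviPI
  accessibility.
* **gcg**: C both preceded and followed by G. The mark at such a site
  cannot be attributed to either enzyme, so GCG sites are excluded from
  both analyses. This is the established NOMe-seq convention and is
  required for correct calling.
* **control**: C adjacent to no G. These carry no methylation of either
  kind and must read T after conversion; the observed converted fraction
  per clone is the conversion-rate estimate used for QC.

Note the CCG cytosine is kept in the CpG class (it is a genuine CpG and
will resist conversion when methylated); only the GCG overlap is
ambiguous. Treating CCG as a conversion control would bias QC downward.

## The simulator

The generator is the study-conditions oracle for every downstream stage;
its defaults are fixed once and are not tuned per analysis.

**Reference amplicons.** `generate_reference()` plants CG and GC motifs
by stratified sampling (one motif per window of width 1/density) on a
G-free A/C/T background, plus a couple of GCG motifs to exercise the
ambiguous path. Stratification guarantees the even GpC coverage an
informative NOMe amplicon needs — every ~1/density bp window contains a
GpC — rather than leaving informativeness to chance. Defaults (600 bp,
CpG density 0.04, GpC density 0.05, TSS at the midpoint) give a
CpG-island-scale amplicon with ~30 CpGs and ~35 GpCs, matching the
scale of promoter bisulfite amplicons.

**Populations.** Molecule classes couple a per-CpG methylation
probability with a nucleosome configuration. The demethylated class
(p = 0.03 per CpG) is *enforced by construction* to carry ≤ 2 methylated
CpGs, and the hypermethylated class (p = 0.98) to carry ≥ 90% — so exact
configured class counts are realized exactly, which is what a fixture
encoding a printed "10 of 32 demethylated" composition requires. A free
(unenforced) class is available for property tests of the binomial
sampler.

**Nucleosomes.** Core-particle width defaults to 147 bp (the canonical
particle; mononucleosome gels select ~150 bp fragments). A TSS-occupied
molecule receives *two abutting* core particles spanning the TSS
(294 bp of protection) plus flank tiling with 15–45 bp linkers; a
TSS-depleted molecule keeps a nucleosome-depleted region of ±180 bp
around the TSS. The di-nucleosome block is deliberate: a single 147 bp
particle can evade a ≥ 150 bp footprint rule whenever accessible GpCs sit
immediately at its edges, which would make truth-vs-call equivalence
depend on GpC spacing. Promoter occupancy in silenced alleles is
typically multi-nucleosomal (TSS plus exon-1 particles), so the block is
also the biologically sensible configuration. GpC accessibility is
derived, not sampled: a GpC is accessible iff it lies in no nucleosome
interval.

**Chemistry.** `apply_assays()` applies, in order: enzymatic GpC marking
of accessible sites (efficiency default 0.97), bisulfite conversion of
unmethylated Cs (rate default 0.995), inappropriate conversion of
methylated Cs (default 0.002), and per-base sequencing errors (default
0.001). These defaults are typical of a well-run bisulfite experiment;
`perfect_assay_params()` gives the error-free limit in which calling
must reproduce truth exactly. Ambiguous GCG cytosines are simulated as
enzyme targets but carry no endogenous methylation — they are excluded
from calling either way, so only the conversion-control tally could be
affected, and they are not counted there.

**Amplification bias.** NOMe assays over a TSS are sometimes designed to
preferentially amplify unmethylated templates. `amplify_with_bias()`
models the simplest monotone form: a clone with *m* methylated CpGs
inside the primer footprints is sampled with weight `w^m`, `w ∈ [0, 1]`
(`w = 1` unbiased, `w = 0` hard exclusion).

**Ct tables.** Under 100% amplification efficiency,
`ct = base_ct − log2(q) + N(0, σ)`. The clone-depth and noise parameters
the underlying assays do not pin down (cloning depth per day, Ct noise)
are exposed as arguments rather than assumed.

What the generator does *not* emulate: read-level FASTQ qualities,
chimeric/recombinant clones, strand errors, PCR duplicate families with
shared errors, or chromatogram artifacts. Passing tests therefore show
correctness of the analytic layer under a faithful but idealized error
model, not robustness to every artifact of real Sanger data.

## Alignment

Amplicon clones match the reference end to end up to a few events, so
`align_clone()` runs a banded global alignment (match 0, mismatch 1,
gap 1) with band `|Δlength| + 2`; a reference C read as T is bisulfite
conversion and scores as a match. The banded dynamic program is run even
when lengths are equal: a compensating insertion+deletion pair leaves the
length unchanged but makes the gapless identity map grossly suboptimal,
and the aligner is required (and tested) to agree with an exhaustive
dynamic-programming oracle on small instances. When the identity map is
optimal the DP returns it. Clones whose non-C/T mismatch fraction
exceeds 0.10 (configurable) are rejected with a logged reason; clones
deviating more than ±10% in length are not attempted.

## Calling and QC

At each CpG site: C → methylated, T → unmethylated, anything else
(including a site unaligned because of a deletion) → undetermined. At
each GpC site: C → accessible (enzyme-marked), T → inaccessible, else
undetermined. Undetermined is a first-class state: it leaves both the
numerator and denominator of every downstream fraction. Conversion QC
passes a clone when its control-cytosine conversion rate is ≥ 0.95
(configurable); the assays behind such data report no explicit rule, so
the threshold is exposed, and clones with no informative control
cytosines are retained with an undetermined QC flag and a warning.

## Classification and footprints

A molecule with fewer than 5 determined CpG calls is unclassifiable and
excluded (logged). Otherwise it is **demethylated** when
`mcpg ≤ max_methylated` (default 2 — "complete or near-complete
demethylation"), **hypermethylated** when `mcpg/assayed ≥ 0.9` (the 0.9
is a package convention; only the demethylated/not dichotomy carries the
headline statistics), else intermediate.

Footprints are maximal runs of inaccessible GpCs. The protected interval
extends *to the nearest flanking accessible GpC* (exclusive) on each
side, or to the amplicon edge: an inaccessible run's protection
plausibly extends to the nearest positive evidence of accessibility, and
edge-bounded runs still count (protection is never claimed beyond the
assayed sequence, but a run reaching the edge is not discarded).
Measuring instead only the span of the inaccessible GpCs themselves
would systematically undercall nucleosomes on sparse GpC grids; the
convention is configurable via `min_length` and documented here because
the ≥ 150 bp rule's precise measurement basis is a genuine open choice.
Undetermined GpCs are transparent — they neither break nor bound runs,
because a missing observation is not evidence of accessibility. A run
must contain at least one *called* inaccessible GpC; a molecule whose
GpCs are all undetermined yields an undetermined occupancy verdict. A
molecule is TSS-occupied iff a retained (≥ 150 bp) footprint contains
the TSS coordinate.

Percentages in population summaries are rounded half-up (31.25 → 31.3),
matching how such percentages are conventionally printed; R's
round-half-even would print 31.2.

## Bulk quantification

All qPCR arithmetic assumes 100% amplification efficiency (base 2);
no standard curves are modeled, and the base is a parameter everywhere
(efficiency *e* ⇒ base 1 + *e*), with a property test asserting the
swap propagates consistently. Replicates are averaged on the Ct scale
before transformation (the common convention); linear-scale averaging is
available by flag. All ratios are invariant to a global additive Ct
shift (ΔΔCt cancellation), which is asserted as a property test. ChIP
enrichment follows the subtract-IgG-then-normalize-to-input reading
literally — `max(2^-Ct_ab − 2^-Ct_IgG, 0) / 2^-Ct_input` — with a
dilution factor argument; percent-of-input without subtraction can be
had by passing an infinite IgG Ct. Global methylation uses the
denominator 5mdC + dC (percent of cytosines methylated), the convention
consistent with percent-scale reporting of LC-MS/MS nucleoside data.

## Time-course statistics

**Onset.** Resilencing onset is the first sampled day, after the
post-withdrawal expression maximum, whose value strictly decreases
relative to the previous sampled day. No smoothing: the definition is
phrased on raw measurements, and the sampled grid is daily where it
matters. A flat or non-decreasing series returns "unreached" (`NA` with
a reason attribute) rather than a day.

**Half-recovery.** For a metric driven from baseline *b* to extreme *x*,
the half-recovery day is the linearly interpolated day at which the
series first crosses (b + x)/2 after the extreme's day. Linear
interpolation between sampled days only — sampling is sparse (e.g.
methylation at days 0, 3, 5, 8, 17, 45) and any spline would overfit;
no extrapolation beyond the observed range, with non-crossing series
flagged "unreached".

**Ordering.** `event_order()` sorts metrics by half-recovery day (stable
sort; ties keep listing order and set a flag) and exposes the predicate
`nucleosome_before_methylation`. The simulator's default scenario sets
nucleosome half-recovery at day 6 and methylation at day 11 with 4
percent-point Gaussian noise on the sparse harvest grid; a parameter
recovery test requires the predicate to be `TRUE` in ≥ 95 of 100 seeded
runs, and a `reversed` scenario flips the truth to check the test has
power in both directions.

## Pipeline and problem sizes

`run_pipeline()` chains reference generation, per-day populations,
chemistry, calling, classification, quantification and event ordering
from a JSON config (schema version 1), writing FASTA/BED/TSV/JSON/text
artifacts with per-stage record counts and seed provenance; identical
config + seed gives byte-identical outputs. The bundled default config
uses per-day clone counts of 25–45 molecules on a 600 bp amplicon —
the scale of real allelic bisulfite clone sets, and the scale at which
the whole test suite and acceptance script run in well under a minute
each on one core. Property suites use 1000–2000 molecules or replicates
where binomial/Gaussian parameter recovery within 3 SE is asserted.

## Known limitations

* Single-amplicon, single-strand analysis; no genome-scale bisulfite
  alignment or paired-end short-read support.
* Footprint calling is maximal-run based: no dyad-position inference,
  phasing, or deconvolution of overlapping nucleosome configurations.
* The ±10% clone-length gate and 2-indel band are tuned for Sanger
  amplicon clones; heavily rearranged clones are rejected, not rescued.
* Event ordering is descriptive (an ordering statistic on half-recovery
  days); it does not model causality between marks, nor distinguish
  active remodeling from clonal expansion.
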