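---
title: "Methods: post-alignment ATAC-seq quality assessment with atacdeck"
author: "atacdeck maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-alignment ATAC-seq quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdeck)
```

# The problem

ATAC-seq uses the hyperactive Tn5 transposase, preloaded with sequencing
adaptors, to fragment and tag accessible chromatin in one step.
Because almost every property of a library — over- or
under-transposition, mitochondrial contamination, PCR bottlenecking,
size-selection artefacts, insufficient depth — leaves a distinctive
signature in the aligned reads, a thorough post-alignment quality
assessment can be done before any peak calling. `atacdeck` implements
that assessment as a set of composable steps over a flat alignment
table read from BAM, each with an explicit contract and a synthetic
ground-truth generator to test it against.

# Data model and conventions

Alignments and fragments are plain data frames. All internal
coordinates are **0-based, half-open**; conversion to and from SAM's
1-based inclusive convention happens only at the Rsamtools boundary
(`read_alignments()` / `write_alignments()`). Secondary and
supplementary alignments are dropped (and counted) at read time, since
every downstream metric is defined on primary alignments. Fragments are
the union of the two mate intervals rather than TLEN arithmetic, which
keeps them consistent under soft-clipping; `|TLEN|` is kept as a
cross-check and as the filter quantity.

# Filtering and duplication metrics

`filter_alignments()` applies the standard five criteria in a fixed
order — (1) mitochondrial reference, (2) duplicate flag, (3)
MAPQ ≤ 20, (4) not a proper pair, (5) `|TLEN|` outside 38–2000 bp — and
attributes each removed read to the *first* criterion it matches, so
the removal report is deterministic and sums exactly to the input.
Boundary semantics matter and are pinned by tests: `|TLEN|` = 38 and
2000 are retained, MAPQ = 21 is retained.

Duplicate marking is position-based (Picard-like): records sharing
(reference, strand, strand-adjusted 5′ position, `|TLEN|`) form a
group; the highest-MAPQ record (ties: smallest query name) stays
unflagged. Sequence-based duplicate detection and optical tile
coordinates are out of scope. From the multiplicity histogram of
positions the library metrics follow in closed form: NRF = distinct /
total, PBC1 = M₁ / distinct, PBC2 = M₁ / M₂. When no position is seen
twice PBC2 is undefined; it is `NA` in the data model and rendered as
`inf` in TSV output.

# Cut-site shifting and nucleosome-class binning

Tn5 inserts adaptor pairs 9 bp apart, so insertion points are
recovered by offsetting 5′ ends +4 bp on the plus strand and −5 bp on
the minus strand. `shift_reads()` translates whole records (read
length and strand unchanged); the cut site is then the shifted 5′
position. Records pushed below coordinate 0 are dropped and counted,
and shifting with negated offsets restores the original coordinates
exactly. Whether 3′ ends should be treated separately is
underdetermined; we deliberately shift the whole record and define only
the 5′-derived cut site as meaningful.

The eight size bins (38–100, 100–180, 180–247, 247–315, 315–473,
473–558, 558–615, 615–2000 bp) are half-open `[lower, upper)` with the
last bin closed at 2000. The published boundaries touch (100 ends the
nucleosome-free bin and begins intermediate 1), so a convention is
required: boundary values go to the **higher** bin. Under this rule the
bins partition the integers 38–2000 exactly, which a test asserts for
every value. Di- and tri-nucleosome fragments are split in silico into
2 and 3 contiguous sub-fragments tiling the parent interval — the first
k−1 parts get `floor(size/k)` bp, the remainder goes to the rightmost
part (any fixed rule works; this one is ours). Fragments in
intermediate bins and the "others" bin are excluded from TSS plots by
default, matching standard practice, and can be kept with
`include_intermediate = TRUE`.

# TSS signal matrices

`tss_signal_matrix()` counts point events in bins of relative position
around stranded anchors; minus-strand anchors flip the axis so
positive positions are always downstream in gene orientation. The
default window (±1000 bp) and bin (10 bp) are conventional choices —
wide enough to show ±1–2 phased nucleosomes, fine enough to localise
them — and are configurable. Events default to fragment midpoints
(symmetric for both mates; cut sites and per-base coverage are
alternatives via `representation`). The default normalisation is
counts-per-million events per matrix so nucleosome-free and
nucleosome-bound heatmaps share a scale; `raw_counts` preserves the
exact conservation property (matrix total = events in any window) that
the tests verify against a brute-force double loop.

One numerical subtlety: with half-open integer bins, mirroring an
anchor's strand reverses its row exactly only for events off the bin
boundaries (an event at relative position 0 has no mirror-image bin).
The property test therefore excludes boundary positions; the central
bin, however, is symmetric by construction — a cut exactly at the TSS
lands centrally for either strand.

# Footprinting

PFMs (JASPAR text or bare 4-row counts) are converted to log-odds
weights with a pseudocount of 0.25 per cell and a uniform background:
`w[b,i] = log2(((c[b,i]+0.25)/(colsum+1))/0.25)`. Scores are scaled to
`relative_score = (s − min)/(max − min)`, and `scan_genome()` reports
all windows on both strands reaching the threshold (default 0.95;
reported in output metadata since published footprint figures rarely
state it). Opposite-strand hits at the same locus are deduplicated
keeping the higher score, ties to the plus strand. `N` bases score 0
(background). The scanner is validated against brute-force scoring of
every window and cross-checked against `Biostrings::matchPWM`.

`footprint_profile()` aggregates cut sites over sites ± 100 bp of
flank, flipping minus-strand sites, and divides by the number of sites
to give an average cut rate per position. Input is restricted by
default to cut sites from fragments shorter than 100 bp — the
nucleosome-free fragments that carry footprint information — and this
gate is overridable. Tn5 sequence bias is *not* corrected; valleys at
strongly biased motifs should be interpreted with care.

# Library complexity

The duplication frequency-of-frequencies histogram `n_j` (distinct
fragments seen exactly j times) determines the expected distinct count
under thinning exactly: for effort t ≤ 1,
`E[D(t)] = Σ_j n_j (1 − (1−t)^j)`, which the tests check against
empirical subsampling. For t > 1 the default estimator adds the
Good–Toulmin alternating series in the extra effort s = t − 1,
`Σ_j (−1)^{j+1} n_j s^j`, stabilised by Euler's series transformation
(the raw series diverges for s > 1; the transform re-expands in
y = s/(1+s) < 1). A zero-truncated negative-binomial MLE
(`method = "ztnb"`, fitted with `optim`) offers a parametric
alternative. Correctness is defined by recovery of the closed-form
Poisson expectation `L(1 − e^{−λt})` on simulated libraries (within
10% at t = 4 in the tests), not by numeric identity with any particular
published implementation; curves are forced non-decreasing, and
bootstrap confidence bands are intentionally out of scope. Larger true
libraries at equal depth yield uniformly higher curves, which is the
qualitative signature used to rank biological replicates for further
sequencing.

Subsampling is pair-coherent and platform-stable: a template survives
iff `xxhash32(paste(qname, seed)) / 2^32 < fraction`, so both mates
always travel together and results are reproducible for a given
(fraction, seed).

# Peak calling and saturation

The internal peak caller is deliberately minimal: fragment midpoints
are counted in sliding windows (200 bp, step 50), each window is
tested against the genome-wide Poisson rate λ = N·window/genome_size,
p-values are Benjamini–Hochberg adjusted across windows, and
significant (q ≤ 0.05) overlapping/adjacent windows are merged. It has
no local background model, no shifting model and no broad-peak logic —
it exists to make saturation analysis self-contained, and an adapter
(`read_peaks_bed()`) accepts externally produced peak files whenever a
full caller is available. Null simulations bound its realised
significant-window fraction at ≤ 1.5× nominal FDR in the tests.

`saturation_curve()` subsamples to a fraction grid (default
0.1…1.0), calls peaks per subsample, and tabulates peak count and
total width versus effective fragments, with `loess.smooth` overlays
(span 0.5). The fraction-1.0 row is exactly the full-data call.

# The synthetic-data generator

`simulate_genome()`/`simulate_library()` generate the fixtures all
tests run on: i.i.d. genomes at a chosen GC, planted motif consensus
instances, stranded TSSs, and paired-end libraries drawn class-first
(nucleosome-free / mono / di / tri / background), then size
(truncated normal per class: NF 60±15, mono 200±15, di 390±25,
tri 580±20 bp; background uniform 38–1000), then location. Default
class weights (0.45/0.25/0.12/0.08/0.10) put roughly half the mass
below 100 bp, matching what a successful library shows; TSS-proximal
placement (probability 0.8, within ±200 bp) models promoter
enrichment; mitochondrial contamination (default 0.1) goes to a
dedicated small reference; PCR duplicates are coordinate-identical
extra pairs named `*.dup1` and recorded in the truth table, never
pre-flagged in the BAM. Footprint protection thins fragments whose
*shift-corrected* insertion points (start+4 / end−6) fall in a planted
motif core, surviving with probability `protection` per hit, so the
downstream profile sees a core/flank cut-rate ratio close to the
protection factor (the whole-fragment thinning couples the two ends
and biases the ratio upward by a few percent at NF fragment sizes).

What the generator does **not** model — Tn5 sequence bias, base
qualities, indels/soft-clipping, chromatin-state heterogeneity,
optical duplicates — bounds what green tests mean: they certify the
arithmetic and the statistical machinery, not robustness to every
artefact of real sequencing.

# Problem sizes and numerical choices

Test and acceptance runs use libraries of 3,000–50,000 fragments on
0.1–5 Mb genomes, 10–150 TSSs and 100–500 motif sites — sizes at which
every stochastic check has comfortable statistical margin while the
whole suite completes in well under a minute. Degenerate inputs follow
fixed rules: empty streams yield empty-but-valid outputs (header-only
BAM, all-zero profiles, no peaks); a single-multiplicity histogram
warns that extrapolation is weakly determined; PBC2 with M₂ = 0 is
`NA`/`inf`; anchors without strand are treated as plus with a warning.
All tie-breaks (duplicate representative, site-strand dedup, NF
ordering) are deterministic and documented at the function they affect.

# Limitations

Single-end and long-read data are unsupported; CRAM is unsupported;
per-base CIGAR events beyond the aligned span are ignored. The
complexity extrapolator is a point estimator. The internal peak caller
is not a substitute for a full-featured caller on real data. Footprint
depth is depth-dependent, so footprints should only be compared across
libraries of similar effective depth.
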