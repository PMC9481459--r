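---
title: "Methods: multi-target guide discovery and cut-site-resolved analysis"
author: "multicut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-target guide discovery and cut-site-resolved analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicut)
```

# The problem

A multi-target guide RNA (mgRNA) is a 20-nt guide derived from a repeat-element
consensus (for example a ~280-bp SINE) so that one guide directs Cas9 to a
predetermined number of near-identical, well-mapped endogenous sites. With a
single transfection such a guide turns the genome into a panel of hundreds of
cut sites spanning diverse chromatin states, and short-read sequencing
(ChIP-seq of Cas9 or repair factors, ATAC-seq, amplicon sequencing) reads out
binding, cleavage, repair and accessibility at every site simultaneously.

`multicut` implements the computational machinery of that platform: guide
enumeration and on-target search, mappability scoring of the resulting site
panels, cut-site-resolved fragment classification, peak attribution, amplicon
outcome calling, and feature-based regression — all exercisable end-to-end on
synthetic genomes with known ground truth.

# Coordinate model

All genomic coordinates are 0-based, half-open; 1-based interchange formats
(SAM) are converted at the I/O boundary. SpCas9 cleaves bluntly between the
3rd and 4th protospacer nucleotides counting from the PAM. We encode the cut
as the integer `c` with the cleavage bond between genomic bases `c - 1` and
`c`:

* `+` strand site starting at `s` (PAM at `[s+20, s+23)`): `c = s + 17`.
* `-` strand site starting at `s` (PAM at `[s-3, s)` on the forward strand):
  `c = s + 3`.

The "+4" nucleotide — the fourth base from the PAM, which distinguishes blunt
from staggered (5'-overhang, later filled in) cleavage products — then sits at
`c - 1` for `+` sites and at `c` for `-` sites, always on the PAM-distal side
of the bond. Minus-strand sites are analysed by reflecting fragment intervals
about the bond (`f0' = 2c - f1`, `f1' = 2c - f0`), which maps them exactly
onto `+` geometry; every cut-site statistic is therefore strand-mirror
invariant by construction, and the test suite asserts this.

# Guide enumeration and on-target search

`enumerate_candidates()` slides a 20-nt window over the template and its
reverse complement and emits each substring plus every variant with up to 3
substitutions confined to the 9 most PAM-proximal positions (the seed region,
where mismatches most strongly modulate activity). Candidates are filtered to
GC fraction in the inclusive band [0.40, 0.70] and deduplicated. For one
20-nt substring and one strand the variant count is exactly
`1 + 27 + 324 + 2268 = 2620` (`sum over k of C(9,k) * 3^k`), which the tests
verify by independent exhaustive expansion.

`find_on_targets()` declares an on-target site to be an exact 20-mer match
followed by an NGG PAM on the matching strand (`N` anywhere in protospacer or
PAM disqualifies the locus). Exact matching is the reproducible default: the
original site panels were produced by an external aligner in multi-hit mode
whose mismatch tolerance is version-dependent, so determinism is preferred
and mismatch-tolerant search remains available through
`genome_search_mismatches`. Sites are ordered by (chromosome, cut) and
truncated at a cap of 1,000 per guide — the cap used to keep full-genome
panels computationally bounded; which 1,000 survive the cap is not specified
by the source protocol, so the deterministic genomic order is this package's
choice.

Gene/chromatin annotation (`annotate_sites()`) takes a consensus across
chromatin-state tracks from several cell lines. Plurality voting needs a tie
rule that the word "consensus" does not supply; we break ties by a fixed
priority list, by default labels ordered by increasing genome-wide footprint,
so rarer (more informative) states win. The order is user-overridable.

# Read simulation and mappability

Repeat-derived sites risk being unmappable with short reads.
`simulate_fragments()` emulates the published simulation: 100 paired-end
fragments per site, lengths uniform on 200-600 bp, each fragment spanning the
cut, residing PAM-distal, or residing PAM-proximal with equal probability;
one-sided fragments put their cut-facing edge at an exponentially distributed
distance from the cut. The exponential's mean is not stated in the source
protocol; we default to 150 bp — the scale of ChIP fragment sizes — and expose
it in `sim_config()`.

`naive_align()` is an exhaustive, end-to-end, substitution-only paired-end
aligner: concordant orientations, ordered mates, implied fragment length at
most 1,000 bp. Because it enumerates every candidate position, it serves as
ground truth ("oracle") for mappability: a read pair is *ambiguous* unless
its best-scoring alignment is uniquely best **and** coincides with the pair's
recorded origin (`ambiguity_proportion()`). It is deliberately not a
general-purpose aligner — no indels, no quality scores, no index — and an
external aligner can be substituted through the SAM-ingestion adapter
(`read_fragments_sam()`). Tests assert the field-expected orderings: 2x75
ambiguity never exceeds 2x36, and paired-end never exceeds single-end, on
both unique and duplicated-block fixtures; on a duplicated-block genome the
ambiguity equals the interval-arithmetic fraction of pairs wholly inside the
repeat.

# Cut-site-resolved fragment classification

For a paired-end fragment `[f0, f1)` near a cut `c` (+ geometry):

* **span** — the fragment strictly covers both bases flanking the bond
  (`f0 < c - 1` and `f1 > c`): an intact (uncleaved or re-ligated) molecule.
* **abut** — the fragment lies on one side with its cut-facing edge within 5
  bp (inclusive) of the cut: a cleaved molecule bound on one side. "Proximal"
  always denotes the PAM-containing side.
* **species** — exact edge positions resolve the ±4-nt species that separate
  blunt from staggered cleavage after end repair: `dist+4` (`f1 = c`),
  `dist-4` (`f1 = c - 1`), `prox+4` (`f0 = c - 1`, the filled-in overhang),
  `prox-4` (`f0 = c`). These are 1-bp distinctions, so the edges are exact by
  default.

The span rule must exclude `f0 = c - 1` — otherwise a `prox+4` fragment
(which carries a duplicated +4 base across the bond) would be called
spanning; this is why spanning requires a base strictly left of `c - 1`.
Degenerate 1-bp fragments at the bond are classified on the proximal branch.
An exhaustive edge sweep against a hand-derived truth table (both strands) is
part of both the test suite and the acceptance script.

Enrichment is reported as RPM — fragments per million mapped in the parent
library, the genome-wide denominator — in assay-specific windows (200 kb for
53BP1/γH2AX, 2.5 kb MRE11, 1.5 kb Cas9), as base-pair pileups of whole
fragments including the unsequenced middle (`bp_pileup()`), or as sliding
windows (`sliding_window_profile()`, presets 4 bp/1 bp/1.5 kb for fine ATAC,
1 kb/1 kb/50 kb wide ATAC, 10 kb/10 kb/2 Mb for damage marks). Background
subtraction is position-wise and retains negative values: clipping would bias
averaged profiles upward. FWHM is measured between the outermost linearly
interpolated half-maximum crossings around the global peak; discretized
triangle and Gaussian profiles reproduce their closed forms to well under
2 bp.

`fragment_length_analysis()` histograms fragment lengths within 1.5 kb of the
cut sites (10-bp bins over 50-600 bp), forms the treated-minus-control
excess, and fits `A * exp(-L / lambda)` by unweighted least squares
(`minpack.lm::nlsLM`, log-linear initialisation). The fit details (range,
bins, weighting) are this package's choices; the source protocol names only
the exponential-decay model. A fit is refused, not forced, when the excess is
non-positive everywhere. Parameter recovery on simulated data: a planted
`lambda = 120` bp excess of 5,000 fragments over a flat control is recovered
within 10%.

# Peak attribution and mismatch architecture

Peaks called externally (e.g. MACS2, consumed as BED-like tables) with fold
enrichment >= 4 are attributed to the protospacer that best explains them:
scan both strands of a 400-bp window around the summit for NGG-adjacent
20-mers and take the fewest-mismatch one. The source algorithm assumes a
unique correct site per window; when reality disagrees we break ties by
distance to the summit, then leftmost coordinate — a deterministic chain of
this package's choosing. Mismatch sets are labelled by zone:
`(dist)`/`(prox)`/`(mix)` with a zero-padded count, the PAM-distal zone being
positions >= 12 from the PAM.

# Amplicon editing outcomes

Reads are demultiplexed by aligning their first 50 bp and assigning to the
target whose expected locus lies within 1,000 bp. A read is *edited* when the
intact 20-nt theoretical protospacer is absent (either orientation accepted;
reads shorter than 20 nt are indeterminate and excluded from rates).
Classification anchors on two 20-bp key sequences taken 20 bp upstream and
downstream of the cut: a shorter-than-expected between-key distance is a
deletion of that size, longer is an insertion, equal with a mutated
protospacer is an SNV. Subclasses follow the standard five categories
(deletions <= 5 bp, > 5 bp, 1-bp insertions, longer insertions, SNV). Reads
in which a key is missing or duplicated are *unclassified* rather than
fuzzily matched — a deletion that destroys a key is unclassifiable by
construction and is reported in the QC tally.

Deletion side attribution reconstructs the deleted reference interval by
left-aligned comparison of the between-key segment and counts deleted bases
on the PAM-proximal versus PAM-distal side of the cut; exact ties are
"balanced". Left alignment is a convention: with microhomology at the
deletion junction the physical deletion is ambiguous, and any consistent
convention (we use the leftmost placement) resolves it deterministically.

Outcome diversity is summarized as Shannon entropy `H = -sum(p log2 p)` per
target with a running cumulative sum across targets — the quantity relevant
to using editing outcomes as lineage barcodes. The outcome alphabet is the
set of distinct (class, size, side) tuples; the source figure does not define
its alphabet, so this is documented as the package's definition.

# Epigenetic features and the regression protocol

Per-site marker enrichment uses preset radii (50 kb for RNA-seq and histone
marks, 50 bp for DNase/ATAC, 10 bp for MNase). The feature matrix combines a
mismatch block — one binary indicator per protospacer position, counted from
the PAM — with one RPM column per marker. "One-hot encoding of mismatch
state" is ambiguous between per-position binary and per-position base
identity; binary is the default and an 80-column substituted-base expansion
is available behind `expand_bases = TRUE`.

`fit_eval()` follows the published protocol: a seeded random 70/30
train/test split, hyperparameters chosen by 5-fold cross-validation on the
training 70%, evaluation by Pearson r and RMSE on the held-out 30%. The
regressor is a pluggable ensemble-of-trees interface with a random forest
(`ranger`) default; the source names the regressor family but no settings, so
the small fixed grid (300 trees; mtry at p/3 and sqrt(p); minimum node size
5) is documented here as this package's choice. On synthetic data a noiseless
linear target is recovered with test r >= 0.99, pure noise stays below |r| <
0.2, and combining feature families never loses more than 0.05 r against the
best single family when the target genuinely depends on both.

# What the synthetic generators emulate — and what they do not

`make_genome()` plants protospacer+PAM copies (optionally with seed-region
mismatches, both strands, >= 2 kb apart so per-site windows never overlap) in
an i.i.d. uniform-base background, with optional exact duplicated blocks for
ambiguity tests. `make_cutsite_fragments()` places fragment edges so the
span/abut/species truth is known by construction;
`make_amplicon_reads()` applies deletions, insertions and SNVs at the cut
with attached truth. Every generator is a deterministic function of (seed,
parameters).

Real data differ in ways the generators deliberately do not model: genomic
base composition is not i.i.d. (repeats beyond the planted ones, GC
heterogeneity — a `gc_skew` stress knob is provided), sequencing errors and
quality scores are absent, ChIP pulldown efficiency and duplicate structure
are not modelled, and fragment-length distributions of real libraries are not
uniform. Passing tests therefore demonstrate the correctness of the
*rules and estimators* under controlled truth, not the biological effect
sizes of any particular dataset; headline biological numbers from real
genomes (e.g. the size of a full hg38 candidate set) require those external
inputs.

# Problem sizes and numerical choices

The test and acceptance workloads use desk-scale fixtures chosen to keep the
whole suite in a few minutes while leaving no rule untested: 1-Mb genomes
with 50 planted sites for recovery, 1,000 simulated read pairs per
mappability condition, 10,000 fragments for mixture recovery, 5,000 excess
fragments for decay fitting, and n = 1,000 rows for the regression nulls.
Other numerical choices collected here: GC bounds inclusive; abut tolerance
5 bp inclusive; species edges exact (0 tolerance); concordance window
1,000 bp; negative background-subtracted values retained; exponential fit on
[50, 600] bp with 10-bp bins; ties in peak attribution broken by distance
then coordinate; `0 log 0 := 0` in entropy.

# Known limitations

* The naive aligner scales linearly in genome size and is meant for
  fixtures and windows, not whole mammalian genomes.
* Exact-match site discovery understates the site panel of guides whose
  genomic copies carry mismatches outside the enumerated template variants.
* Amplicon classification is key-anchored string arithmetic, not CIGAR-level
  realignment; complex (multi-part) edits and edits destroying a key are
  reported as unclassified rather than resolved.
* No UMI handling, duplicate marking, or spike-in normalization; these are
  assumed upstream.

# A worked end-to-end example

```{r example}
guide <- "ACGTTGCAGGTCAATCCGGA"
fx <- make_genome(n_chrom = 1, chrom_len = 60000,
                  planted = list(list(guide = guide, copies = 4)), seed = 3)
sites <- find_on_targets(guide, fx$genome)
nrow(sites)

frags <- make_cutsite_fragments(sites, c(span = 0.5, prox_m4 = 0.3,
                                         dist_p4 = 0.2),
                                n = 2000, seed = 11)
count_span_abut(frags[frags$site == 1, ], sites[1, ],
                library_size = attr(frags, "library_size"))[
  c("span_rpm", "prox_rpm", "dist_rpm")]

tg <- amplicon_targets(sites, fx$genome)
reads <- make_amplicon_reads(tg, fx$genome,
                             c(unedited = 0.7, del = 0.2, ins = 0.05,
                               snv = 0.05), n_reads = 400, seed = 5)
sub <- reads[reads$target == 1, ]
s <- summarize_target_outcomes(sub$mate1, tg[1, ], fx$genome)
s$mutation_rate
table(s$calls$subclass)
```
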