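---
title: "Dissecting mitochondrial control-region architecture with mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mitochondrial control-region architecture with mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

## The problem

Vertebrate mitogenomes share a canonical 37-locus circular arrangement and a
single large non-coding region — the control region or D-loop — between
tRNA-Pro and tRNA-Phe. The control region harbours short functional
elements: termination-associated sites (TAS) near its 5′ end and the
conserved sequence blocks CSB I–III towards its 3′ end, involved in
replication and transcription control. Deviations from the canonical plan
(control-region expansion by tandem repeats, extra non-coding inserts formed
by partial duplication, tRNA block rearrangements) are rare and biologically
informative, but detecting and describing them typically involves ad hoc
manual work. `mitoarch` turns that workflow into tested, seeded code:
coordinates, scans, repeat maps, gene-order comparisons, size statistics and
supermatrix construction.

## Coordinates on a circle

All spans are 0-based half-open. On a circle of length $L$ a span is stored
as `(start, end)` with `start` in $[0, L)$ and `end = start + length`
*not* reduced mod $L$; a span wraps the origin iff `end > L`. All sequence
extraction funnels through one helper (`extract_span()`), so the wrapping
convention lives in exactly one place. GenBank's 1-based inclusive
coordinates are converted only at the file boundary, and BED-style output
tables split wrapping features into two rows sharing a group label.
`region_between(g, a, b)` walks forward around the circle from the 3′ end of
`a` to the 5′ start of `b`; the result may wrap and may have length zero.

## Degenerate motif scanning

A motif is an ordered list of IUPAC literals and bounded spacers, with
optional alternatives (the CSB I query is "`AT` *or* `ATG`, then a spacer,
then `GACA`"). Scanning expands the motif into every concrete
(alternative, spacer-length) template and reports **every** distinct
(start, spacer, alternative, strand) match — overlapping hits are all kept,
because TAS sites embedded in tandem repeats genuinely overlap, and greedy
masking would hide them.

Fixed queries:

| element | query | defaults |
|---|---|---|
| TAS | `ATG N(8–9) CAT` | — |
| CSB I | `AT`\|`ATG` + spacer + `GACA` | spacer 10–40 bp canonical; relaxed cap 80 bp, optionally `GANA` |
| CSB II | `AAACCCCCC NNN CCC` | — |
| CSB III | `AAACCCC` | flank A/C fraction ≥ 0.8 over 20 bp per side, pooled |

Decisions worth stating:

* **"In some distance"** for CSB I has no published bound; 10–40 bp
  canonical and an 80 bp relaxed cap bracket typical vertebrate CSB
  spacing and are exposed as parameters. Relaxed-mode hits are labelled
  `mode = "relaxed"` so they are never silently mixed with canonical ones.
* **"Relieved identity constraints on the third base"** is implemented as
  freeing position 3 of the `GACA` core to `N` — the only third base the
  relaxation can refer to in that query.
* **"An otherwise A/C-homopolymer rich region"** (CSB III) is quantified as
  the pooled A/C fraction of both 20 bp flanks with threshold 0.8, clipped
  at region edges; the score is attached to every hit so the threshold can
  be revisited without rescanning.
* **Ambiguity:** genome `N` matches nothing except pattern `N`.
  Gap-filled GenBank records therefore cannot produce phantom hits.
* A structural quirk the test suite documents: the TAS query is its own
  reverse complement (revcomp(`CAT`) = `ATG`), so every TAS site is found
  on both strands by a both-strand scan. Strand asymmetry is meaningful
  for CSB I/III, not for TAS.

`conservation_profile()` supports the usual pre-localization step: per
aligned column, the fraction of sequences carrying the modal (non-gap)
residue, gaps counting as mismatches, plus a sliding-window mean.

## Repeat discovery

**Dispersed repeats** follow a deterministic seed-and-chain version of the
manual "consecutive 10-nt blocks as query" procedure: the query region is
tiled into non-overlapping `block_bp = 10` blocks; each block is matched
(≤ `max_mismatch = 1`) against every target region on both strands; hits
whose query/target offsets agree within `chain_gap = 1` block are chained
(bridging up to `max_gap_blocks = 5` missing blocks); chains with at least
`min_blocks` blocks become matching segments; segment end-points that
overlap ≥ 50% in the same region are merged, and linked occurrences form a
family. `min_blocks` defaults to 3 (~30 bp): with ≤1 mismatch per 10-mer,
pairs of diagonal-consistent chance hits occur at an appreciable rate in
kilobase-scale random sequence, while three consistent blocks are
vanishingly unlikely by chance. Member strands are propagated from a
reference member through the segment links (a minus-strand segment flips
orientation), so a copy planted on the light strand is reported with
strand −1 regardless of which member anchors the family.

**Consensus** is gapless majority vote over left-aligned members
(minus-strand members reverse-complemented at extraction), ties broken by
the fixed order A<C<G<T and recorded in a `ties` attribute. Members whose
lengths differ by more than 2× are refused with a suggestion to split the
family — the v1 model is substitution-only, and such families are usually
two families.

**Tandem arrays** are found by a transparent period scan: for each period
$p$ the sequence is compared against itself shifted by $p$, and maximal
runs where the rolling $p$-window identity stays ≥ 0.8 are reported with
fractional copy number. Overlapping candidates across periods are resolved
keeping the highest identity, minus a small penalty (`5e-4`/bp of period)
so the fundamental period beats its harmonics, whose observed identity is
statistically indistinguishable when copies diverge independently from a
master. The default `min_period = 20` is forced by the null model: at
$p = 10$ and threshold 0.8, the binomial tail $P(\mathrm{Bin}(10, 0.25)
\ge 8)$ times ~500 window positions already yields ~0.2 chance "arrays"
per 500 bp of random sequence, and a single above-threshold window formally
has 2.0 copies. Short-period hunts should lower `min_period` deliberately.

**Folding propensity** is maximum non-crossing base pairing
(Watson–Crick + GU, hairpin loops ≥ 3) by dynamic programming. This is a
deliberate, documented stand-in for minimum-free-energy folding: it answers
"can this consensus pair extensively with itself?" with an exactly testable
score (the suite checks it against exhaustive structure enumeration for all
sequences ≤ 15 nt). `FoldResult` carries `method = "max-pairing"` so the
pair count is never confused with a free energy in kcal/mol.

## Gene orders and breakpoints

`extract_order()` reads the signed circular order of canonical loci from an
annotation, linearized at tRNA-Phe (the conventional vertebrate start).
`compare_to_canonical()` counts signed circular breakpoints: an observed
adjacency $a \to b$ is conserved when the reference order contains
$a \to b$ or its joint reversal $-b \to -a$. Runs of breakpoints separated
by at most `cluster_gap = 2` conserved adjacencies are grouped; each group's
minimal window (the loci strictly between its outermost breakpoints) is
classified `swap/strand-flip` if the observed window equals the canonical
sub-order with exactly one contiguous segment reversed-and-strand-flipped,
else `shuffle`. The two rearrangements the package's simulator can plant
illustrate both outcomes: Gln(+)/Ile(−) in place of Ile(+)/Gln(−) is a
single signed reversal; Ser/Leu/His in place of His/Ser/Leu with unchanged
strands is not expressible as one reversal and classifies as a shuffle.
The comparator reports structure only — no event history, no minimal
reversal-distance solver — and the canonical vertebrate order ships as an
editable TSV, since users may want a different reference.

## Size statistics and the codon supermatrix

Species with several database entries are collapsed to their median length
(even counts: mean of the central two) before any distributional statement;
`percent_larger()` uses strict inequality and reports numerator and
denominator; grouped summaries use linear-interpolation quantiles (R type
7), a convention fixed here because plotting-tool defaults differ.
Partiality of records is an input flag, not inferred from headers.

`build_matrix()` concatenates per-gene codon alignments in sorted gene-name
order (so results are independent of map iteration order), excludes ND6 by
default (it evolves under different constraints from the other twelve
protein-coding genes), and removes a codon column *whole, in all taxa* as
soon as any taxon has a gap in any of its three positions. Per-base gap
removal would silently shift reading frames; whole-codon removal is the only
interpretation compatible with downstream frame checking.
`validate_frames()` translates every gene/taxon under the vertebrate
mitochondrial code (NCBI table 2, where `TGA` = Trp and `AGA`/`AGG` are
stops), reporting internal stops and tolerating a terminal one. Output
formats are FASTA, relaxed PHYLIP and a RAxML-style partition file; tree
inference itself is out of scope.

## The synthetic genome generator: what a green test establishes

`simulate_genome()` emits a circular genome with the canonical 37 loci at
representative vertebrate lengths (from the packaged order table), a control
region between tRNA-Pro and tRNA-Phe, and a truth record of every planted
span. Defaults state the world the tests assume: 16.5 kb genome, GC 0.45,
three TAS sites with random 8/9 bp spacers, CSB I with a 20 bp spacer,
CSB II with free `NNN`, CSB III inside pure-A/C 20 bp flanks, and a
period-40, 5-copy tandem array at 2% per-copy divergence. An optional insert
between tRNA-Phe and 12S duplicates the control region's 3′ tail plus a
tRNA-Phe copy: the duplicated segment receives a light 0.05 substitution
rate (a recent duplication, discoverable by exact 10-nt windows, which is
how such inserts are found in practice), while the tRNA-Phe copy is
"degenerate" at 0.15 — the published degree of similarity is not
quantified, so this is a one-time realism choice, not a tuning knob.
The insert extends the genome beyond `genome_length`; the extension is
reported as `slack` in the truth record.

What the generator does **not** emulate: codon structure or selection in
the coding placeholders, indels (truth spans stay exact under the
substitution-only model), heteroplasmy, within-array period drift, or
phylogenetic correlation between simulated genomes. A green
planted-truth test therefore establishes that the scanners and repeat
finders recover what was planted under i.i.d. background — it does not
certify performance on diverged real repeats with indels, and the repeat
module's gapless consensus is explicitly v1.

## Numerical and degenerate-input conventions

* Hit ordering is (start, strand +1 first, end, spacer); family labels are
  `RF_k` by decreasing total member span; architecture elements sort by
  (start, end, label). All outputs are deterministic for a fixed seed.
* Empty regions scan to empty hit tables; empty architecture inputs give
  an empty map; an empty size table is an error (a fraction of nothing is
  meaningless).
* `ac_fraction()` returns `NA` when no flank bases exist after clipping.
* Duplicate identical CDS/tRNA/rRNA spans are rejected at genome
  construction; duplicated canonical loci abort order extraction with the
  locus named.
* The CLI mirrors the library defaults, logs to stderr, writes a JSON run
  manifest (package version, parameters, input hashes) beside its outputs,
  and performs no network access. Config files are JSON.

## Known limitations

Breakpoint counting is not a rearrangement-distance; the classifier
recognises single signed reversals and calls everything else a shuffle.
The GenBank parser targets the flat-file subset that mitogenome records
use (single spans, `complement`, two-part origin-wrapping `join`), not the
full location grammar. Folding scores are pair counts, not energies.
Database-snapshot-dependent quantities (e.g. the fraction of species with
larger genomes at a given date) are reproduced as computations over
user-supplied tables, never as fixed numbers.
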