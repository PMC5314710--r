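# mitoarch

Vertebrate mitochondrial genomes are compact circles of ~16.5 kb carrying a
fixed complement of 37 loci (13 protein-coding genes, 2 rRNAs, 22 tRNAs) and
one substantial non-coding stretch, the control region (D-loop), between
tRNA-Pro and tRNA-Phe. Occasionally a lineage breaks the pattern: the
control region balloons with tandem repeats, extra non-coding sequence
appears elsewhere on the circle via partial duplication, or blocks of tRNAs
are rearranged. `mitoarch` is an R toolkit for dissecting exactly these
phenomena — aimed at researchers in mitogenomics and molecular evolution who
want a scripted, reproducible version of analyses that are usually done by
hand in a genome browser.

## What it computes

* **Control-region motif scanning.** Degenerate queries with bounded
  spacers over IUPAC alphabets: the termination-associated site
  TAS = `ATG N(8–9) CAT`; CSB I = `AT|ATG … GACA` (spacer 10–40 bp
  canonical, relaxable to 80 bp and/or a freed third core base);
  CSB II = `AAACCCCCC NNN CCC`; CSB III = `AAACCCC` inside an A/C-rich
  context (pooled 20 bp flank A/C fraction ≥ 0.8). Every distinct
  (start, spacer, alternative, strand) match is reported; overlaps are
  never masked. Genome `N` matches nothing but pattern `N`.
* **Repeat discovery.** Windowed dot plots (10/15 nt); dispersed repeat
  families by tiling a query region into consecutive 10-nt blocks,
  matching each block (≤1 mismatch) in all target regions on both strands,
  chaining offset-consistent hits and grouping linked occurrences;
  majority-vote consensus; tandem arrays by period scanning with
  adjacent-copy identity.
* **Folding propensity** of repeat consensi by maximum non-crossing base
  pairing (Watson–Crick + GU, hairpin loop ≥ 3) — a transparent dynamic
  programming stand-in for free-energy folding, tagged `max-pairing` so it
  is never mistaken for an energy.
* **Architecture maps**: the ordered, to-scale element list (TAS, CSBs,
  tandem arrays, repeat-family members, tRNAs) of a non-coding region.
* **Gene-order screening.** Signed circular gene orders from annotations;
  signed breakpoint counts against the canonical vertebrate order
  (an adjacency `a→b` is conserved if the reference contains `a→b` or
  `−b→−a`); minimal deviation windows classified as `swap/strand-flip`
  (single signed reversal) or `shuffle`.
* **Size statistics**: per-species median deduplication, strictly-larger
  percentile statements, grouped five-number summaries.
* **Codon supermatrices**: concatenation of per-gene codon alignments with
  ND6 excluded by default, whole-codon-column gap removal, and
  reading-frame validation under the vertebrate mitochondrial code.
* **A synthetic mitogenome generator** that plants all of the above
  (motifs, tandem arrays, a control-region-derived insert with a degenerate
  tRNA-Phe copy, named tRNA rearrangements) with an exact machine-readable
  truth record, so the entire pipeline is testable offline.

## Worked example

```r
library(mitoarch)

sim <- simulate_genome(sim_config(seed = 42, insert_spec = list(length = 400)))
cr  <- region_between(sim$genome, "Pro", "Phe")
cr
#> <mito_region> Pro-Phe [15975,16900) 925 bp on sim00000042

scan_tas(cr$seq)[, c("label", "start", "end", "strand", "spacer", "match")]
#>   label start end strand spacer           match
#> 1   TAS    25  40      1      9 ATGTCTCGCTGACAT
#> 2   TAS    52  67      1      9 ATGCGTTTCAGGCAT
#> 3   TAS    79  93      1      8  ATGAAATAGATCAT

scan_csb(cr$seq, "III")
#>     label start end strand   match spacer context_score      mode
#> 1 CSB-III   412 419      1 AAACCCC      0             1 canonical

find_tandem(cr$seq)
#>   start end period copies  identity
#> 1    95 313     40   5.45 0.9611511
#> 2   392 438     23   2.00 0.8260870

d <- compare_to_canonical(extract_order(simulate_genome(
  sim_config(seed = 42, rearrangement = "gln_ile_swap_round"))$genome))
d
#> <gene_order_diff> 2 breakpoint(s), 1 deviation window(s)
#>   window_loci      observed      expected   classification
#> 1     Gln,Ile Gln(+),Ile(-) Ile(+),Gln(-) swap/strand-flip
```

Reading the output: the simulated control region spans bases 15975–16900 of
the circle; the scanner recovers all three planted TAS sites (two with 9 bp
spacers, one with 8); the planted CSB III heptamer at region position 412
sits in a perfectly A/C-rich context (`context_score = 1`); the period-40
tandem array is found at 95–313 with ~96% adjacent-copy identity (the second
row is the CSB II/III neighbourhood, itself A/C-periodic); and the rearranged
genome shows the diagnostic Gln(+)/Ile(−) inversion — two breakpoints whose
minimal window is exactly one signed reversal of the canonical
Ile(+)/Gln(−) block.

A command-line wrapper covers the same stages
(`inst/scripts/mitoarch simulate|regions|scan-motifs|find-repeats|
find-tandem|fold|architecture|gene-order|size-stats|build-matrix`), writing
TSV/FASTA/GenBank outputs plus a JSON run manifest.

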