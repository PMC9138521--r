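---
title: "Annotating regulatory SNPs by allele-specific PWM scanning"
author: "rsnpdb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating regulatory SNPs by allele-specific PWM scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpdb)
```

## The problem

A transcription factor (TF) recognizes short, degenerate DNA words in the
promoter of a gene. A single-nucleotide polymorphism (SNP) inside such a
binding site can abolish it, create a new one, or shift its binding
affinity — making the SNP *regulatory* (an rSNP). `rsnpdb` annotates a SNP
catalog against a library of position weight matrices (PWMs): for every SNP
in a gene's promoter it scans the reference and the alternate allele of the
surrounding sequence and classifies each binding site as a **gain**,
**loss**, **score_change** or **no_change**.

This vignette documents the model, the tunable parameters, the numerical
conventions, and what the synthetic test fixtures do and do not show.

## Promoter model

Promoters are anchored at the transcription start site (TSS), taken from a
configurable GFF3 feature type (default `gene`: feature start on the plus
strand, feature end on the minus strand — one TSS per gene; per-transcript
promoters are out of scope). The *build* window spans 7,500 bp upstream to
2,500 bp downstream of the TSS in gene orientation, deliberately generous:
regulatory elements well outside the few-hundred-bp core promoter are
routinely bound by TFs. The *query* window, applied when retrieving or
summarizing results, defaults to −1,000/+100 bp, the region most users mean
by "promoter". Narrowing is a pure re-filter on stored TSS distances;
widening beyond the build window is refused because the stored results
would be incomplete.

Window bounds are inclusive on both ends. Distance to the TSS is signed in
gene orientation, with the TSS base itself at distance 0 counting toward
the downstream side — which is why the default query window's downstream
extent of +100 bp covers 101 bases but its upstream extent covers exactly
1,000. A SNP inside the promoters of several genes is linked to, and
annotated for, each gene independently; if those genes lie on opposite
strands the SNP obtains two independent result sets, one per strand.

All internal coordinates are 1-based and inclusive, the native convention
of the R/Bioconductor interval stack (IRanges) and of GFF3 and VCF
themselves; interval work is delegated to `GenomicRanges`.

## Search sequences

For each (SNP, gene-strand) context, 25 bp of flank on each side of the SNP
yields a 51-bp sequence with the variant at position 26; minus-strand
contexts use the reverse complement with complemented alleles (catalog
alleles are, per VCF/GVF convention, reported on the genome plus strand).
Contexts are deduplicated across genes sharing a strand: the scan depends
only on the sequence, and results are re-joined to every gene through the
SNP–gene links.

Three discard rules apply, in a fixed precedence so each discarded context
is counted exactly once: `too_short` (SNP nearer than 25 bp to a contig
edge), then `contains_N` (checked on the full 51-bp window, so a window
passing on one strand passes on both), then `ref_mismatch` (the genome base
differs from the catalog's reference allele — a real-data pathology of
catalog/assembly version skew; such SNPs are excluded rather than annotated
against a base that is not there). Emitted plus discarded contexts always
sum to attempted contexts.

## Scoring model

Scanning follows the MATCH family of PWM scorers. Counts are regularized
with a pseudocount $p$ (default 0.8 per base, configurable; the scores are
insensitive to moderate choices, and $p=0$ is allowed only when every
position has observations):

$$f_{ib} = \frac{c_{ib} + p}{\sum_b c_{ib} + 4p}, \qquad
I_i = \sum_b f_{ib}\,\ln(4 f_{ib}).$$

$I_i$ is 0 for an uninformative position and approaches $\ln 4$ for a fully
conserved one. A window $s$ of PWM width $w$ scores

$$\mathrm{MSS} = \frac{\mathrm{Current} - \mathrm{Min}}
{\mathrm{Max} - \mathrm{Min}}, \qquad
\mathrm{Current} = \sum_{i=1}^{w} I_i\, f_{i,s_i},$$

with Min and Max substituting per-position minimum and maximum frequencies.
The **matrix similarity score** runs over all positions; the **core
similarity score** over the 5 consecutive positions of maximal summed
information. Both lie in $[0,1]$: the consensus word scores exactly 1, the
anti-consensus exactly 0. Degenerate case: a matrix with Max = Min (all
positions uniform) is defined to score 1 everywhere, so the cutoffs decide.

Numerical conventions:

* the core window is the *computed* maximal 5-window, leftmost on ties
  (uniform matrices therefore core at position 1); a core annotated in the
  library (`core_start`) overrides the computation;
* both orientations of every sequence are scanned by default, as binding
  sites live on double-stranded DNA; reverse-orientation matches are
  reported at their footprint start in the scanned sequence's own
  coordinates, with the site string given in PWM orientation;
* a match requires *both* scores to reach their cutoffs (defaults
  0.75/0.85, used when the library carries none). Cutoffs are data, not
  algorithm: libraries distributed with per-matrix false-positive-minimizing
  cutoffs are honored via the `CO` line of the flat-file dialect.

## Consequence classification

Matches of the two alleles are paired by positional identity
`(pwm_id, offset, orientation)` — for a 1-bp substitution the only pairing
under which gain and loss are well defined. Only in alt → gain; only in
ref → loss; in both → score_change when the matrix scores differ *after
rounding to 3 decimals* (the precision at which similarity scores are
conventionally reported), else no_change. The rounding avoids calling
floating-point noise a change of binding affinity; a core-only difference
with equal rounded matrix score is no_change.

Records whose footprint does not cover position 26 are dropped: a window
not containing the SNP is the same string in both alleles, so only
no_change records can ever be removed by this restriction — a provable
invariant, checked in the test suite. An **rSNP** is a SNP with at least
one gain/loss/score_change; its affected-site count is over distinct
(PWM, offset, orientation, gene strand) combinations.

The persistent store excludes no_change rows by default (they carry no
regulatory signal and dominate the volume); `keep_no_change = TRUE`
retains them.

## The four-table store

`build_database()` writes `snp_info`, `gene_info`, `snp_region` and
`TFBS_results` into one SQLite file — exactly four tables, nothing else —
after verifying referential integrity (every link references an existing
SNP and gene; every result row joins to at least one link on its strand).
Exports are ordered by (chrom, pos, SNP, gene, PWM, offset) and numbers
printed at fixed precision, so identical inputs give byte-identical files.
The TSV export renders the site visualization textually: core positions
uppercase, and the SNP base bracketed (`aa[T]ATAAtt`), since color is not
available in a flat file.

Summary statistics are computed within the query window: promoter SNP and
rSNP counts, % rSNP, rSNPs per promoter averaged over *all* annotated genes
(a gene without promoter SNPs contributes 0 — species averages would
otherwise be inflated), mean affected TFBSs per rSNP, and a TSS-distance
histogram over the proximal promoter in 50-bp, left-closed right-open bins
on [−750, +250) — so a distance of −750 falls in the first bin and +250 is
outside.

## Synthetic fixtures and what they show

`generate_fixtures()` emits a complete input set (FASTA, GFF3, VCF,
PWM flat file) plus a ground-truth table. Background sequence is i.i.d.
nucleotides at a configurable GC content (default 0.4, a typical plant
genome-wide value). Planted effects use sharp width-6 matrices
(97/1/1/1 columns): with the default 0.85 matrix cutoff a single mismatch
scores $1 - 1/6 \approx 0.833$ and destroys the site, which makes loss and
gain constructions exact. Score-change plants use a mixed SNP column
(60/36/2/2), keeping both alleles above cutoff at distinct scores.
Consensus words are rejection-sampled to differ from each other and from
their own reverse complements in at least two positions, so a single-base
substitution can never convert one planted site into a perfect site of
another matrix. Every plant is verified at generation time by running the
package's own extraction/scan/classification on it, with bounded local
resampling of the flanks when chance background matches interfere;
generation fails loudly rather than emit a wrong truth table.

What passing fixture tests show: the windowing, extraction, scoring,
classification and bookkeeping machinery is exact under the stated model.
What they do not show: performance on real genomes, whose promoters have
repeats, composition structure and motif clustering that i.i.d. background
does not emulate, and whose PWM libraries are wider, softer and partially
redundant. The test suite exercises genomes of tens of kilobases, a few
genes and tens of SNPs per case (20 seeds for the recovery property),
sizes chosen to keep each property check exhaustive.

## Limitations

* Scores follow the published MATCH scoring scheme; numerical identity
  with the proprietary binary is not claimed (and its per-matrix cutoff
  profiles are proprietary inputs, not derivable here).
* One TSS per gene; isoform-specific promoters are not modeled.
* Single-nucleotide, biallelic variants only; indels, multiallelic sites
  and haplotype-combined effects are filtered out and counted.
* No p-value calibration of score changes and no binding-energy model:
  a score_change is a statement about PWM similarity, not measured
  affinity.
* The i.i.d. fixture background quantifies chance matches only under that
  background model; raising both cutoffs to 1.0 gives a configuration in
  which background false positives vanish entirely.
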