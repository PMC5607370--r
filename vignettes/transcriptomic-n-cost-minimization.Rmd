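---
title: "Transcriptomic nitrogen cost minimization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic nitrogen cost minimization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncostmin)
```

## The problem

Oligotrophic marine cyanobacteria such as *Prochlorococcus* live where
nitrogen is chronically scarce, and their genomes are already nitrogen
cost minimized: codon and amino-acid usage are biased toward residues with
fewer N atoms. `ncostmin` implements the analysis needed to ask whether
cells can *dynamically* extend this frugality during acute N starvation by
restructuring their transcriptome: initiating transcription at sites inside
annotated genes (internal TSSs), producing shortened sense transcripts
(intraRNAs) whose translated isoforms — starting at the nearest downstream
in-frame methionine — carry fewer nitrogen atoms than the full-length
proteins.

The pipeline has five analytical stages, each usable on its own:

1. **TSS detection** from 5'-end read coverage of a TSS-enriched library
   versus a non-enriched control (dRNA-seq style), via a Skellam test.
2. **Positional classification** of each TSS (primary, internal, antisense,
   downstream, orphan) against a gene annotation.
3. **Internal-transcription dynamics**: the internal:primary abundance
   ratio per gene, compared between N-replete and N-deplete conditions,
   with a conservation check across time points.
4. **Truncation accounting**: translation of full and truncated isoforms
   and whole-residue nitrogen budgets (mol N per mol protein).
5. **Motif statistics**: Gly–Gly codon-pair observed:expected ratios binned
   by anti-Shine–Dalgarno affinity (ribosome-pausing potential),
   pyrimidine-rich k-mer enrichment (S1-mediated translation initiation),
   and NtcA promoter-box scans upstream of translational starts.

A synthetic-data generator with planted ground truth makes each stage
testable without any external download.

## The detection model

Let $e$ and $c$ be the 5'-end counts at one position in the enriched and
(depth-scaled) control libraries, with background rates $\lambda_e$ and
$\lambda_c$. Under the null of no TSS, $e - c$ is distributed as
$\mathrm{Skellam}(\lambda_e, \lambda_c)$ — the difference of two
independent Poisson variables. A position is called when

* $e \ge$ the noise threshold (default 4),
* $P(D \ge e - c) <$ the significance threshold (default $10^{-10}$),
* after merging calls within the merge range (default 5 nt, keeping the
  highest-count position, ties to the smaller coordinate), the
  enriched-minus-control difference is at least the curation threshold
  (default 100), automating what was originally a manual browser curation.

The Skellam upper tail is evaluated by summing the Bessel-function form of
the mass function in log space with exponentially scaled `besselI`; at very
large order the scaled Bessel underflows to zero, which is the correct
limit of the term, so that underflow is accepted silently. The unit suite
checks the implementation against an independent two-Poisson convolution
oracle to below $10^{-9}$ absolute over rates up to 20 and counts up to 200.

Background rates are estimated per strand by a trimmed mean (positions at
or below the 95th percentile of nonzero counts), floored at 0.01, which
keeps TSS spikes out of the background. Published Skellam-based TSS
annotators do not state their exact background windowing; the trimmed mean
is this package's documented choice. Control counts are scaled by the ratio of total 5'-end
depths before the test and before the curation difference; `normalize =
FALSE` reproduces raw-count behaviour, and whether the curation difference
should be applied before or after scaling is genuinely open — the default
is after.

Classification windows follow a literal reading of the category
definitions: *primary* within 250 nt upstream of the gene's annotated 5'
end, inclusive of 250 and of distance 0; *internal* within the gene body;
*antisense* within an opposite-strand gene body; *downstream* strictly less
than 30 nt past the 3' end; *orphan* if and only if nothing else applies. A
call may hold several categories at once (a leaderless primary TSS, sitting
exactly on the start codon, is also internal by the window definitions);
the category census counts each call once under its full combination. When
the annotation provides no experimentally mapped TSSs, the translational
start anchors the primary window.

## Internal-transcription dynamics

The internal transcription ratio is the 5'-end read abundance at the
internal TSS divided by the abundance at the primary TSS, both summed over
a strand-aware downstream-inclusive window (default 5 nt, the merge-range
scale; the integration window for "read mapping at" a TSS is not defined
anywhere authoritative, so it is a parameter). Ratios are invariant to
library depth by construction.

Internal TSSs are kept when the ratio exceeds 10% of the primary TSS in at
least one condition. The cutoff is applied with a 5% *relative* boundary
tolerance (retain when ratio $\ge 0.10 \times 0.95$): an unbiased
count-based estimate of a ratio sitting exactly on the cutoff falls below
it with probability one half, so a literal strict reading would
arbitrarily halve the retention of boundary genes; the tolerance is a
counting-noise allowance, set from the Poisson coefficient of variation at
the operating counts, and `boundary_tol = 0` restores the literal rule.

Between conditions the package reports a three-way direction — *similar*
when the deplete:replete fold change lies within $[1/1.2, 1.2]$, otherwise
up in one condition — together with a **paired Wilcoxon signed-rank test**
on per-position normalized counts (each position in the ±window around the
internal TSS, divided by the condition's primary-window abundance, paired
by position across conditions). Pairing is essential: per-position means
vary over orders of magnitude along the saw-tooth pileup, and that
structure is shared by both conditions, so an unpaired rank-sum comparison
is swamped by it and has essentially no power. Two consequences are worth
stating plainly:

* With an 11-position window, the signed-rank statistic has at most
  $2^{-k}$ two-sided granularity for $k$ informative (non-tied) pairs —
  typically $k \approx 6$–11 here, a p-value floor of roughly $10^{-3}$ to
  0.06. Per-gene p-values far below that require many more sampling units
  (e.g. whole-transcript windows with replicates) than a single
  saw-tooth provides, so the direction call is ratio-based and the p-value
  is a supporting statistic, not the classifier.
* Being discrete, the test cannot be exactly uniform under the null; the
  suite verifies *validity* (rejection at no more than the nominal rate)
  rather than exact uniformity.

Genes with no primary TSS in either condition are routed to a direct
comparison: depth-normalized internal abundance in deplete over replete,
with an infinity sentinel when the replete abundance is zero. A 12 h TSS
counts as conserved at 24 h when a 24 h call exists on the same strand
within the merge range.

## Nitrogen accounting

Truncated isoforms begin at the nearest downstream in-frame methionine (at
or downstream of the TSS in the transcript direction); near-cognate
internal starts are deliberately not considered. Translation uses the
bacterial code with GTG/TTG initiators read as Met; the trailing stop is
retained in codon statistics but excluded from translation.

Nitrogen is counted per whole residue in peptide linkage: one backbone N
plus side-chain increments Arg +3, His +2, Lys/Asn/Gln/Trp +1. Whole-residue
budgets are the right currency for "mol N per mol protein" totals; a
side-chain-only switch is provided for the alternative accounting, along
with optional carbon accounting and RNA-level N accounting of the removed
5' segment (A=5, G=5, C=3, U=2 atoms per base). Aggregation reports the
total saving, the pooled percent ($100\sum \Delta N / \sum N_{full}$), the
mean of per-protein percents, and the range — pooled and mean-of-percents
are both given because an "average percent saving" can be stated either
way and the two differ when protein sizes differ.

## Motif statistics

Gly–Gly pairs are counted over in-frame adjacent codon pairs within genes
(never across gene boundaries) and compared with the independence
expectation $E[(a,b)] = P(a)P(b)N_{adj}$ from genome-wide codon
frequencies. Hexamer pairs built from GGA/GGG mimic the Shine–Dalgarno
sequence and pair strongly with the anti-SD at the 16S rRNA 3' end
(ribosome pausing); the default affinity table scores codons GGA = 2,
GGG = 1, GGT = GGC = 0, sums the two codons and splits the 0–4 range into
four bins. No published ΔG table for the 16 hexamers accompanies the
original analysis, so the table is configurable and all binned outputs can
be reproduced under any user-supplied scoring.

Pyrimidine-rich (and purine-rich) k-mers are counted as all length-k
windows with at least $\lceil 0.8k \rceil$ class bases; overlapping windows
all count, with an optional collapse to maximal runs since a printed motif
tally could be either convention. The expectation is a binomial
composition null, $N_{windows} \cdot P(X \ge \lceil 0.8k \rceil)$ with the
class fraction fitted on the same region set (a genome-wide option
exists). Enrichment is tested with Fisher's exact test on a 2×2 table of
observed versus rounded expected counts — the exact test needs integers,
and the rounding construction is this package's documented reading of
"normalized counts".

NtcA boxes are scanned with an IUPAC pattern (default GTA-N8-TAC, the
canonical cyanobacterial NtcA box) over the coding-strand upstream window;
a site counts when its 5' base lies strictly less than 100 bp upstream of
the translational start.

## What the generator emulates — and what it does not

`simulate_genome()` + `plant_tss()` + `simulate_coverage()` produce:

* coding genes drawn codon-by-codon from a configurable codon
  distribution (ATG start, single stop, alternating strands), intergenic
  spacers with a controlled pyrimidine fraction, planted NtcA boxes at
  recorded distances;
* an in-frame ATG planted at a per-gene fraction of the CDS drawn from
  0.10–0.35 by default, with the internal TSS placed on it — emulating the
  observation that internal transcripts begin near viable internal starts
  whose truncated isoforms lose roughly 10–40% of their residues;
* primary TSSs 20–60 nt upstream of gene starts (distance 0 for designated
  leaderless genes), internal:primary ratios per condition, an
  enriched:control contrast (default 10×), and 24 h conservation flags
  drawn at a configurable rate;
* per-position Poisson counts: background rate (default 0.5 per position)
  plus, at TSSs, the planted mean in the enriched library or mean divided
  by the enrichment factor in the control, with a geometric decay tail
  (factor 0.5 per nt over 5 nt) creating the saw-tooth 5'-end pileup.

Default study sizes follow the published study's structure where one
exists: an 85-gene set partitioned 64/13/8 into up-in-deplete /
up-in-replete / similar, ratio levels 0.2/0.4/0.8 around the 10% filter,
and 72/81 conservation. Where no value is stated (background noise rate,
enrichment factor, decay shape, primary offsets), defaults are set once to
values typical of bacterial dRNA-seq pileups and are not tuned.

The generator deliberately does **not** emulate: read-level artifacts
(mapping bias, soft-clipping — input is coverage, not reads), processed 5'
monophosphate ends surviving enrichment, overdispersed counts (Poisson by
default, matching the Skellam null so calibration tests are
interpretable), operon structure, overlapping genes, or the codon-usage
and GC biases of any real genome. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to every artifact of real libraries; on real data the
normalization switch, curation threshold and window sizes are the knobs to
revisit.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and bedGraph (0-based half-open) conversions happen only at I/O.
  Output TSVs report 0-based positions as produced by the internal model.
* Merge ties break toward the smaller coordinate; merging is chained
  (positions within range of a neighbour join the same cluster) and
  idempotent.
* All-zero coverage strands get the background floor (0.01) with a
  warning; zero primary abundance routes a gene to the direct-comparison
  path; a degenerate Fisher table (zero margin) reports p = 1 with a flag;
  genes with ambiguous bases are excluded from codon statistics.
* A gene's own primary call (leaderless: at the start codon, hence also
  classified internal) is excluded from its internal-TSS dynamics rows.
* Bins with zero expected count are dropped from pooled O/E with a
  warning; regions shorter than k contribute zero windows.

## Problem sizes

The shipped tests and the acceptance script run on synthetic studies of
50–85 genes (genomes of roughly 50–60 kb), mean 5'-end counts of
1000–2000 at planted TSSs, and 100-replicate Monte-Carlo calibrations —
sizes chosen so the whole suite completes in a few minutes on a single
core while every statistical check retains the power it needs. All
stages scale linearly in genome length and library count and run
comfortably at the ~1.7 Mb scale of a real cyanobacterial genome.

## Known limitations

* The Wilcoxon sampling unit (positions within one window) is a modelling
  choice; with replicate libraries, replicate-level ratios are the better
  unit and the positional default should be treated as a fallback.
* The anti-SD affinity table is ordinal, not thermodynamic; no RNA-duplex
  energy model is computed.
* The NtcA default pattern is the canonical box, not a position-weight
  matrix; degenerate-pattern hits carry no score.
* No operon/UTR reconstruction and no antisense dynamics: antisense calls
  are censused only.
* Reproducing published genome-scale values requires the reference genome,
  annotation and deposited coverage, which are not redistributable inside
  this package; the pipeline accepts them as ordinary FASTA/GFF3/bedGraph
  inputs.
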