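# ncostmin

Transcriptomic nitrogen cost minimization from differential 5'-end coverage.

Oligotrophic cyanobacteria such as *Prochlorococcus* already minimize the
nitrogen content of their proteomes genomically, through codon and
amino-acid bias. `ncostmin` implements the analysis that asks whether cells
extend this frugality *dynamically* under acute N starvation: it detects
transcription start sites (TSSs) from dRNA-seq-style 5'-end coverage of
TSS-enriched versus non-enriched libraries, classifies them positionally,
quantifies internal transcription (intraRNAs initiated inside annotated
genes) between N-replete and N-deplete conditions, derives the truncated
protein isoforms those internal TSSs imply, and accounts the nitrogen atoms
they save. Genome-scale motif statistics round out the picture:
Gly–Gly codon-pair observed:expected ratios binned by anti-Shine–Dalgarno
affinity (ribosome-pausing potential), pyrimidine-rich k-mer enrichment
(S1-mediated translation initiation), and NtcA promoter-box scans.

It is written for microbial transcriptomics researchers with a genome
(FASTA), an annotation (GFF3), and per-strand 5'-end coverage (bedGraph)
per library.

## The core model

At each genomic position, let `e` and `c` be 5'-end counts in the enriched
and depth-scaled control libraries with background rates λₑ, λ꜀. Under the
no-TSS null, `e − c ~ Skellam(λₑ, λ꜀)`; positions are called TSSs when
`e ≥ 4`, `P(D ≥ e − c) < 1e-10`, calls within 5 nt are merged, and the
count difference is at least 100 (the automated analogue of manual
curation). Calls are classified as primary (≤250 nt upstream of a gene's
5' end), internal, antisense, downstream (<30 nt), or orphan; combinations
are allowed. The internal transcription ratio is the windowed 5'-end
abundance at an internal TSS over that at the primary TSS; internal TSSs
above 10% are compared between conditions (paired Wilcoxon signed-rank on
per-position normalized counts, plus a fold-change direction call).
Truncated isoforms start at the nearest downstream in-frame Met; nitrogen
is counted per whole residue (backbone 1 N; side chains: Arg +3, His +2,
Lys/Asn/Gln/Trp +1), giving mol N per mol protein for both isoforms and
the percent saving.

A synthetic-data generator (`simulate_genome()`, `plant_tss()`,
`simulate_coverage()`, `write_fixture()`) plants all of this with known
truth — saw-tooth pileups, enrichment contrast, condition-specific ratios,
NtcA boxes — so every stage is testable offline.

## Worked example

Simulate a 20-gene study in which internal transcription rises under
N-deprivation (planted ratios 0.2 replete → 0.8 deplete), call and
classify TSSs, compare conditions, and account the nitrogen savings:

```r
library(ncostmin)

sim <- simulate_genome(n_genes = 20, mean_gene_len = 150, ntca_sites = 4, seed = 42)
tss <- plant_tss(sim$genes, sim$genome, primary_mean = 2000,
                 ratio_replete = 0.2, ratio_deplete = 0.8, seed = 42)
dep <- simulate_coverage(sim$genome, transform(tss, mean_count = mean_deplete),
                         noise_rate = 0.5, seed = 1)
rep_ <- simulate_coverage(sim$genome, transform(tss, mean_count = mean_replete),
                          noise_rate = 0.5, seed = 2)

calls <- classify_tss(call_tss(dep$enriched, dep$control), sim$genes)
category_census(calls)
#> Internal  Primary
#>       10       20

crep <- classify_tss(call_tss(rep_$enriched, rep_$control), sim$genes)
dyn <- internal_dynamics_table(calls, crep, dep$enriched, rep_$enriched)
direction_census(dyn)
#> up_in_deplete up_in_replete       similar
#>            10             0             0

head(dyn[, c("gene_id", "ratio_replete", "ratio_deplete", "direction")], 3)
#>   gene_id ratio_replete ratio_deplete     direction
#> 1 SIM0002         0.205         0.788 up_in_deplete
#> 2 SIM0004         0.205         0.826 up_in_deplete
#> 3 SIM0006         0.199         0.792 up_in_deplete
```

All 20 planted primary and 10 internal TSSs are recovered; every
internal-TSS gene shows the planted increase under deprivation. The
truncated isoform implied by the first internal TSS:

```r
g <- sim$genes[sim$genes$gene_id == dyn$gene_id[1], ]
truncation_saving(g, sim$genome, dyn$internal_tss_position[1])[
  , c("start_codon_offset_aa", "n_full", "n_trunc", "n_saving", "pct_saving")]
#>   start_codon_offset_aa n_full n_trunc n_saving pct_saving
#> 1                    22    224     197       27       12.1
```

Translation of the shortened transcript starts 22 residues in and saves 27
of 224 nitrogen atoms (12.1%). Motif statistics on the same genome:

```r
codons <- lapply(seq_len(nrow(sim$genes)),
                 function(i) coding_codons(sim$genes[i, ], sim$genome))
bin_by_affinity(codon_pair_stats(codons))
#>        bin observed expected o_e_ratio
#> 1      low        7     3.73      1.88
#> 2  mid_low        5     2.97      1.68
#> 3 mid_high        5     4.87      1.03
#> 4     high        3     2.93      1.02

ntca_scan(sim$genes, sim$genome)$n_genes
#> [1] 4   # the 4 planted NtcA boxes, all <100 bp upstream of a start
```

On a neutral random genome the Gly–Gly O/E ratios scatter around 1 (small
counts here; low-bin excess is sampling noise) — a genome under selection
for slow translation shows systematic excess in the high-affinity bins.

`run_pipeline(config)` chains all stages from a YAML config of file paths
and writes per-stage TSVs, a JSON summary and a manifest;
`inst/cli/ncostmin.R` is a thin command-line wrapper
(`simulate` / `run-all` / `validate`).

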