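# maccr — chromatin accessibility from MNase titration series

Digesting the same chromatin at several MNase concentrations and
sequencing the protected fragments probes accessibility quantitatively:
open loci release fragments at low enzyme and are over-digested at high
enzyme, protected loci behave oppositely. `maccr` turns a four-point
titration (1.5, 6.25, 25, 100 units by default) into a per-bin
accessibility score — the ordinary least-squares slope of library-normalized
read frequency against −log(concentration):

```
MACC_b = cov(x, y_b) / var(x),   x = −log c
```

Positive scores mark open chromatin, negative scores protected chromatin.
The package is aimed at regulatory-genomics analyses that compare
accessibility between RNAi conditions and across chromosomes (for example
X versus autosomes in dosage-compensation studies), and provides:

* **Scoring**: binning, hotspot (Z ≥ 7) filtering, counts-per-million
  normalization, slope fitting, lowess GC-bias correction, median-shift
  and X-read-doubling validations (`bin_genome`, `filter_hotspots`,
  `count_fragments`, `normalize_library`, `compute_macc`, `gc_correct`).
* **Differential accessibility**: per-bin moderated two-sample t with
  empirical-Bayes variance shrinkage, feature classification
  (gene body / TSS-TTS / enhancer / unannotated), genome-fraction
  normalized category counts, chromosome distribution summaries with
  Mann–Whitney tests (`test_bins`, `classify_regions`,
  `chromosome_distribution`).
* **Anchored profiles**: interpolated site profiles with 95% confidence
  bands, scaled metagenes, ranked heatmap matrices, score splits,
  per-concentration nucleosome read-frequency profiles (`site_profile`,
  `metagene_profile`, `heatmap_matrix`, `read_frequency_profile`).
* **Nascent transcription and qPCR**: observed-TSS definition from 5′-end
  signal, moderated differential Start-RNA abundance, per-chromosome
  regulation summaries, percent-input ChIP-qPCR enrichment and ΔCt math
  (`define_obstss`, `differential_start`, `regulation_summary`,
  `qpcr_enrichment`, `relative_abundance`).
* **A ground-truth generator**: synthetic genome, titration fragments,
  Start-seq counts and qPCR tables with known per-bin true slopes, so
  every stage is testable without external data (`sim_config`,
  `make_genome`, `simulate_titration`).

Inputs are plain-text standards: fragment BED or paired-end SAM/BAM,
chrom.sizes, FASTA, BED annotation; tracks are written as bedGraph, tables
as TSV. Coordinates are 0-based half-open throughout.

## Worked example

Simulate a small genome, score the control condition, and compare the
recovered accessibility with the generator's truth:

```r
library(maccr)

cfg <- sim_config(seed = 3,
                  chrom_sizes = c(chrX = 2e5, chr2L = 2e5, chr2R = 2e5),
                  n_genes = 60, n_enhancers = 40, depth = 1e5)
genome <- make_genome(cfg)
genome
#> synthetic genome: 3 chromosomes (600,000 bp), 60 genes, 24 peaks, 66 entry sites
#>   seed 3; entry-site groups: A=44 B=11 C=11

sim <- simulate_titration(genome, "control", replicate = 1)
tc  <- count_titration(sim$fragments, genome$bins)
track <- gc_correct(compute_macc(normalize_library(tc)))

round(cor(track$score, genome$truth$control), 3)
#> [1] 0.871
round(cor(track$score, genome$bins$gc), 3)
#> [1] -0.008
```

The corrected score recovers the true per-bin slope (r = 0.87 at this
shallow depth; > 0.95 at the default validation depth of 2×10⁶ fragments
per sample) and carries essentially no residual GC trend. The same objects
feed the rest of the pipeline: `test_bins()` for differential
accessibility between conditions, `site_profile()` for peak-anchored
average profiles, and `run_pipeline()` to execute the whole chain and
write bedGraph/TSV outputs deterministically for a given seed.

A thin command-line wrapper over the same functions is installed at
`inst/cli/macc.R` (`simulate`, `score`, `run` subcommands).

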