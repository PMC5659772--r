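---
title: "Scoring chromatin accessibility from MNase titration series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromatin accessibility from MNase titration series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maccr)
```

## The measurement and the statistic

Micrococcal nuclease (MNase) preferentially digests linker and open
chromatin. Digesting aliquots of the same chromatin at several enzyme
concentrations and sequencing the protected fragments yields richer
information than a single digestion: open loci release fragments readily
at *low* MNase and are over-digested (lost) at high MNase, while
well-protected loci require high enzyme to release nucleosome-sized
fragments at all.

`maccr` quantifies this with a per-bin regression. For each fixed-width
genomic bin $b$ (100 bp by default), let $y_{bc}$ be the library-normalized
fragment frequency at concentration $c$ (counts per million of the
post-filter column total). The accessibility score is the ordinary
least-squares slope

$$\mathrm{MACC}_b = \frac{\mathrm{cov}(x, y_b)}{\mathrm{var}(x)},
  \qquad x = -\log c ,$$

so open chromatin (high frequency at low concentration) scores positive
and protected chromatin scores negative. The natural log is used; any
other base rescales every score by one constant and is available through
`compute_macc(log_base=)`.

Upstream of the fit:

* **Hotspot filtering** (`filter_hotspots`): positions whose fragment-start
  count has a Z-score of at least 7 relative to all covered positions of the
  sample are masked, and fragments starting there are dropped. The reference
  population (all covered positions of the sample) is this package's
  choice; filtering precedes normalization, and both facts are logged in
  the count attributes.
* **Counting** (`count_fragments`): each fragment is assigned to exactly
  one bin by its midpoint, which avoids double counting across the grid.
  The accessibility statistic uses fragments of 100-200 bp; nucleosome
  read-frequency profiles use 140-160 bp. Both windows are parameters.
* **GC correction** (`gc_correct`): the expected score as a smooth
  function of bin GC content is estimated by lowess (span 0.3) over all
  scored bins and subtracted, preserving the genome-wide mean. Bins
  without GC annotation (no sequence, or all-N) pass through and are
  flagged. With fewer than 100 annotated bins the correction refuses to
  run rather than fit a meaningless curve.

Two recomputation validations mirror standard practice for X/autosome
comparisons in male cells: `median_shift` centers each sample at zero
before cross-sample comparison, and `double_x_reads` doubles raw X-linked
counts (compensating one X versus two autosome copies) before
renormalization.

## Differential accessibility

`test_bins` compares replicate score tracks of two conditions per bin with
a moderated two-sample t statistic: per-bin pooled variances are shrunk
toward a common prior variance, with the prior degrees of freedom
estimated from the spread of log sample variances by the method of moments
(`trigamma` inversion), and two-sided p-values use the t distribution with
the augmented degrees of freedom. This reproduces the standard
empirical-Bayes shrinkage behaviour with two replicates per condition; the
unit tests cross-check the statistic, the prior df, and the p-values
against an independent implementation of the same model. Headline outputs
threshold the raw p-value at 0.01, as is conventional for this assay; a
Benjamini-Hochberg column is included for reference but not used for the
headline tables.

Feature classification (`classify_regions`) assigns each bin by midpoint
with precedence TSS/TTS > enhancer > gene body > unannotated, using 500 bp
windows upstream of gene starts and downstream of gene ends (strand-aware)
and +/- 500 bp around enhancer centers. The precedence order keeps
regulatory windows distinct from gene bodies where they overlap; counts
can be normalized by the merged, non-double-counted fraction of the genome
each category covers, with a zero-coverage category reported as undefined.

Chromosome-level summaries report type-7 quartiles and the boxplot notch
convention $1.58\,\mathrm{IQR}/\sqrt{n}$, with two-sided Mann-Whitney
tests between chromosome groups and conditions.

## Anchored profiles

`site_profile` evaluates a track at a 10 bp offset grid around each anchor
by linear interpolation between *bin centers* (the center convention is
symmetric and grid-consistent), averages across sites with equal weight,
smooths with a short running window, and attaches the pointwise 95%
confidence band from the normal approximation
$\bar s \pm 1.96\,\mathrm{sd}/\sqrt{n}$ across sites. Anchors whose flank
would leave the chromosome are dropped and counted, not padded.
Minus-strand anchors are flipped so positive offsets always point
downstream. Metagene profiles (`metagene_profile`) rescale each gene body
to 100 interpolated positions (the resolution is a package choice) with
flanks in fixed bp; heatmap matrices share the same rows and sort by an
explicit key with stable ties. Score splits (`split_by_score`) use type-7
quantile boundaries with boundary ties kept in the lower group.

## The synthetic-data generator

Because the full assay cannot be rerun at desk scale, every stage is
validated against a generator with known ground truth
(`sim_config`/`make_genome`/`simulate_titration`). The generator emulates
the study design: four MNase concentrations (1.5, 6.25, 25, 100 units),
two replicates, three RNAi conditions (control, *clamp*, *msl2*), one X
chromosome plus two autosomes, X-restricted chromatin entry sites in
groups A/B/C at full-scale counts 176/43/45 (scaled by 0.25 by default),
and occupancy-scored binding peaks denser on the X (60/Mb vs 30/Mb, in
line with the density of GA-rich binding sites on the Drosophila X).

The expected normalized frequency of bin $b$ at concentration $c$ is
linear in $x = -\log c$:

$$\mu_b(c) = \beta_b + \bigl(a_b + g(\mathrm{GC}_b)\bigr)\,(x - \bar x),$$

so the estimand of `compute_macc` *is* the true slope and recovery tests
are exact in expectation. The GC confounder $g$ (a smooth centered
function of bin GC with linear and quadratic terms) is placed on the
slope, not the intercept: an intercept-only GC term would leave the
fitted slope unbiased and make GC correction untestable. Truth tables
store the GC-free slope $a_b$ per condition. Fragment counts are Poisson
(negative binomial optionally) around $\mu$ scaled to the configured
depth; fragment lengths are Normal(150, 15) truncated to [100, 250] bp,
matching the assay's mononucleosome-sized selection. Replicate-to-replicate
variability beyond counting noise is not separately parameterized (its
magnitude is not established for this assay); the defaults are exposed in
`sim_config` and the consequences are visible in the calibration tests.

Condition truth:

* *control*: a smooth background slope field (sd 0.12) plus an
  accessibility bump $A_p e^{-d/\lambda}$ around every peak
  ($\lambda$ = 2 kb, height proportional to occupancy) — with the bump
  support capped at $8\lambda$, peak influence spans roughly +/- 14 kb,
  the long-distance range observed for this factor;
* *clamp* RNAi: 70% of each peak bump removed, so the perturbation decays
  exponentially with distance from peak anchors;
* *msl2* RNAi: control minus a fixed decrement within 200 bp of entry-site
  centers only, reproducing the focal effect at entry sites.

Nascent-transcription counts per TSS are negative binomial around a
lognormal baseline; under *clamp* RNAi 10% of TSS are perturbed two-fold
(log2 effect 1.5), with the probability of positive regulation (abundance
decreasing after RNAi) set to 0.62 on the X and 0.35 on autosomes. qPCR Ct
tables invert the percent-input enrichment model exactly, plus Gaussian Ct
noise.

**What the generator does not emulate:** sequence-level MNase cut
preferences, chromatin three-dimensional structure, mappability artifacts,
replicate batch effects, and immunoprecipitation efficiency. Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated generative model, not robustness to every artifact of real
libraries.

## Normalization redistributes one-signed perturbations

One property of the pipeline deserves emphasis because it shapes the
validation results. Library-size normalization fixes every concentration
column's total, so when an RNAi condition *only removes* accessibility
near peaks, the removed slope mass necessarily reappears spread across all
other bins (in proportion to their baseline frequency). On the synthetic
genome, where peak neighbourhoods cover a large genome fraction, the
observed per-bin difference (RNAi - control) is therefore the local
perturbation plus a constant positive far-field offset of roughly 13% of
the near-peak amplitude. The offset is proportional to the bin baseline,
so neither median-shifting nor mean-centering removes it exactly. The
locality checks consequently assess the *distance trend*: band means of
the difference must decay monotonically out to five decay lengths and show
no residual distance dependence beyond that, relative to the far-field
plateau. The truth tables themselves are exactly local, and that is tested
separately. In real data the same effect exists but is diluted by the much
larger unperturbed genome fraction; randomized-site controls
(`randomized_sites`) and per-sample median-shifting are the standard
guards and both are implemented.

## Nascent transcription and qPCR

Observed TSS are defined as the argmax of 5'-end signal within +/- 250 bp
of the annotated start (ties to the lower coordinate, zero-signal genes
excluded); this is a deliberate simplification of the published protocol
and is labelled non-canonical in the output metadata. Differential
abundance normalizes to counts per million per replicate, transforms as
log2(cpm + 1), and reuses the moderated statistic; the original
normalization is not stated, so this stand-in is recorded in the result
attributes. Per-chromosome summaries round percentages to one decimal,
matching the reporting style of the assay (1,007 of 9,740 prints as
10.3%). CPM normalization shares the redistribution property above:
strongly asymmetric perturbations leak a small common shift into all TSS,
visible in the recovery test as a mildly elevated false-positive rate.

ChIP-qPCR enrichment assumes perfect per-cycle doubling (efficiency 2,
configurable): percent input is
$100 \cdot 2^{(Ct_\mathrm{input} - \log_2(1/f)) - Ct_\mathrm{IP}}$ with
input fraction $f$ (1% by default, giving a $\log_2 100$ dilution
adjustment), log2 fold enrichment is taken against an unbound
internal-control locus measured in the same replicate, replicate values
are averaged with SEM, and conditions are compared by a two-sided
equal-variance t-test. Technical-replicate Ct values are averaged *before*
the power transform in `relative_abundance`; the alternative order changes
the answer and the chosen order is asserted in tests. Whether technical
duplicates were originally averaged before or after input normalization is
not stated; averaging first is this package's documented convention.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including on disk (BED
  conventions); chromosome names pass through untouched and mismatches
  fail loudly.
* The slope is computed in closed form from centered cross-products; a
  long-hand normal-equations oracle agrees to below 1e-9.
* Zero pooled variance in the moderated test: identical constant
  replicates give p = 1 (zero numerator), a nonzero difference with zero
  variance gives p = 0.
* Hotspot filtering with zero spread of per-position counts (or a single
  covered position) masks nothing and warns.
* Double normalization is refused; zero-total concentration columns are
  an error, not NaN tracks.
* All randomness flows from one seed; derived sub-stream seeds stay below
  2^31. Rerunning the pipeline with a fixed seed produces byte-identical
  files (verified by checksum in the tests).

## Validation problem sizes

The heavier checks run on a genome of three 1 Mb chromosomes (30,000 bins
of 100 bp) at 2e6 fragments per sample — about 67 fragments per bin per
concentration, 530 aggregated across the series and replicates — where
the corrected score correlates with the true slope at r > 0.95 and the
residual score-GC correlation is below 0.01. Calibration of the
differential test uses a 10,000-bin genome with four control replicates
split two against two: p-values are uniform (Kolmogorov-Smirnov), type-I
error is within 1.5x nominal at 0.01 and 0.05, and power at an injected
shift of three replicate-noise standard deviations exceeds 0.8 at the 0.05
level (at 0.01 the same two-versus-two design has ~0.65 power, which is
why the power statement is made at 0.05). These sizes are package choices
that keep the default test run fast while leaving wide margins on every
threshold.

## Limitations

The moderated test assumes approximately Gaussian replicate noise on the
score scale and exchangeable per-bin variances around a common prior; very
low-count bins violate this first. The GC correction is one-dimensional
and cannot separate a GC effect from true accessibility that happens to
track GC. The observed-TSS definition and the Start-seq normalization are
stand-ins for unpublished details of the original analysis. None of the
biological interpretation (which factors open chromatin where) is encoded
in the package; it only reproduces the measurements.
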