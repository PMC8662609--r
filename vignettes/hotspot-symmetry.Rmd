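---
title: "Homolog symmetry of recombination hotspots in hybrid mice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homolog symmetry of recombination hotspots in hybrid mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In house mice, the zinc-finger protein PRDM9 positions meiotic
recombination hotspots by binding specific DNA motifs and depositing
H3K4me3, after which DSBs (double-strand breaks) form at a subset of
bound sites. Because DSB repair is mutagenically biased against the
motif, the *strongest* binding sites of a PRDM9 allele are progressively
lost — "eroded" — from the genome in which that allele resides. In an F1
hybrid between two diverged strains, each PRDM9 allele therefore binds
mainly the *other* parent's chromosome, where its best motifs are still
intact. A DSB on one homolog with no PRDM9 bound at the matching
position on the other homolog impairs homology search; when too few
hotspots are symmetrically bound, chromosomes fail to synapse, meiosis
arrests, and the hybrid is sterile. Replacing one allele with a *de
novo* allele (one whose motifs neither genome has eroded) restores
symmetric binding, synapsis and — partially — fertility.

`hotspotsym` implements the quantitative side of this analysis as a
reusable, fully testable pipeline over *synthetic* data: a generator
emulates DMC1-SSDS-like reads from a hybrid with configurable erosion,
and the analysis stages recover homolog bias per hotspot, classify
hotspots as matched vs eroded, attribute them to alleles, and relate
synapsis rates to sperm production through a threshold model.

## Pipeline overview

1. **synthetic data** — two haplotypes differing at biallelic SNPs;
   hotspots with per-allele, per-homolog intensities; strand-offset read
   pileups with sequencing error; phenotype cohorts.
2. **variant filtering** — keep SNPs that are biallelic, `FILTER=PASS`
   and homozygous-ALT in the non-reference strain (heterozygous,
   missing-genotype, indel and multiallelic records are dropped; a third
   allele cannot be attributed to either homolog).
3. **read assignment** — at each informative SNP a read base votes for
   the haplotype it matches; the read-level call is the vote majority,
   with ties and all-abstain reads `ambiguous` and SNP-free reads
   `uninformative`.
4. **peak calling** — sliding-window Poisson enrichment against
   max(local, global) background with Benjamini–Hochberg correction;
   merged windows become peaks; SSDS centres exploit the strand-offset
   geometry (plus-strand reads upstream, minus-strand downstream of the
   DSB).
5. **allele attribution** — a hybrid peak is attributed to the allele
   whose single-allele reference map has a centre within `max_dist`
   (default 500 bp), provided the other map has none (conservative
   ambiguity rule).
6. **homolog symmetry** — per peak, the B6-homolog read fraction `f` is
   estimated with misclassification correction (below); peaks with
   `0.25 <= f_hat <= 0.75` are *matched*, peaks beyond that band
   *eroded*; per-allele matched-read proportions summarise each regime.
7. **phenotypes** — Welch t-tests between genotype groups and a step
   ("cliff-edge") fit of log sperm count against synapsis rate.

## The misclassification-corrected fraction estimator

Each informative read carries the wrong homolog label with small
probability $\varepsilon$ (sequencing error at the SNP base, residual
mis-assignment). If the true B6 fraction at a hotspot is $f$, an
observed read is labelled B6 with probability

$$p = \varepsilon + f\,(1 - 2\varepsilon),$$

so with $n$ informative reads, $n_{B6} \sim \mathrm{Bin}(n, p)$ and the
maximum-likelihood estimate is the clamped inverse map

$$\hat f = \mathrm{clamp}\!\left(\frac{\hat p - \varepsilon}
  {1 - 2\varepsilon},\, 0,\, 1\right), \qquad \hat p = n_{B6}/n .$$

The 95% interval is the Wilson score interval on $\hat p$ pushed through
the same monotone map. $\varepsilon < 0.5$ is required for
identifiability. Under the generator's uniform-substitution error model
an error at the SNP base hits the *other* allele with probability
$\varepsilon_{\text{seq}}/3$ (the remaining $2\varepsilon_{\text{seq}}/3$
produce abstentions), so single-SNP reads flip with rate
$\varepsilon_{\text{seq}}/3$ — the value the pipeline passes as
$\varepsilon$ when analysing its own simulations. For real data it is a
free parameter (default 0.01).

The classification band is **inclusive** at 0.25 and 0.75: erosion is
defined strictly as more than 75% of reads from one homolog, so the
endpoints belong to "matched".

Matched-read proportions are reported in three weightings: by
informative reads (the estimator's own currency), by total
strand-resolved peak reads (comparable with the simulator's truth, which
counts all reads), and by peaks. Informative-read counts per hotspot
fluctuate with the accidental local SNP density of each hotspot's small
footprint, so the total-read weighting is the more stable summary of
signal; whether published proportions weight by all or only informative
reads is ambiguous, hence all are reported.

## The synthetic-data generator

What it emulates, and the key defaults:

| parameter | default | meaning |
|---|---|---|
| `heat_meanlog`, `heat_sdlog` | 0, 0.75 | log-normal per-hotspot intensity; heavy-tailed, as binding affinities span strong to weak |
| `erosion_prob` | per scenario | probability a hotspot's site is lost on its allele's own background |
| `erosion_factor` | 0.05 | multiplicative residual heat on the eroded homolog (erosion is not always complete loss) |
| `min_spacing` | 5000 bp | minimum distance between hotspot centres; hotspots are discrete, well-separated loci and a caller cannot resolve closer pairs |
| `frag_offset_mean`, `frag_offset_sd` | 100, 30 bp | strand-specific displacement of SSDS read midpoints from the DSB site |
| `seq_error_rate` | 0.001 | per-base substitution error, uniform over the other three bases |
| `read_length` | 50 bp, single-end | typical short-read tag geometry |
| `background_per_kb` | 0.5 | uniform non-hotspot reads |

Erosion acts on the homolog carrying the allele's own genetic
background: allele 1 (the reference-strain allele) erodes on the B6
homolog, allele 2 on the ALT homolog. Coordinates are 0-based
half-open internally; VCF is written 1-based, BED 0-based half-open.
Reads are emitted pre-aligned (their placement is known from
simulation); no aligner is run, as the analysis starts from mapped tags.

**The two study regimes.** `regime_config()` fixes the conditions the
analysis contrasts. Under the erosion model the expected read-weighted
matched proportion at erosion probability $p$ is
$2(1-p) / \left(2(1-p) + (1+\text{factor})\,p\right)$; inverting this
(`erosion_for_matched()`) gives $p = 0.915$ for the wild-type regime
(15% matched) and $p = 0.559$ for the de novo allele (60% matched). The
de novo allele is thus modelled with a *much-reduced residual* erosion
probability rather than exactly zero: engineered alleles observed in
hybrids retain 47–67% matched signal, not 100%, because their binding
sites are not perfectly symmetric either. Each regime simulates 200
hotspots per allele on a 20 Mb chromosome with 1 SNP per 100 bp
(SPRET-level divergence) and ~160 reads per non-eroded hotspot —
small enough to run in seconds, large enough that the matched-read
proportion is estimated to about ±0.01.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: PCR duplicates and mappability
artefacts; motif-dependent binding (heats are drawn, not computed from
sequence); erosion biased towards the strongest sites (erosion is
independent of heat here); indel variation between strains; multi-
chromosome structure and the X/Y-specific behaviour of hybrids;
single-stranded-DNA-specific read-type structure of the original
protocol. Results on real data additionally depend on the upstream
caller and variant quality.

## Phenotype model and the cliff-edge fit

Each simulated mouse contributes `nuclei_synapsed ~ Bin(nuclei, p_group)`
over ~100–115 scored nuclei, testis and lean body weights per group, and
a sperm count drawn from a near-zero Poisson law when the group's true
synapsis probability is below the threshold $\tau = 0.5$ and from a
log-normal law around $10^6$ otherwise. The default cohort (4 groups
× 6 mice, true synapsis 0.25 / 0.45 / 0.55 / 0.95) spans the spectrum
from sterile wild-type hybrid through partially rescued hybrids to a
parental control, with the two middle groups straddling the threshold —
a threshold is only identifiable from data on both sides of it. A
design-stage power calculation fixed the nuclei count: with only ~65
nuclei per mouse the binomial noise in observed synapsis rates leaves
the threshold recoverable to ±0.05 in barely ~80% of cohorts, while
~100–115 nuclei give ~97%; the higher count is standard for careful
cytological scoring.

The fit itself: sperm counts are log10-transformed with azoospermic
mice floored at a pseudo-count of 2 (the plotting convention for zero
counts); the step model
$E[\log_{10} s] = m_{<}\,1(x<\tau) + m_{\ge}\,1(x\ge\tau)$
is fitted by exhaustive search of $\tau$ over midpoints between
consecutive distinct synapsis values, minimising SSE. A step rather
than a hinge or segmented regression is deliberate: the relationship is
a cliff edge, not a smooth increase. The bootstrap (resampling mice,
default 1000 replicates, seeded) gives a percentile interval for
$\tau$. Degenerate data — all mice on one side, or a flat SSE
landscape — are flagged rather than fitted. Group comparisons use
Welch's unequal-variance t-test, two-sided, with the convention
$t = 0,\ p = 1$ for two constant equal groups.

## Numerical and design choices

* **Peak calling**: window 1 kb, step 100 bp, background window 10 kb,
  `min_reads` 5, `q <= 0.01`, merge gap 1 kb — chosen to resolve
  hotspots at the simulated spacing; all configurable. The SSDS centre
  is the midpoint of the strand-specific mean read midpoints, falling
  back to the overall mean when a strand is empty.
* **Read-level majority vote** rather than a read-level likelihood:
  read calls stay interpretable as counts, and the
  $\varepsilon$-corrected estimator downstream absorbs
  misclassification. Bases below Q20 abstain; duplicate/secondary/
  supplementary alignments are dropped on input.
* **Attribution by centre distance** (500 bp) rather than reciprocal
  overlap: hotspot positions are point-like. Peaks near both maps are
  left unattributed rather than guessed.
* **`min_reads` = 5** informative reads for a resolved symmetry class;
  below that a peak is `unresolved` and excluded from proportions.
* **Determinism**: one master seed spawns fixed per-stage streams
  (`stage_seed()`), so any stage can be rerun in isolation and a full
  rerun is byte-identical.
* **Repeat masking** of SNPs is not applied; whether the original
  filtering did so is unknown, and the generator contains no repeats.

## Problem sizes used by the test-suite and acceptance script

Module tests run on 0.2 Mb simulations (~2,000 reads, seconds each).
The end-to-end regime analyses use the 20 Mb / 400-hotspot configs
described above (~10 s each). The estimator is checked against a
two-stage grid search (resolution $10^{-8}$) on 1,000 random count
triples, interval coverage on 200 replicates of 50 reads, and the
cliff-edge threshold on 100 simulated cohorts of 24 mice. These sizes
were chosen so the whole suite completes in a few minutes while leaving
the statistical assertions well-powered.

## Known limitations

* The erosion probability is uniform across hotspots; real erosion
  preferentially removes the strongest sites, which would make the
  *read-weighted* matched proportion lower than the peak-weighted one
  even at equal erosion counts.
* The caller is a generic enrichment test, not a reimplementation of
  any published SSDS caller; absolute peak numbers on real data would
  differ.
* Attribution relies on reference maps with point centres; alleles with
  overlapping binding repertoires would need motif-level evidence,
  which is out of scope.
* The phenotype model treats sperm production as a pure threshold
  process; biological intermediates (partial arrest, bystander cell
  death) are subsumed into the two sperm-count laws.
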