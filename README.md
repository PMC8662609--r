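# hotspotsym

Allele-specific analysis of meiotic recombination hotspots in F1 hybrid
mice, with a synthetic-data generator that makes every stage testable
without external data.

## Background

PRDM9 positions meiotic recombination hotspots by sequence-specific DNA
binding. Within a population, the strongest binding sites of the
resident *Prdm9* allele are progressively eroded by biased DSB repair.
In a hybrid between two diverged mouse strains each allele therefore
binds mostly the *other* parent's chromosome: DSBs land on one homolog
while the matching position on the other homolog is unbound, homology
search falters, chromosomes fail to synapse and the hybrid is sterile.
A *de novo* allele (e.g. an engineered one) whose motifs are intact on
both genomes restores symmetric binding — and, above a threshold level
of synapsis, sperm production.

`hotspotsym` implements the quantitative pipeline for this analysis:

* **simulate** a hybrid chromosome: two haplotypes differing at
  biallelic SNPs, hotspots with per-allele/per-homolog intensities and
  configurable erosion, strand-offset SSDS-like reads with sequencing
  error (FASTA/VCF/SAM out), and phenotype cohorts;
* **filter** strain-distinguishing SNPs from a VCF (PASS, biallelic,
  homozygous-ALT);
* **assign** each read to its homolog of origin by majority vote over
  the SNPs it covers;
* **call peaks** with a sliding-window Poisson test (BH-corrected) and
  strand-geometry centre estimation;
* **attribute** each peak to the PRDM9 allele that activates it via
  single-allele reference maps;
* **estimate** each hotspot's B6-homolog read fraction `f` with the
  misclassification-corrected MLE
  `f_hat = clamp((p_obs - eps) / (1 - 2 eps), 0, 1)` and Wilson
  intervals, classify hotspots as *matched* (`0.25 <= f_hat <= 0.75`)
  or *eroded* (`> 75%` of reads from one homolog), and summarise
  per-allele matched-read proportions;
* **fit** the "cliff-edge" threshold model of sperm production vs
  synapsis rate (step regression with exhaustive threshold search and a
  bootstrap CI), plus Welch t-tests between genotype groups.

See `vignettes/hotspot-symmetry.Rmd` for the models, assumptions and
design choices.

## Worked example

The numbered scripts under `analysis/` reproduce the whole analysis
(`01_simulate.R` → `02_hotspot_symmetry.R` → `03_phenotypes.R`,
tables under `results/`, bulky per-stage files under `scratch/`).
In brief:

```r
library(hotspotsym)

cfg <- regime_config("denovo", seed = 1)   # engineered-allele hybrid
hap <- generate_haplotypes(cfg)
hs  <- generate_hotspots(cfg)
rd  <- simulate_reads(hs, hap, cfg)
asn <- assign_reads(rd, hap$variants)
pk  <- attach_reads(call_peaks(rd, cfg$chrom_length), asn)
at  <- attribute_peaks(pk, hs[hs$allele == "allele1", ],
                       hs[hs$allele == "allele2", ])
sym <- hotspot_symmetry(pk, epsilon = cfg$seq_error_rate / 3)
matched_read_proportion(sym, at, "allele1")$total_read_weighted
```

Running the scripts prints (seed 1):

```
[eroded] 400 hotspots (361 eroded), 50911 reads; true matched-read
         proportion: allele1 0.205, allele2 0.137
[denovo] 400 hotspots (303 eroded), 57364 reads; true matched-read
         proportion: allele1 0.585, allele2 0.131
[eroded]  allele1: matched-read proportion 0.200 (185 peaks)
          allele2: matched-read proportion 0.146 (181 peaks)
[denovo]  allele1: matched-read proportion 0.589 (186 peaks)
          allele2: matched-read proportion 0.140 (178 peaks)
```

i.e. the pipeline recovers each simulation's true matched-read
proportion to ~0.01: in the wild-type-like hybrid both alleles sit
mostly at eroded, one-homolog hotspots (~15–20% matched signal), while
the de novo allele binds at matched positions for ~60% of its signal.
The phenotype stage then prints:

```
Cliff-edge threshold fit
  tau_hat     : 0.491 (95% bootstrap CI 0.430-0.532)
  mean log10 sperm below/above: 0.73 / 6.12
```

— sperm production switches on at roughly 50% autosomal synapsis:
cohort members below the fitted threshold are (nearly) azoospermic,
members above produce ~10^6 sperm.

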