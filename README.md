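# dimerqc

Quality control for adapter-dimer contamination in small RNA sequencing.

Adapter dimers form during library preparation when a 5' adapter ligates
directly to a 3' adapter with no biological insert between them.  The
product amplifies and clusters *more* efficiently than real library
molecules and sequences as the full 3' adapter starting at read position
0.  Heavily contaminated samples lose most of their reads during
pre-processing; worse, when the dimer burden varies between samples it
generates batch effects that can dominate the biology in downstream
ordination.  dimerqc is for sequencing facilities and analysts working
with low-input small RNA material (extracellular vesicles, plasma,
FFPE tissue) who need to detect this failure mode before and after
sequencing.

## What it computes

* **Per-read detection.** Error-tolerant semi-global adapter alignment
  under unit-cost edit distance: a candidate aligning *a* adapter bases
  with *e* edits is admissible iff *e* &le; floor(rate &middot; *a*) and
  *a* &ge; min_overlap; best = fewest errors, then longest adapter span,
  then leftmost.  A read whose 3' adapter match implies an insert of
  &le; 2 nt is an adapter dimer.  Reads classify into
  DIMER / SHORT / LOW_QUALITY / CLEAN, with
  n_raw = n_dimer + n_short + n_lowq + n_clean exactly.
* **Per-sample QC.** Read-loss percentages, the cumulative 3'-adapter
  content curve (adapter at position 0 = dimer fingerprint),
  overrepresented sequences (> 0.1% of the library), per-position mean
  quality; JSON reports, optional cleaned FASTQ.
* **Cohort stratification.** Samples ordered by read loss, piecewise
  linear regression of loss on rank with exhaustive breakpoint search
  and BIC model selection; per-segment slope, intercept, R&sup2;.  Plus
  per-sample loss decomposition into dominant causes and a Spearman test
  of RNA input vs loss.
* **Batch-effect test.** log2 counts-per-million, pairwise
  leading-log-fold-change distances (root-mean-square of the top-500
  largest |&Delta;log2 CPM|), classical metric MDS, and a seeded
  permutation test of Spearman correlation between per-sample dimer
  percentage and each MDS coordinate.
* **Electropherogram screening.** Dimer-peak detection in library
  traces (Ion Torrent dimers near 88 bp, libraries near 110 bp;
  Illumina dimers near 120 bp) and a dimer-to-total area ratio.
* **Simulator.** Seeded generation of libraries and cohorts with exact
  ground truth (construct geometry, platform read models, noise,
  dimer-coupled composition bias) - the package's own test harness.

## Worked example

```r
library(dimerqc)

# a contaminated Ion Torrent plasma-style library with known truth
cfg <- sim_config(n_reads = 10000, dimer_fraction = 0.35,
                  short_fraction = 0.10, platform = "iontorrent",
                  substitution_rate = 0.01, indel_rate = 0.01, seed = 42)
lib <- simulate_library(cfg)
qc  <- process_sample(lib$reads, platform_preset("iontorrent-smallrna"),
                      "plasma_04")
print(qc)
#> sample_qc 'plasma_04': 10000 raw reads
#>   dimer 35.0%  short 10.0%  low-quality 0.0%  clean 55.0%  (read loss 45.0%)
head(qc$overrepresented, 2)
#>                         sequence count percentage
#> 1 ATCACCGACTGCCCATAGAGAGGAAAGCGG  1892      18.92
#> 2  ATCACCGACTGCCATAGAGAGGAAAGCGG    39       0.39
```

The recovered dimer percentage matches the simulated 35% despite 1%
substitution and indel noise, and the top overrepresented sequence is
the full Ion 3' adapter itself - the post-sequencing dimer fingerprint.

```r
# a 12-sample cohort whose composition is tilted with dimer burden
co  <- simulate_cohort(12, seq(0.05, 0.8, length.out = 12),
                       sim_config(n_reads = 5000, n_features = 300,
                                  dimer_bias_coupling = 1, seed = 42),
                       emit_reads = FALSE)
mds <- leading_logfc_mds(log_cpm(co$counts), top_n = 300)
dimer_batch_effect_test(mds, co$truth_fractions[, "dimer"] * 100,
                        n_perm = 10000, seed = 1)
#>   dimension spearman_rho     p_perm n_perm seed
#> 1         1    0.9930070 0.00009999  10000    1
#> 2         2   -0.2937063 0.35626437  10000    1
```

Dimer content orders the samples along MDS dimension 1 almost perfectly
(rho 0.99, permutation p = 1/10001): a batch effect driven by a purely
technical variable.

```r
# pre-sequencing: the same contamination seen in the electropherogram
tr  <- simulate_trace(list(c(88, 2, 150), c(110, 2, 300)),
                      noise_sd = 1, seed = 1)
detect_dimer_peak(tr, dimer_window = c(80, 95),
                  library_window = c(100, 130))
#> dimer 88.0 bp, library 110.0 bp, ratio 0.337
```

## Command line

`exec/dimerqc` exposes the same pipeline as subcommands:

```sh
dimerqc simulate --n-samples 12 --n-reads 10000 \
    --dimer-fracs 0.05,0.1,0.2,0.4,0.6,0.8 --platform iontorrent \
    --seed 1 --out-dir sim/
dimerqc scan sim/sample_01.fastq.gz --preset iontorrent-smallrna \
    --json s01.json --clean-out s01.clean.fastq.gz
dimerqc cohort s*.json --out cohort.tsv
dimerqc mds sim/counts.tsv --qc cohort.tsv --n-perm 10000 --seed 1 \
    --out mds.tsv
dimerqc epg trace.csv --dimer-window 80:95 --library-window 100:130 \
    --out peaks.json
```

Exit codes: 0 ok, 1 usage error, 2 data error.  Every output embeds the
tool version and resolved parameters.

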