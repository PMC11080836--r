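---
title: "Detecting adapter-dimer contamination in small RNA sequencing: methods and design"
author: "dimerqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adapter-dimer contamination in small RNA sequencing}
  %\VignetteEncoding{UTF-8}
---

## The problem

Small RNA library preparation ligates single-stranded adapters to both
ends of short biological inserts (typically 18-30 nt).  When a 5' adapter
ligates directly to a 3' adapter with no insert in between, the product -
an *adapter dimer* - still carries everything needed to amplify, bind the
flow cell or sphere, and be sequenced.  Being shorter, it amplifies and
clusters *more* efficiently than genuine library molecules.  A dimer read
is easy to recognise after sequencing: the first sequenced base is already
the first base of the 3' adapter, so the full adapter sits at read
position 0 with a zero-length insert.

Dimer contamination has two costs.  First, contaminated samples lose a
large fraction of their reads during pre-processing (adapter clipping,
quality trimming, minimum-length filtering), down to the point of
sequencing failure.  Second, and more insidiously, when the dimer burden
*varies between samples* it couples a technical variable to the usable
sequencing depth and to the recovered expression profile, producing batch
effects that can dominate the biological signal in ordination plots.

dimerqc implements the complete detection workflow: per-read adapter
matching and classification, per-sample QC aggregation, cohort-level
read-loss stratification, pre-sequencing electropherogram peak detection,
and a formal batch-effect test on MDS coordinates - together with a
seeded simulator that generates libraries with known composition so every
stage is testable without external data.

## Adapter matching

The core primitive is an error-tolerant semi-global alignment of an
adapter inside a read under unit-cost edit distance
(`find_adapter()`).  Three modes mirror the standard trimming idioms:

* **back** (3' adapter): the candidate set is the full adapter at any
  read position, plus adapter *prefixes* reaching the read's 3' end
  (partial read-through);
* **front** (5' adapter/primer): the full adapter at any position, plus
  adapter *suffixes* anchored at the read's 5' start;
* **anywhere**: the union of both, used for Ion Torrent chemistry where
  the adapter can be encountered on either side.

A candidate aligning `a` adapter bases with `e` edits (mismatches,
insertions, deletions) is admissible iff `e <= floor(rate * a)` and
`a >= min_overlap` (default 3).  The best admissible candidate has the
fewest errors, then the most aligned adapter bases, then the smallest
start coordinate (then the smallest end, so reports are bit-stable).
`N` never matches anything.  This error-budget dialect is the closest
simple reading of the widely used trimming tools' documented rule; the
package carries its own ground truth in the form of an exhaustive
brute-force reference (`find_adapter_oracle()`) that enumerates every
(start, end, span) candidate with plain anchored dynamic programming,
and the test suite keeps the two in exact agreement across tens of
thousands of randomized inputs.

Two platform presets are shipped verbatim from the respective kit
chemistries: `illumina-truseq-smallrna` (3' adapter
`TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC`, error rate 0.1, plus the 5' RT
primer `CGACAGGTTCAGAGTTCTACAGTCCGACGATC`) and `iontorrent-smallrna`
(`ATCACCGACTGCCCATAGAGAGGAAAGCGG`, anywhere mode, error rate 0.2).

**Design choice - anchored 5' primer evidence.**  The 5' primer pass is
anchored at the read start.  With the generic 3-base minimum overlap, a
random insert's first three bases would spuriously match a 3-base primer
suffix in 1 of 64 reads, silently eroding genuine inserts (and pushing
boundary-length inserts below the length filter).  Because this pass
exists to remove complete primer read-through artifacts, the preset
requires full-length primer evidence (`min_overlap` equal to the primer
length, with the usual 10% error budget).  A full 32-mer cannot fit
inside a 16-30 nt insert within budget, so the preset provably never
truncates real inserts, while true primer carry-over - which is full
length by construction - is still removed.

## Read classification

`classify_reads()` applies, per read: (1) locate the 3' adapter; a match
whose implied insert is at most `dimer_max_insert` (default 2 nt,
tolerating a couple of junk bases at the ligation junction; 0 recovers
the strict adapter-at-position-0 definition) is a `DIMER`.  (2) Trim the
adapter, and the 5' primer where configured.  (3) Quality-trim the 3'
end with the classic partial-sum rule: cut at the position minimising
the running sum of `quality - threshold` accumulated from the 3' end
(threshold default Phred 20), keeping the longest read among ties.
(4) Reads ending below `min_length` (default 15 nt, the shortest insert
that maps non-promiscuously) are `SHORT` when an adapter was found or
the read was already short before quality trimming, else `LOW_QUALITY`.
(5) Everything else is `CLEAN`.  The priority `DIMER > SHORT` keeps the
two loss sources disjoint, so a cohort's read loss decomposes exactly:
per sample, `n_raw = n_dimer + n_short + n_lowq + n_clean` always.

Some published pipelines quality-trim with a sliding window instead of
the partial-sum rule; on high-quality data at threshold 20 the
difference is marginal, and the partial-sum rule is used uniformly here
for both platforms.

`process_sample()` aggregates a whole FASTQ (streamed in bounded-memory
chunks) into a `sample_qc` record: class counts and percentages, the
cumulative 3'-adapter-content curve over read positions (a high value at
position 0 is the dimer fingerprint), exact overrepresented-sequence
counts (full read sequences present at more than 0.1% of the library -
full 3' adapter sequences passing this filter are dimers seen
post-sequencing), and mean quality per position.  Overrepresented
sequences are counted exactly on full-length raw reads, preferring
exactness over the truncation-and-subsampling shortcuts some report
tools take at interactive scale.

## Cohort stratification and loss decomposition

Contaminated cohorts typically split into a majority of samples with
modest, slowly varying read loss and a contaminated tail whose loss
climbs steeply.  `segment_by_read_loss()` formalises the visual
stratification: samples are ordered by ascending loss, loss is regressed
on rank, and every placement of up to two breakpoints (each segment at
least 3 samples) is fitted exhaustively by least squares; the model
minimising BIC (total residual sum of squares; two parameters per
segment plus one per breakpoint) wins.  Each segment reports slope
(% loss per rank), intercept and R-squared.  The exhaustive search is
exact - there is no heuristic optimisation - and the result is invariant
to the input order of samples.

One behaviour worth knowing: ordering samples by loss makes the fitted
values order statistics, which are smoother than independent noise, so
on long shallow segments BIC occasionally affords an extra interior
split.  The steep-segment boundary - the scientifically meaningful
quantity - is unaffected; in the packaged recovery study (two regimes
with slopes 1 and 6, unit noise, 40 samples) the boundary is recovered
to within one rank in ~98 of 100 replicates.

`decompose_loss()` expresses each sample's dimer/short/low-quality
percentages as fractions of its total loss and labels the dominant
cause; zero-loss samples are labelled `NONE`.
`loss_vs_input_correlation()` tests the common suspicion that low RNA
input drives read loss, using Spearman rank correlation - inputs span
orders of magnitude across experiments, so rank correlation is the
appropriate scale-free choice - with the exact small-sample null
distribution below n = 10 and the large-sample approximation otherwise.

## Expression-level batch effects

`log_cpm()` converts a feature-by-sample count matrix to
`log2((count + prior) / (libsize + 2 * prior) * 1e6)` with a prior count
of 2.  `leading_logfc_mds()` computes, per sample pair, the
root-mean-square of the `top_n` (default 500) largest absolute log-CPM
differences - the "leading log-fold-change" distance - and embeds
samples by classical metric MDS (double centering of squared distances,
eigendecomposition, coordinates scaled by the square roots of the
eigenvalues).  For Euclidean-embeddable distance matrices the embedding
is exact to machine precision.  Axis signs are fixed by making the
largest-magnitude loading positive; unlike a first-nonzero-loading rule
this is equivariant under sample reordering, so permuting the input
columns permutes the embedding identically.

The package turns the usual visual reading of an MDS plot ("the
contaminated samples cluster together") into a test:
`dimer_batch_effect_test()` computes the Spearman correlation between
per-sample dimer percentage and each MDS coordinate, with a two-sided
permutation p-value `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)` under a
seeded generator.  In simulation the test holds its nominal level (type
I error 0.04-0.06 at alpha = 0.05 over hundreds of null cohorts) and
reaches full power when a dimer-coupled composition bias of plausible
size is injected (see below).

## Electropherogram screening

Dimer contamination is visible *before* sequencing as a discrete peak in
the library electropherogram below the library size - around 88 bp on
Ion Torrent chemistry and around 120 bp for Illumina TruSeq small RNA
libraries (whose library peak sits near 145-160 bp).
`detect_dimer_peak()` smooths the trace (5-point moving average), takes
the 5th percentile of the smoothed signal as baseline, estimates the
baseline noise robustly from first differences (plain MAD of the
baseline region degenerates when instruments clip negative noise to
zero), and calls, per user window, the tallest local maximum exceeding
baseline + 3 x noise.  Peak areas are trapezoidal integrals of the raw
signal above the quiet-region noise floor; integration is deliberately
not rectified pointwise, so zero-mean residual noise cancels instead of
accumulating with window width.  The summary statistic is
`dimer_area / (dimer_area + library_area)`; it is reported, not
thresholded - no instrument-independent cutoff for "too contaminated"
is defensible, and the ratio is monotone in the underlying dimer amount,
which is what decision-making needs.  Default windows are the Ion
Torrent sizes (dimer 80-95 bp, library 100-130 bp); both are plain
parameters since instruments report bp or migration minutes.

## The simulator

`simulate_library()` generates reads by the construct geometry itself,
so ground truth is exact by construction.  Per read a class is drawn:
`DIMER` (insert length 0), `SHORT` (insert uniform between
`dimer_max_insert + 1` and `min_length - 1`), or `CLEAN` (a feature from
a pool with Dirichlet-distributed abundances).  Short inserts start
above `dimer_max_insert` so the three construct classes are
geometrically disjoint - a generator that labelled a 1-nt-insert
construct `SHORT` while every classifier following the field's
operational definition calls it a dimer would make exact round-trip
validation impossible by design, not by defect.

Platform geometry follows the instruments: Illumina reads are
`insert + 3' adapter + downstream construct filler`, truncated/padded to
the fixed 75 nt read length, so dimer reads show the full adapter at
position 0 followed by deterministic construct sequence (adapter
read-through); Ion Torrent reads are `insert + adapter` at natural,
variable length.  Defaults model a TruSeq-style miRNA experiment:
insert lengths truncated-normal with mean 22 nt, sd 2, range 16-30
(matching a 22-30 nt size selection), 300 features, symmetric
Dirichlet(1) abundances.  Substitution and indel noise (indels being an
Ion characteristic) are per-base Bernoulli events, off by default and
set to 0.01 in the validation studies.  Qualities follow a linear decay
with Gaussian jitter (Illumina start 36, slope -0.05/base, sd 2; Ion
30/-0.08/3), clipped to [2, 40] - the simplest model that exercises
quality trimming, with no claim to instrument realism.  All randomness
flows from one seed; identical configurations are bit-identical.

`simulate_cohort()` shares one feature pool across samples and, when
`dimer_bias_coupling > 0`, tilts each sample's abundances along a fixed
random direction proportionally to its dimer fraction (multiplicative
logit tilt).  This is the mechanism hypothesised behind dimer-driven
batch effects - contamination level modulating recovered composition -
and it gives the batch-effect test something real to detect.  The power
studies use coupling 1.0 with dimer fractions spanning 0.05-0.8; the
calibration studies use coupling 0.  A counts-only mode
(`emit_reads = FALSE`) draws the identical multinomial class and feature
counts without constructing read strings, which keeps
hundreds-of-cohorts calibration studies cheap.

What the simulator does *not* model: PCR duplicates, cluster-density
effects, homopolymer error spectra, positional bias in ligation, or real
miRNA sequence composition (features are random DNA unless a FASTA is
supplied).  Green tests therefore certify the *algorithms* - matching,
classification, segmentation, testing - against known truth; they are
not evidence about any particular instrument's error profile.

## Problem sizes and numerical choices

The packaged validation studies run at desk scale, chosen as the
smallest sizes at which the statistical assertions have comfortable
margins: 10^4-read libraries (binomial SE of a 40% fraction is 0.5
percentage points), 10^4 randomized matcher triples, 100-replicate
segmentation studies, 200 + 200 cohorts for test calibration and power
at 1000 permutations, and 100 randomized electropherogram
configurations at signal-to-noise 10 or better.  Error budgets use
`floor(rate * aligned + 1e-9)` to keep exact decimal products stable in
floating point.  Degenerate inputs are handled explicitly: empty
samples are flagged rather than divided by zero, constant dimer vectors
make the batch test undefined (flagged, not silently zero), constant
RNA input flags the correlation, sub-6-sample cohorts return a single
segment, and a perfectly linear cohort prefers one segment because the
residual floor (1e-12) makes extra parameters pure BIC penalty.

## Limitations

* The matcher's error-budget dialect (floor of rate times *aligned*
  adapter bases) is one defensible reading of the common tools' rule;
  tools differ in corner cases (indel handling near read ends, overlap
  accounting).  The in-repo brute-force reference, not any external
  tool, defines this package's semantics.
* Segmentation assumes loss-vs-rank is piecewise linear; cohorts with
  smoothly accelerating loss will be split somewhat arbitrarily, and
  BIC's extra-split tendency on order statistics (above) applies.
* The batch-effect test is correlational per dimension; it demonstrates
  technical structure but does not correct it, and it inherits MDS's
  rotation indeterminacy across near-degenerate eigenvalues.
* Electropherogram windows must be supplied in the instrument's units;
  no ladder-based time-to-bp calibration is attempted.
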