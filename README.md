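# keescan

Classification of H3K79me2/3-marked enhancer elements (KEEs) and differential
testing of enhancer–promoter Capture-C interactions under DOT1L inhibition.

## The problem

In MLL-rearranged leukemia cells a subset of active enhancers carries
H3K79me2/3 — a histone mark written exclusively by DOT1L and classically
associated with transcribed gene bodies, not enhancers. Characterizing these
elements requires a chain of genomic analyses: calling enhancers from
histone-mark peak co-occurrence, quantitative between-condition ChIP
normalization with a spike-in genome, statistical testing of promoter-anchored
Capture-C contact profiles, and contingency statistics linking enhancer class
to transcriptional and accessibility changes. `keescan` implements that chain
for analysts working with peak calls, binned signal tracks, per-fragment 3C
count matrices, and differential expression/accessibility tables.

## The core definitions and statistics

* **KEE**: a 200 bp genome bucket overlapping peaks of H3K4me1, H3K27ac *and*
  H3K79me2 (or me3); **non-KEE**: H3K4me1 + H3K27ac without H3K79me2/3.
  Enhancer buckets < 1 kb apart merge; a merged call is a KEE if it contains
  any KEE bucket. Calls are assigned to their nearest gene and genes with ≥ 1
  KEE are KEE genes.
* **ChIP-rx factor**: `f = (n_spike_input/n_target_input) /
  (n_spike_ip/n_target_ip)`, applied multiplicatively to tags-per-10-million
  tracks; global loss of target signal drives `f` below 1.
* **Differential Capture-C**: per-fragment counts normalized to reads per
  100k cis-reported reads; peaks filtered (cis, inside the interaction
  domain, > 10 kb from the probe); each peak tested with an exact paired
  Wilcoxon signed-rank over (fragment × replicate) pairs, Holm–Bonferroni
  adjusted within the probe's peak family.
* **Integration**: Pearson correlation of log2 per-enhancer read sums between
  paired tracks; Wilcoxon rank-sum expression comparisons; Fisher's exact
  test on class × status contingency tables; scaled-body metaprofiles.

A seeded synthetic-data generator (`sim_config()`, `write_sim_inputs()`)
produces every input with a ground-truth manifest, so classification
exactness, test calibration (null false-positive rate) and effect recovery
are all verifiable.

## Worked example

```r
library(keescan)
res <- run_kee_pipeline("kee_run", sim_config(seed = 7))
res$classification$summary
#>    klass  n proportion median_length_bp intragenic_fraction
#> 1    KEE 30        0.5             1200           0.4333333
#> 2 nonKEE 30        0.5             1000           0.5666667
res$recovery$exact
#> [1] TRUE
res$spikein$rx_factor
#> [1] 0.44469090 0.04437309
res$integration$mark_correlation
#> [1] 0.9741315
```

Sixty enhancer calls match the generator's manifest one-to-one with correct
classes (`exact = TRUE`); median call lengths run ~200 bp above the true
enhancer lengths because calls are unions of 200 bp buckets. The dot1li rx
factor is ~10× below the control factor, recovering the simulated
near-complete global loss of H3K79me3, and the H3K79me2/me3 signal
correlation at KEEs reproduces the tight mark concordance the classification
relies on. The same run writes `capture_results.tsv`, in which
Holm-significant interaction losses occur at KEE peaks (mean normalized
contact change < 0) and not at non-KEE peaks.

The same steps can be run as a narrated workflow:

```sh
Rscript analysis/01_simulate.R             # inputs + ground truth -> results/sim/
Rscript analysis/02_classify_enhancers.R   # KEE/non-KEE calls, gene labels
Rscript analysis/03_spikein_normalization.R
Rscript analysis/04_capturec_differential.R
Rscript analysis/05_integration_stats.R
```

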