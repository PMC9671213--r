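---
title: "Reference-free genotype imputation with a denoising convolutional autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free genotype imputation with a denoising convolutional autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcimpute)
```

## The problem

SNP-array genotyping and low-coverage sequencing produce incomplete
genotype matrices. Reference-based imputation fills the gaps by matching a
target sample against a large haplotype reference panel; when no panel is
available (non-model populations, consent restrictions, private cohorts), a
reference-free method must recover missing genotypes from the correlation
structure of the dataset itself. The structure that makes this possible is
linkage disequilibrium (LD): alleles at nearby loci are correlated, so a
genotype hidden at one site is largely predictable from its neighbours.

`dcimpute` implements a reference-free imputer built around a 1D
convolutional denoising autoencoder, together with the complete
benchmarking harness needed to evaluate it: masking protocols, the
CR/Hellinger/SEN/IQS/PCC metric suite, MAF stratification, paired t-test
model comparison, and an LD-aware genotype simulator so every stage can be
exercised without external data.

## Data model and encoding

A `genotype_matrix` holds samples x SNPs genotype classes. Diploid entries
are the number of non-reference alleles: 0 (hom ref), 1 (het), 2 (hom
alt), with `NA` for missing. A haploid "yeast-style" mode holds two strain
classes 1 and 2 (the second strain recoded from -1 to 2 so all classes are
non-negative).

Before entering the network, diploid genotypes are shifted by +1 so that
class 0 can stand for *missing*, then one-hot encoded over 4 channels:

| genotype | shifted class | one-hot |
|---|---|---|
| missing | 0 | (1,0,0,0) |
| 0 | 1 | (0,1,0,0) |
| 1 | 2 | (0,0,1,0) |
| 2 | 3 | (0,0,0,1) |

Haploid panels use 3 channels with the classes mapped directly
(missing -> (1,0,0), 1 -> (0,1,0), 2 -> (0,0,1)). Channel 1 is the
reserved missing channel in both modes. Masking an entry therefore *is*
the corruption step of a denoising autoencoder: the corrupted input
carries the missing channel where the clean target carries a genotype.

## Model

The network is an encoder-bottleneck-decoder stack of six 1D convolutions
(stride 1, same padding, kernel width 5, L1 kernel penalty 1e-4):

```
conv32 -> maxpool2 -> dropout0.2 ->
conv64 -> maxpool2 -> dropout0.2 ->
conv128 (bottleneck) ->
conv64 -> upsample2 -> dropout0.2 ->
conv32 -> upsample2 -> dropout0.2 ->
convC (softmax over channels)
```

Hidden activations are ReLU; the output layer is a per-position softmax so
each (sample, SNP) gets a probability vector over the C channels. Because
two pooling layers halve the SNP dimension twice and two upsampling layers
restore it, the SNP count must be divisible by 4; `truncate_to_multiple()`
drops trailing SNPs in position order to enforce this (e.g. 162,027 SNPs
become 162,024).

The convolutional form is the point: a kernel of width 5 sees a local
window of neighbouring SNPs, which is exactly the LD neighbourhood that
carries the information needed for reference-free imputation.

Defaults live in `model_spec()` and `training_config()` and follow the
standard configuration: filter counts (32, 64, 128, 64, 32, C), dropout
0.2, pool/upsample factor 2, Adam with initial learning rate 0.001, batch
size 32, 100 epochs, loss weight `alpha = 1`.

## Loss

Training minimizes categorical cross-entropy between the clean one-hot
target `x` and the predicted posterior `xhat`, averaged over the
N = samples x SNPs positions:

$$L_{CCE}(x, \hat{x}) = -\frac{1}{N}\sum_{i=1}^{N}\sum_{c=1}^{C} x_{ic}\,\log \hat{x}_{ic},$$

wrapped as a weighted loss $\alpha\, L_{CCE}$ (default $\alpha = 1$) plus
the L1 kernel penalties. The loss sums over *all* positions, not only
masked ones: the 0%-missing regime (pure reconstruction) only makes sense
under full reconstruction, and observed positions act as anchors for the
masked ones. Numerical choices: predictions are clamped at 1e-7 before the
log, so a perfect prediction scores about 1e-7 instead of producing -Inf;
Adam uses epsilon 1e-7; weights are Glorot-uniform initialized under a
caller-supplied seed; biases are excluded from the L1 penalty. All
backward passes are exact analytic gradients, checked against central
finite differences in the test suite.

## The training-loop contrast

The package's training loop exists in two first-class modes:

* `per_batch` — one optimizer step on each mini-batch's own loss. This is
  the customized loop: the second batch's loss is minimized starting from
  weights already updated for the first.
* `averaged_k` — gradients of the mean loss over `k` consecutive batches
  are accumulated before a single step (default `k = 2`), the baseline
  behaviour it is contrasted with.

With `k = 1` the two modes coincide bit-for-bit, which the tests assert.
The benchmark question — does per-batch stepping converge faster? — is
answered empirically by `run_experiment()`, which trains both modes under
identical splits, masks and initialization (paired by seed) and compares
epochs-to-threshold on validation loss. At equal epoch counts `per_batch`
simply takes k times more optimizer steps; that is the point of the
contrast, not an artifact.

Other loop conventions: training batches are reshuffled every epoch from
the seeded RNG stream; the final partial batch is used, not dropped; no
early stopping or learning-rate schedule; validation metrics are computed
in inference mode (dropout off). Given a fixed platform and BLAS thread
configuration, (seed, config, data) fully determines the trained weights.

## Masking and splitting protocol

`split_samples()` randomly partitions samples 64/16/20 into
train/validation/test (floored sizes, remainder to train).
`mask_random()` then hides `round(ratio * n_nonmissing)` currently
non-missing entries uniformly without replacement — entrywise, never whole
SNPs — recording them in a `mask_plan` so evaluations are replayable.
Masking is applied after splitting, independently per partition, at
enforced missing ratios of 0%, 10% and 20%. Training inputs are the
masked encodings; training targets the unmasked ones.

## SNP filters

`filter_snps()` natively reimplements the standard pre-imputation QC:
per-SNP missingness (default 0: any missing call removes the SNP), a
Hardy-Weinberg equilibrium test (p < 1e-6 removes), and MAF < 0.1%
removes. HWE uses the one-degree-of-freedom chi-square on observed vs
expected genotype counts rather than an exact test: it is self-contained,
and at a 1e-6 threshold the choice of variant is immaterial except at very
small sample sizes. Sample-level QC, multiallelic splitting and strand
harmonization are upstream concerns for dedicated tools and are out of
scope; `read_vcf()` does skip (and count) multiallelic records.

`bin_by_maf()` labels SNPs with the four standard evaluation bins
(MAF > 5%, 1-5%, 0.5-1%, 0.1-0.5%). The published bin definitions use
strict inequalities that leave boundary membership ambiguous; boundaries
are assigned to the lower bin here (left-open intervals), documented and
configurable via `edges`.

## Evaluation metrics

All metrics compare against ground truth on an explicit scope: the masked
entries when a mask plan is supplied, otherwise every non-missing entry
(the 0% regime). The aggregation orders matter and follow the reporting
conventions exactly:

* **CR** — per sample across its in-scope SNPs, then the unweighted mean
  over samples. This differs from the pooled fraction whenever samples
  have unequal in-scope counts, and the tests construct such a case.
* **Hellinger score** — per (SNP, sample), `1 - H(P, Q)` where P is the
  point mass at the true genotype and Q the posterior renormalized over
  genotype channels; `H = sqrt(1 - sqrt(Q_true))` (the
  sqrt(1 - Bhattacharyya) convention, which gives the full [0, 1] range
  with disjoint point masses scoring 0). Aggregation: per-SNP mean (and
  separately min) across samples, then mean over SNPs. The min variant is
  a lower bound on imputation quality.
* **SEN score** — `1 - |d_true - d_imp| / 2` on scalar dosages (the
  per-entry granularity reduces the scaled Euclidean norm to a scaled
  absolute difference); aggregation as for Hellinger. Dosage is the
  expectation of the renormalized genotype posterior, in [0, 2].
* **IQS** — per SNP, Cohen's-kappa-style chance correction
  `(Po - Pc)/(1 - Pc)` from the truth-vs-call contingency table, then the
  mean over SNPs. When both margins concentrate on one class (Pc = 1)
  kappa is undefined; such SNPs score 1 if agreement is perfect and 0
  otherwise, and are flagged rather than dropped, because rare-variant
  behaviour is precisely where IQS earns its keep. Negative per-SNP kappas
  are reported as-is.
* **PCC** — per SNP, Pearson correlation between true genotypes and
  imputed dosages; zero-variance SNPs are excluded and counted.

The true genotype "distribution" is a point mass at the sequenced hard
call throughout — sequenced genotypes carry no posterior. Decoding a
posterior to hard calls takes the argmax over genotype channels, excluding
the missing channel by default (an imputer must output genotypes; a flag
retains the channel for diagnostics), with ties broken deterministically
toward the lower genotype class.

Why both CR and IQS: a majority-class guesser scores CR near 1 on rare
variants while learning nothing. The chance-corrected IQS stays near 0 in
that situation — the acceptance suite constructs a panel of MAF ~0.25%
SNPs where all-hom-ref calls achieve CR > 0.95 yet IQS < 0.1.

## The simulator

Real benchmark panels are external; the package instead ships a generator
whose outputs have the one property the imputer needs: local LD.

* `simulate_founders()` draws a per-SNP target alternate-allele frequency
  uniformly in `maf_range` and places `round(f * n_founders)` alternate
  alleles (clamped to [1, n_founders - 1]) at random founders. Count-based
  placement was chosen over Bernoulli draws with rejection because it
  guarantees the realized founder frequency lands in the target range (up
  to the rounding grid) and no column is monomorphic, with no retry loop.
* `simulate_mosaic()` copies founder haplotypes with a first-order Markov
  switch process: at each SNP the copied founder changes with probability
  `switch_rate` (uniformly to any founder). Low switch rates give long
  shared segments, hence high adjacent-SNP r-squared decaying with
  distance — the same qualitative LD decay a convolutional imputer
  exploits in real data. There is no mutation step, so offspring allele
  frequencies equal founder frequencies exactly (integer arithmetic),
  which the tests assert.
* `haplotypes_to_genotypes()` pairs consecutive haplotypes into diploid
  0/1/2 genotypes. Positions are 1-based consecutive integers; physical
  distance is proxied by SNP index.
* `simulate_yeast_panel()` emulates a two-strain haploid cross: each
  sample alternates between strain classes 1 and 2 in contiguous blocks of
  geometric length (mean `block_length`).

What the simulator does **not** emulate: coalescent genealogies,
recombination-rate maps, mutation, demographic structure, genotyping
error, or the heterogeneity of human cohorts. Default parameters
(20 founders, switch rate 0.02, MAF in [0.1, 0.5], 200 samples x 64 SNPs)
were chosen once as a realistic desk-scale stand-in for a strongly
LD-structured region; passing tests on these panels demonstrate that the
pipeline is correct and that the model learns LD structure, not that it
matches published accuracy on real cohorts — those depend on external
datasets and GPU-scale training.

## Experiment harness

`run_experiment()` reproduces the benchmark design: per repeat it derives
a seed, splits 64/16/20, masks all partitions at each ratio, trains every
mode under identical splits/masks/initialization, imputes the test split,
and scores it. Means and sample SDs (n-1 denominator) are tabulated per
(metric, ratio, mode) and the two modes are compared with a two-sided
paired t-test (pairing by shared seed; with n repeats, df = n - 1). Each
repeat re-derives everything — split, masks, initialization — from its own
seed. Degenerate zero-variance differences are flagged rather than
silently producing NaNs. No multiple-testing correction is applied across
cells; each p-value stands alone. `maf_stratified_experiment()` runs the
same design with every metric additionally restricted to each MAF bin
(bins computed on the unmasked full panel).

Failed cells are marked and skipped, never hidden: the grid is complete by
construction, and determinism of the whole grid under `base_seed` is
asserted in the tests.

## Problem sizes used in the tests

The shipped tests run entirely on simulated panels sized for a single CPU:
metric oracles on 20 x 30 instances; training fixtures of 16-80 samples x
16-64 SNPs; the reconstruction check at 64 x 64 for 50 epochs; the
imputation-gain check at 20% masking with 150 epochs x 3 seeds; the
convergence contrast at 30 epochs x 5 paired seeds; and the full 3-ratio x
2-mode x 2-repeat grid at 3 epochs for the determinism check. The
acceptance script trains the full 12-model grid on a 200 x 64 panel at 60
epochs. These sizes are the package's own choice of desk-scale experiment;
larger panels simply scale linearly in time and memory.

## Known limitations

* Reference-free imputation needs enough samples to learn from; very small
  cohorts will underperform reference-based tools by construction.
* The optimizer moves weights by roughly the learning rate per step, so
  few-sample panels (few batches per epoch) need correspondingly more
  epochs to converge than large panels at the same epoch count.
* Determinism is guaranteed per platform/BLAS-threading configuration, not
  across platforms.
* Haploid mode reports CR, Hellinger and IQS; dosage-based metrics
  (SEN, PCC) are defined for diploid posteriors only.
* VCF support covers biallelic SNPs with GT fields; genotype likelihoods,
  indels and multiallelic splitting are out of scope.
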