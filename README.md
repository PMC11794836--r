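# karyodetect

Semi-supervised detection and localization of structural chromosome
abnormalities — deletions and reciprocal translocations — in
single-chromosome (singlet) Giemsa-banded images.

Clinical karyotype archives hold abundant normal chromosome images but
few labeled abnormal ones. `karyodetect` exploits that asymmetry with a
hybrid model:

1. **Unsupervised stage.** A convolutional autoencoder (three conv
   layers, 16/32/64 filters, LeakyReLU; mirrored decoder with 64/32/16
   filters, ReLU) is pretrained on unlabeled *normal* images with mean
   squared reconstruction error
   `MSE = (1/n) Σᵢ (yᵢ − ŷᵢ)²`. Because the encoder only ever sees
   normal banding, anomalous inputs reconstruct poorly; errors above
   `μ + k·σ` of the normal validation errors flag anomalies.
2. **Supervised stage.** A small classifier head is trained on the
   frozen encoder's latent features (plus the unsupervised
   reconstruction-error score) with cross-entropy, then the last two
   encoder layers are fine-tuned jointly with the head under
   class-weighted cross-entropy (Adam, lr 1e-4, 20 epochs, batch 20).
3. **Localization.** Chromosomes flagged abnormal are compared against
   a class-matched normal reference with the windowed structural
   similarity index,
   `SSIM = (2μxμy + c₁)(2σxy + c₂) / ((μx² + μy² + c₁)(σx² + σy² + c₂))`,
   the largest low-similarity region is cropped and template-matched by
   normalized cross-correlation against a candidate donor chromosome:
   a high peak identifies translocated material and its donor class;
   a low peak reports a deletion-like change.

Real clinical image sets of this kind are proprietary, so the package
includes a synthetic banded-chromosome generator (24 class-specific
band patterns, seeded noise, ground-truth deletion/translocation
annotations) that emulates the statistical shape of such a corpus at
desk scale. Every stage of the pipeline is developed and tested against
it; see the methods vignette (`vignettes/karyodetect-methods.Rmd`) for
what the generator does and does not emulate.

## Worked example

```r
library(karyodetect)

# a seeded synthetic dataset: 2,000 unlabeled normals for pretraining,
# 600 labeled (23% abnormal), 200 validation, 200 test (8.5% abnormal)
split <- make_split(split_config(), seed = 1)

# pretrain -> frozen head -> fine-tune (about 7 minutes on one CPU)
model <- karyo_fit(split, seed = 11)

pred <- predict(model, split$test)
report <- evaluation_report(
  vapply(split$test, function(im) im$is_abnormal, logical(1)),
  pred$abnormal, pred$score)
print(report)
#> Evaluation (positive class: abnormal)
#>           predicted
#> truth      positive negative
#>   positive       15        2
#>   negative        0      183
#>           Normal % Abnormal %
#> Accuracy  99.00    99.00
#> Precision 98.92    100.00
#> Recall    100.00   88.24
#> F1 score  99.46    93.75
#> AUC: 0.9582
```

Of the 17 truly abnormal test chromosomes, 15 are flagged with no false
alarms; the abnormality score ranks abnormal above normal with ROC AUC
0.96. Localizing a zero-noise der(9) translocation fixture then
recovers the donor:

```r
ders <- apply_translocation(canonical_pattern(9), canonical_pattern(22), 5, 3)
der9 <- standardize(render_chromosome(ders$der_a, noise_sd = 0))
ref  <- function(cl) standardize(render_chromosome(canonical_pattern(cl), noise_sd = 0))
localize_translocation(der9, ref(9), ref(22))
#> <localization_report> translocated
#>   region rows 22 - 32 cols 1 - 32 (area 94 windows)
#>   partner match: score 1 at row 19 col 7 | donor class 22
```

The low-similarity region sits over the exchanged distal segment, and
the crop matches chromosome 22's reference exactly (correlation 1 at
zero noise) — the segment came from chromosome 22.

The whole pipeline is also scriptable:

```sh
Rscript inst/cli/karyodetect.R run-all --seed 7 --out run/
```

which writes split manifests, per-stage loss logs, checkpoints, the
evaluation report (JSON/CSV, with ROC points), localization reports,
and a provenance file.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's end-to-end computation from scratch under the
given seed — generating the default synthetic splits, training all
stages, evaluating on the held-out test split, and localizing flagged
anomalies — leaving the run artifacts next to the output file.
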