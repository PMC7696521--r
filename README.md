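# deepasym

EEG-based pre-screening of major depressive disorder (MDD) from
hemispheric band-power asymmetry. `deepasym` converts multi-channel EEG
recordings into per-band 16×16 pairwise asymmetry matrices, renders them
as 64×64 RGB images, and classifies them with a compact three-layer
convolutional neural network under k-fold cross-validation. It is aimed
at EEG/neuroinformatics researchers who want a transparent, fully seeded
reference implementation of the asymmetry-image representation — including
an EDF reader/writer, Welch/Simpson spectral estimation, a synthetic EEG
generator with controllable hemispheric alpha asymmetry, and
confusion-matrix/ROC evaluation.

## The method

For channels *ch₁*, *ch₂* with relative band powers *Rp₁*, *Rp₂*, the
asymmetry score is

    A(ch1, ch2) = (Rp1 − Rp2) / (Rp1 + Rp2)  ∈ [−1, 1]

where relative power is the Simpson-integrated Welch PSD over the analysis
band (delta 0.5–4, theta 4–8, alpha 8–13 or beta 13–30 Hz) divided by the
integral over 0.5–30 Hz. Scores over all pairs of the 16 lateral 10–20
channels (Fp1, F3, C3, P3, O1, F7, T3, T5, Fp2, F4, C4, P4, O2, F8, T4,
T6) form an antisymmetric 16×16 matrix, colorized with a fixed diverging
map (−1 blue, 0 green, +1 red) and block-replicated to a 64×64×3 image.
The classifier is a 1,273,537-parameter CNN — three valid-padding 3×3
convolution blocks (32/64/128 filters, ReLU, 2×2 max-pool, batch norm
after the first pool), a 256-unit dense layer with dropout, and a sigmoid
output — trained with Adam (lr 1e-4) on binary cross-entropy for 10 epochs
of mini-batches of 32. See the vignette in `vignettes/deep-asymmetry.Rmd`
for the full model description and design rationale.

## Worked example

Simulate a two-group dataset with a 3× left-hemisphere alpha boost in the
MDD-like group, run the full pipeline, and cross-validate:

```r
library(deepasym)

spec <- synth_spec(n_subjects_per_group = 5, duration = 300,
                   asymmetry_effect = 3, seed = 11)
imgs <- make_benchmark(spec)          # 10 subjects x 75 epochs = 750 images
report <- cross_validate(imgs, cnn_config(seed = 7), k = 5, mode = "epoch")
print(report)
```

```
<cv_report> 5-fold, epoch-level split, seed 7
 fold n_test accuracy sensitivity specificity auc
    1    150      100         100         100   1
    2    150      100         100         100   1
    3    150      100         100         100   1
    4    150      100         100         100   1
    5    150      100         100         100   1
means: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, AUC 1.0000
note: epoch-level folds: epochs of one subject may appear in both training and test sets
```

With this strong injected effect the per-epoch alpha images are linearly
separated by hemisphere and the network classifies every held-out epoch
correctly; shuffling the labels (a permutation null) drops mean accuracy
to ~48 % and AUC to ~0.46, confirming the signal is carried by the labels
and not by the pipeline. Sensitivity is the true-positive rate over
MDD-like subjects' epochs, specificity over controls; the leakage note
reminds you that epoch-level splits share subjects across folds — use
`mode = "subject"` for subject-level generalization.

A command-line wrapper ships in `exec/`:

```sh
deepasym simulate --n 5 --effect 2.0 --seed 7 --outdir sim/
deepasym evaluate --edfdir sim/ --band alpha --k 5 --seed 7 --out report.json
```

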