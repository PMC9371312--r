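# ctgnet

Joint lesion segmentation and image classification for breast ultrasound
(BUS) with a **cross-task guided network**: instead of merely sharing an
encoder, the two tasks exchange *attention soft masks*. The coarse
three-tissue segmentation gates the classifier's features (lesion
attention module, LAM); the classifier's per-class features and scores
shape the fine segmentation (category selection module, CSM); and a
gland-masked self-attention block (anatomical knowledge guidance module,
AKGM) encodes the prior that breast lesions arise in the mammary-gland
layer. Everything — forward passes, analytic backpropagation, Adam,
dynamic loss balancing — is implemented in this package (R with compiled
kernels), and the whole pipeline is exercised on seeded synthetic
ultrasound phantoms, so no clinical data are required to test it.

## The model in brief

One grayscale image `I` flows through four units:

```
F'      = ASPP(encoder(I))                          shared features, stride 8
M       = softmax(coarse_decoder(F'))               soft masks (M_l, M_m, M_b)
F_LAM   = F' + F' * M_m + F' * M_l                  lesion attention
G, H    = FC(GAP(F_LAM)), softmax(...)              per-class features, scores
F_CSM   = [conv(G) * H^T] conv(F')                  category attention
F_AKGM  = alpha * (V S^T) + F',  S = softmax(Q'^T K'),  Q' = Q * M_m, K' = K * M_m
fine    = softmax(fine_decoder([F_CSM; F_AKGM]))    final lesion mask
```

Training minimises `lambda_1 * L_cls + lambda_2 * (L_cseg + L_fseg)` —
cross-entropy plus two soft Dice losses — with the task weights set each
epoch by dynamic weight averaging at temperature 2 (`lambda_1 +
lambda_2 = 2` always), Adam, and early stopping on the validation loss.
The attention masks are never detached, so gradients genuinely cross
between tasks. The methods vignette
(`vignettes/ctgnet-methods.Rmd`) documents every design choice the
architecture description leaves open.

## Worked example

```r
library(ctgnet)

# seeded synthetic BUS phantoms: layered anatomy, hypoechoic lesions in
# the gland band, multiplicative speckle
pcfg  <- phantom_config(seed = 1)              # 64x64, binary labels
train <- generate_dataset(pcfg, 200)
val   <- generate_dataset(pcfg, 24,  start_index = 200)
test  <- generate_dataset(pcfg, 50,  start_index = 224)

fit <- ctgnet_fit(train, val, config = ctg_config(desk_profile = TRUE),
                  seed = 1)
print(fit)
ev <- evaluate_model(fit, test)
round(ev$summary[, c("dsc", "ji", "tpr", "acc", "auc")], 3)
```

```
Cross-task guided network fit
  image 64x64, 2 classes, lightweight encoder, D=32
  epochs run: 20 (best validation epoch: 16)
  final losses: cls 0.0003, coarse 0.0393, fine 0.0546
    dsc    ji   tpr acc auc
1 0.937 0.891 0.955   1   1
```

`dsc`/`ji`/`tpr` are the per-image mean Dice coefficient, Jaccard index
and true-positive rate of the fine lesion mask against the ground truth;
`acc`/`auc` are pooled classification accuracy and the area under the
ROC curve for normal-vs-lesion. On these phantoms the desk-scale network
localises lesions with a mean Dice above 0.9 and classifies essentially
perfectly — the phantoms validate the implementation and learnability,
not clinical performance.

Single images can be pushed through the units directly
(`extract_shared_features()`, `coarse_segment()`, `lam()`, `classify()`,
`csm()`, `akgm()`, `fine_segment()`), and a fitted model supports
`predict()`, `plot()` (training curves), `coef()`, `simulate()` and
`residuals()`.

A thin command-line wrapper is installed at `inst/cli/ctgnet.R`
(`generate`, `train`, `evaluate`, `predict`, `run` subcommands, YAML
configs under `inst/configs/` including the desk experiment and the
LAM/CSM/AKGM ablation wirings).

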