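# florafusion

Classify flower specimens — medicinal chrysanthemum cultivars are the
motivating case — from **paired photographs of the front and the back of the
inflorescence**. Many cultivars look alike from the front (ray floret shape
and colour) but differ on the back (calyx, bracts, receptacle), and vice
versa, so neither view alone identifies every cultivar. florafusion
implements a two-stream residual convolutional network that fuses both views,
for researchers and practitioners in plant phenotyping who need fast,
non-invasive cultivar and origin identification.

## The model

Each view is processed by a 17-convolution residual backbone (7×7/2 stem,
3×3/2 max pool, four stages of two basic blocks, global average pooling).
For a 224×224×3 input the feature sizes run
112²×64 → 56²×64 → 56²×64 → 28²×128 → 14²×256 → 7²×512 → 1²×512.
A standard residual block updates

    x_{l+1} = h(x_l) + F(x_l, W_l),

with identity (or 1×1-projection) shortcut `h` and residual transform `F`.
In the final 512-channel stage the two streams exchange information through
**cross-stream residual connections**: for stream `p` (front or back) with
counterpart `q`,

    x_{l+1}^p = h(x_l^p) + h(x_l^q) + F(x_l^p, W_l^p),

both streams updated synchronously. Each stream then runs a fully connected
chain 512 → 128 → 32 whose layer inputs are fused by an asymmetric weighted
sum,

    y_{l+1}^p = G_p(y_l^p + α · y_l^q),   α = 1/3 by default,

and the two 32-d vectors are concatenated (64-d) into a joint classifier.
Training is staged: the shallow 13 convolutional layers (transferable from
ImageNet weights) are frozen for a first phase, then everything is
fine-tuned at a lower rate; Adam, cross-entropy, batch 24; evaluation uses
stratified 6:2:2 splits repeated with fresh seeds, reporting accuracy, macro
recall, macro F1, the population SD of per-class recall (stability across
classes), parameter count and average inference time.

Because no photographic dataset ships with the package, a procedural
generator draws paired flower images whose class cues are deliberately
split between the views (petal count/hue/centre radius on the front; calyx
ring count/hue/bract spokes on the back), with enumerable single-view Bayes
bounds — so the value of fusing the views is testable end to end.

## Worked example

```r
library(florafusion)

man <- generateDataset(SynthSpec(seed = 1), "demo")   # 6 classes x 20 pairs
man
#> DatasetManifest: 120 pairs, 6 classes
#>   classes: class01, class02, class03, class04, class05, class06

bayesSeparability(SynthSpec(seed = 1))
#> $front 0.667   $back 0.667   $joint 1
# either view alone can identify at most 2/3 of samples; both views identify all

res <- runRepeatedExperiment(man, fastModelSpec(),
                             ExperimentProtocol(nRepeats = 1L, seed = 9L))
res$report
#> EvalReport: acc 1.000, macro recall 1.000, macro F1 1.000, class STD 0.00 pp
#>   params 358,422; AIT not measured
```

On this split the fused model resolves all 24 test pairs, above the 66.7 %
single-view ceiling — the fusion is doing the work. Over three repeated
splits the fused model averages ~92 % while front-only and back-only models
stay near their ~60–67 % bounds (see below). The same pipeline runs from the
shell via `inst/scripts/florafusion` with the commands `synth`, `train`,
`eval`, `ablate` (the eight-variant fusion ablation grid) and `viz`
(gradient-weighted class activation maps and a t-SNE embedding of the fused
64-d features).

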