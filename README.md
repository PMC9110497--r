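# desmokr

Electrocautery smoke obscures the camera view in robot-assisted
laparoscopic surgery, and no paired (smoky / smoke-free) ground truth can
be captured in vivo. **desmokr** removes smoke from laparoscopic frames
by *unpaired* image-to-image translation: two cycle-coupled ResNet
generators (`G`: clear→hazy, `F`: hazy→clear) and two PatchGAN
discriminators trained with a least-squares adversarial objective, a
cycle-consistency loss, and two smoke-aware priors evaluated on the
generated images:

```
L = L_GAN + λ_cyc · L_cyc + α · L_IC + β · L_DC        (α = 3, β = 0.05, λ_cyc = 10)
```

* **Inter-channel discrepancy (IC)** — dense grey smoke is nearly
  achromatic, so Ψ(P) = |P_R−P_G| + |P_G−P_B| + |P_B−P_R| collapses under
  smoke; its image mean, normalised to [0, 1], is mapped through the
  boundary value 1 with a direction-dependent branch so residual smoke in
  the desmoked image costs most.
* **Dark channel prior (DC)** — the patch-wise channel minimum
  I^dark(x) = min_{y∈Ω(x)} min_c I^c(y) is near zero for haze-free tissue
  and lifted by haze; the loss is its trimmed mean (1 % per tail) over
  each generated image, with an optional soft-matting (matting Laplacian)
  refinement for reported values.

The package also ships a scattering-model smoke simulator
(I = J·t + A·(1−t), graded light / medium / heavy / partial smoke over
procedural tissue phantoms) so the whole method is testable at desk
scale, and referenceless evaluation metrics: JNBM perceptual sharpness,
the REA newly-visible-edge rate, and a documented dark-channel fog-density
proxy. The convolutional networks and their backward passes are
implemented in the package (RcppArmadillo im2col/GEMM kernels) and are
verified against finite differences in the test suite.

## Worked example

```r
library(desmokr)

# 1. simulate an unpaired clear/hazy dataset (8 images per domain, 64 px)
root <- tempfile("smoke")
make_dataset(8, 64, c(light = 0.25, medium = 0.25, heavy = 0.25,
                      partial = 0.25), seed = 7, out_dir = root)

# 2. train a small model for two epochs
cfg <- train_config(epochs_const = 1, epochs_decay = 1, batch_size = 2,
                    crop = 64, seed = 7,
                    gen_spec = generator_spec(2, 8),
                    disc_spec = discriminator_spec(2, 12))
ck <- fit(cfg, root, file.path(root, "run"), verbose = FALSE)

# 3. desmoke a held-out hazy frame and measure its dark channel
y <- load_image(list.files(file.path(root, "testB"), full.names = TRUE)[1])
out <- translate(tail(ck, 1), y, "hazy_to_clear")
trimmed_mean(as.numeric(dark_channel(y, 7)), 0.01)
#> [1] 0.2162077
trimmed_mean(as.numeric(dark_channel(out, 7)), 0.01)
#> [1] 0.06064536
```

The two numbers are the trimmed-mean dark channel of the hazy input and
of its translation: the desmoked frame's dark channel drops towards the
near-zero level of clear tissue, which is exactly what the DC loss
optimises. (Two epochs only begin the job; the package's validation
experiment below trains ten.)

A command-line wrapper around the same four workflows is installed as
`exec/desmokr`:

```sh
Rscript exec/desmokr simulate --n 80 --size 64 --seed 7 --out data/
Rscript exec/desmokr train --config run.yaml
Rscript exec/desmokr translate --checkpoint ck.rds --input data/testB --out desmoked/
Rscript exec/desmokr evaluate --images desmoked/ --reference data/testB --report report.csv
```

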