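# ganrecon

Modular tissue classification by per-class generative reconstruction.

## The problem

Segmenting tumor bulk from surrounding stroma on H&E-stained histology
slides is usually cast as discriminative classification: one network is
trained on tiles of *all* classes and must be retrained whenever a class is
added, removed, or rebalanced. `ganrecon` implements the alternative,
model-per-class approach: one **conditional GAN is trained per tissue
class** to reconstruct H&E-like tiles from their **channel-wise Canny edge
maps**, and an unseen tile is classified by which class generator
reconstructs it best.

For a tile x with edge condition y, each class c has a generator G_c trained
on that class alone with the pix2pix-style objective

    min_G max_D  E[log D(x|y)] + E[log(1 - D(G(y)|y))]  +  λ · MSE(G(y), x)

(non-saturating generator term in practice; λ = 100 by default). At
inference the tile is classified by the winner rule

    label(x) = argmin_c  d( x, G_c(y) ),    d = MSE (or 1-SSIM, 200-PSNR)

Because the condition is a 3-channel *binary* edge mask — channel i holds
the Canny edges of color channel i — all color is drained from the input and
each generator must hallucinate its own class's appearance back onto the
structure. A generator asked to reconstruct a tile of a foreign class paints
the wrong textures and colors, and loses the arg-min.

Since every model sees exactly one class, classes can be **added or removed
without touching the other models**, and class imbalance is irrelevant to
training. The package also provides the surrounding workflow: stereology
grid sampling of tiles from annotated images, high-power-field (HPF)
classification by majority vote over 50 random windows, grouped k-fold
evaluation with precision/sensitivity/F1, and a seeded synthetic-texture
generator (nucleus-like blobs vs. wavy fibers) so everything is testable
without slide data.

## Worked example

```r
library(ganrecon)

specs <- default_texture_specs()          # "tumorlike" and "stromalike"
ep    <- edge_params(sigma = 2)           # the sigma_2 conditioning preset

reg <- model_registry()
for (nm in names(specs)) {
  tiles <- generate_tiles(specs[[nm]], n = 200, tile_size = 64)
  cfg   <- training_config(epochs = 5, batch_size = 1,
                           learning_rate = 2e-3,
                           seed = if (nm == "tumorlike") 101 else 102)
  reg <- add_class(reg, train_class_model(tiles, ep, cfg = cfg))
}

tile <- generate_tiles(specs$tumorlike, 201, 64)[[201]]   # held out
r <- classify_tile(reg, tile)
round(r$per_class_errors, 2)
```

On this run the classifier printed:

```
stromalike  tumorlike
   1276.49     424.01
```

with `r$predicted_label == "tumorlike"`. Both generators attempted the
reconstruction; the tumorlike generator's MSE (424) is well below the
stromalike generator's (1276), so the tile is labeled `tumorlike`. Across
120 held-out tiles this configuration reached a tile-level F1 of 100, and
majority voting over 50 windows classified 10 of 10 homogeneous synthetic
HPFs correctly.

A region-level call works the same way:

```r
hpf <- generate_hpf(specs["tumorlike"], c(160, 160), seed = 9)
classify_hpf(reg, hpf$pixels, n_windows = 50, seed = 1)$predicted_label
#> [1] "tumorlike"
```

A thin command-line wrapper over these functions ships at
`inst/cli/ganrecon.R` (subcommands `simulate`, `edges`, `sample`, `train`,
`registry`, `classify`, `run`).

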