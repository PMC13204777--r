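# msod — fly-inspired detection of small moving objects in video

`msod` detects small moving objects (a few pixels across) against
cluttered, *moving* backgrounds, using a four-stage computational model of
the Drosophila visual pathway. It is written for researchers in
bio-inspired vision and small-target detection who want a complete,
deterministic, testable implementation of the circuit — including a seeded
synthetic stimulus generator and an evaluation suite — rather than a
black-box detector.

## The model

Four stages transform a gray frame sequence `L(x, y, t)`:

1. **Retina** — Gaussian blur: `P = L * G_σ1`.
2. **Lamina** — temporal band-pass
   `H(t) = (n2! t^n1 − n1! t^n2) e^(−t) / (n1! n2!)` (zero net area,
   `H(0) = 0`), spatio-temporal lateral inhibition with the separable
   kernel `W_I = [DoG]⁺·W_TP + [DoG]⁻·W_TN`, then half-wave rectification
   into ON and OFF channels. A parallel amacrine/T1 branch computes local
   contrast `T1` = annulus mean − centre mean over 31×31 / 11×11 windows.
3. **Medulla & lobula** — second-order inhibition
   `W1 = A·[DoG]⁺ + B·[DoG]⁻` (net-inhibitory, the origin of small-size
   selectivity), gamma-kernel delays `Γ_{n,τ}`, and a feedback
   Hassenstein–Reichardt correlator:
   `LC11 = (Tm3 + kF₁)(Tm1 + kF₁) − (Tm2 + kF₂)(Mi1 + kF₂)`,
   the model's small-object-selective response.
4. **Mushroom body** — thresholded LC11 maxima are linked into
   trajectories; the running standard deviation of `T1` sampled along each
   trajectory separates genuine movers (contrast varies as they cross the
   background) from background-locked pseudo-objects (contrast constant,
   SD ≈ 0), which are rejected.

Parameter defaults (σ1 = 1; n1, n2 = 1, 6; σ2, σ3 = 1.5, 2.0;
λ1, λ2 = 3, 9; Ψ, Π = 11×11, 31×31; A, B = 1, 3; n3, τ3 = 5, 25;
n4, τ4 = 10, 25; k = 0.01; Th = 0.2; Th2 = 4.0) are exposed through
`msod_params()`. The methods vignette
(`vignettes/msod-methods.Rmd`) explains the discretization decisions —
frame-calibrated band-pass, millisecond delay constants, one-frame
correlator latency — that make these constants work together on a 30 FPS
frame grid.

## Worked example

```r
library(msod)

scene <- baseline_scene(seed = 1)   # 500x250 px, 30 FPS, 21 frames:
seq1  <- render_sequence(scene)     # drifting panorama, 3 pseudo-objects,
seq1$frames                         # 1 independent 5x5 dark mover
#> <msod frames: 500 x 250 px, 21 frames @ 30 FPS, range [0, 255]>

result <- msod_detect(seq1$frames)
result
#> <msod result: 500 x 250 px, 21 frames>
#>   83 detections in 8 trajectories; 21 confirmed points in 5 trajectories

evaluate_detections(result, seq1$truth) |>
  glance() |>
  dplyr::select(dr, pr, rc, f1, vn_raw, vn, n_pseudo_confirmed)
#> # A tibble: 1 × 7
#>      dr    pr    rc    f1 vn_raw    vn n_pseudo_confirmed
#>   <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>              <int>
#> 1     1   0.8     1 0.889   70.5    20                  0
```

Reading the numbers: the confirmed output finds the true mover in every
evaluated frame (`dr = 1`) with pixel-level F1 of 0.89; none of the three
background-locked pseudo-objects is confirmed (`n_pseudo_confirmed = 0`);
and the fraction of response energy off target drops from 70.5% in the raw
LC11 map (`vn_raw`, which still responds to the pseudo-objects) to 20% in
the confirmed output (`vn`) — the false-positive suppression the
mushroom-body stage exists for.

```r
tidy(result)          # per-detection tibble: frame, x, y, trajectory, ct, sd_ct, confirmed
autoplot(result)      # trajectories in the image plane
plot_contrast_sd(result)  # contrast-SD growth: movers climb, pseudos stay flat
```

A thin command-line front end over the same functions lives in
`inst/cli/msod.R` (`simulate`, `detect`, `eval`, `sweep` subcommands).

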