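# organoidval

Small bright-field brain-organoid image collections (often only a few tens
of acquisitions) are too small to train robust deep-learning analysis
tools. One remedy is generative augmentation: train an adversarial
autoencoder (AAE) on the originals and synthesize new images. But when are
the synthetic images good enough? `organoidval` implements a three-way
validation of AAE-generated organoid images:

1. **Similarity/quality metrics** — a seven-metric suite (FID on
   pixel-statistic features, global SSIM, the universal quality index UQI,
   normalized mutual information, MSE, PSNR, and a predictive-residue blur
   index), aggregated by the 40 × 40 cross-pair protocol with an
   original-vs-original reference range per metric.
2. **Psychovisual evaluation** — expert real-vs-generated decisions are
   reduced to per-group confusion counts (TP/FN for originals, FP/TN for
   synthetic), error and positive rates `ER_G = FP/(FP+TN)`,
   `PR_O = TP/(TP+FN)`, time-weighted normalized error rates
   `NER_G = FP·t_FP/(FP+TN)`, decision-time summaries, vote histograms,
   and a routed statistical test battery (Shapiro → Bartlett/Levene →
   ANOVA+Tukey or Kruskal–Wallis+Holm).
3. **Metric–decision concordance** — all 2⁶ − 1 = 63 combinations of the
   six per-image metrics are reduced to a single feature
   (standardize + first principal component), group feature histograms are
   compared by KL divergence, and combination scores are correlated
   (Pearson, Kendall) with NER and decision time to rank the ten best
   proxies for the human decision.

A segmentation stage closes the loop: training sets of 80 images mix the
originals with classical augmentations and with synthetic images validated
by at least *k* experts, a pluggable segmenter is evaluated by
leave-one-out over the originals only, and predicted masks are scored by
Dice, accuracy, sensitivity, specificity, precision and F1, with FP/FN
color overlays.

Everything is testable without external data: `make_dataset()` renders
organoid-like scenes (ovoid body, textured neuroepithelial rim,
dispersed-cell halo, light-to-dark gradient background, optional
artifacts/blur/noise) with exact ground-truth masks, and
`simulate_experts()` generates decision records from configurable
per-group false-positive probabilities and lognormal decision-time models.

The AAE supports six discriminator/reconstruction losses: BCE, BCE + α·L1
(α = 10⁻⁴), least squares, Poisson (ε = 0.25), Wasserstein (exact 1-D
sorted-sample transport), and the perceptual Wasserstein variant with
squared ground distance.

## Worked example

```r
library(organoidval)
library(dplyr)

originals <- make_dataset(8, default_params_sampler(c(64, 64)), seed = 1)
model <- train_aae(originals, loss_spec("P_WASS"),
                   train_config(epochs = 200, image_size = 64, seed = 1))
glance(model)
#>   loss   epochs n_train initial_mse final_mse final_loss
#> 1 P_WASS    200       8      0.0368    0.0278 0.00000673

synthetic <- synthesize(model, 8, seed = 1)
rep_tbl <- group_report(bind_rows(originals, synthetic))
rep_tbl |> filter(metric %in% c("fid", "ssim", "blur"))
#>   metric    group statistic        value
#> 1   ssim original range_min 6.770334e-01
#> 2   ssim original range_max 9.492081e-01
#> 3   ssim   P_WASS      mean 2.213344e-02
#> 4   blur original range_min 1.109007e+01
#> 5   blur original range_max 9.841516e+01
#> 6   blur   P_WASS      mean 4.953127e+03
#> 7    fid original range_min 3.066876e-01
#> 8    fid original range_max 3.066876e-01
#> 9    fid   P_WASS      mean 2.224956e+00
```

Reading the output: training cut the reconstruction MSE by ~25% at this
desk scale, but the synthesized images still fall outside the original
SSIM range (0.68–0.95) and far above the original blur range — the metric
report is doing its job of flagging a generator that has not yet converged
(200 epochs at 64×64 versus the 2,000-epoch full-scale profile).

The psychovisual side runs off the same tibbles:

```r
panel <- default_expert_panel(8, seed = 2)
imgs <- bind_rows(originals[, c("id", "group")], synthetic[, c("id", "group")])
recs <- simulate_experts(imgs, panel, seed = 3)
error_rates(label_decisions(recs))
#>   group        er er_original er_generated positive_rate
#> 1 P_WASS   0.75         NaN          0.75          0.75
#> 2 original 0.0781       0.0781       NaN           0.922
```

Here the simulated panel (whose perceptual-Wasserstein false-positive
probability is centred on 0.62) called 75% of this particular synthetic
batch "real", while crediting 92% of originals as real — the two rates the
study design compares. `ner_by_group()`, `votes_histogram()`,
`correlate_combinations()` and `leave_one_out()` continue the pipeline;
see the methods vignette.

A thin CLI over the same functions lives at `inst/cli/organoidval.R`
(subcommands `simulate`, `train`, `metrics`, `psy`, `concord`, `segeval`).

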