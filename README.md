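# hemofuse

Desk-scale multimodal image–text fusion for intracranial hemorrhage (IH),
entirely on synthetic data. The package re-builds, in plain R, a pipeline
that couples brain-slice image analysis with clinical narratives:

- **Synthetic cohort generator** — elliptical brain phantoms with skull,
  tissue noise and ventricles; subtype-specific lesions (ICH blob with
  edema halo, SDH crescent, EDH biconvex lens, IVH clipped to the
  ventricles, SAH rim); five-frame temporal progression
  (expand → resorb, hyperdense → hypodense); templated consultation /
  progression / procedural / radiology notes; deterministic sentiment and
  risk labels; and a split manifest with 10-images-per-case bookkeeping.
- **M-CLAHE enhancement** — tile histograms with entropy-derived clip
  limits (normalized entropy mapped affinely onto clip multiples of the
  uniform bin height), exact-mass clip-and-redistribute, CDF-min LUTs,
  bilinear blending of the four neighboring tile LUTs, gamma correction
  (default γ = 1.25) and unsharp sharpening, plus a plain-CLAHE /
  Laplacian comparison harness.
- **Toy encoders** — a ViT skeleton (patchify, shared projection,
  per-vector standardization, CLS + positions, multi-head self-attention)
  and a WordPiece tokenizer with token+segment+position embedding tables,
  both seeded and frozen; a pufferfish-style metaheuristic selects the
  patch size over a discrete candidate set.
- **Fusion and classification** — cross-attention (text queries, image
  keys/values, row-stochastic weights) whose fused vector concatenates
  attended values, pooled queries and both modality vectors in one shared
  space; early/late fusion baselines; single-hidden-layer heads trained
  by full-batch gradient descent for subtype, prognosis-sentiment and
  therapeutic-sentiment classification.
- **Metrics and reports** — PSNR, SSIM, RMS contrast, Shannon entropy,
  accuracy/precision/recall/F1 from confusion counts, ROC/AUC and PR
  curves; structured prognosis/therapeutic sentiment reports with the
  subtype→dementia-risk map (ICH High, SDH Moderate, EDH Low, IVH
  Moderate to High, SAH Moderate) and the Estimated Association statistic
  `EA = 100 · complex words / total words`.

Everything is deterministic under a single run seed and runs on one CPU;
there is no external dataset, no GPU and no pretrained weights.

## Worked example

```r
library(hemofuse)

ph <- generate_phantom(phantom_spec(seed = 7))
lesioned <- render_lesion(ph, lesion_spec("SDH", c(10, 32), 8, 85))
sum(lesioned$lesion_mask)            # 97 px crescent along the inner skull

res <- enhance_mclahe(lesioned$pixels)
res$gamma_used                       # 1.25
compare_methods(lesioned$pixels)[, c("method", "psnr_db", "ssim")]
#>      method psnr_db   ssim
#> 1    mCLAHE   12.07 0.6172
#> 2     CLAHE   10.21 0.6978
#> 3 Laplacian   16.34 0.6016

frames <- simulate_progression(ph, lesion_spec("SDH", c(10, 32), 8, 85),
                               progression_params())
sapply(frames, function(f) sum(f$lesion_mask))
#> 97 166 272 138 71        # unimodal: growth to frame 2, then resorption

assign_labels(lesion_spec("SDH", c(10, 32), 8, 85),
              progression_params(), ph)[1:3]
#> prognosis "positive", therapeutic "positive", risk "Moderate"
```

The lesion area peaks at frame 2 and ends below its initial value, so the
area rules label the case prognosis-positive; the shrink factor < 1 makes
the therapeutic sentiment positive; SDH maps to Moderate dementia risk.
The generated radiology note embeds exactly these facts ("subdural
hemorrhage", "risk category : moderate", "the lesion enlarged ... and
partially resorbed") plus positive-lexicon phrases, and
`lexicon_sentiment()` recovers the positive polarity.

The full benchmark — 525 balanced synthetic cases, all fusion
strategies — is one call:

```r
bench <- run_benchmark(seed = 1)
round(100 * bench$subtype_test_accuracy)
#> joint 98   late 96   early 99   image_only 85   text_only 88
```

Joint fusion beats both single-modality baselines because the generator
plants complementary signal: SDH/SAH share the risk wording (text-blind
pair) but differ in geometry, while SDH/EDH look alike at coarse
resolution but differ in risk wording.

## Package layout

| Path | Contents |
| --- | --- |
| `R/phantom.R`, `R/lesion.R` | phantom spec/rendering, subtype lesion geometry |
| `R/progression_select.R`, `R/manifest.R`, `R/notes.R` | temporal simulation, labels, manifest, note templates |
| `R/enhance.R` | M-CLAHE and the method-comparison harness |
| `R/metrics.R` | image-quality and classification metrics |
| `R/vision_embed.R`, `R/poa.R` | toy ViT and the patch-size optimizer |
| `R/text_embed.R`, `R/lexicon.R` | WordPiece, embedding tables, lexicons, EA |
| `R/fusion.R` | cross-attention, fusion strategies, training, evaluation |
| `R/report.R` | risk map, sentiment reports, pipeline runner |
| `vignettes/hemofuse-methods.Rmd` | model assumptions, conventions, design rationale |
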