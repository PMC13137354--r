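---
title: "Methods: desk-scale multimodal hemorrhage image-text fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale multimodal hemorrhage image-text fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package models

`hemofuse` is a desk-scale, fully synthetic re-implementation of a
multimodal pipeline for intracranial hemorrhage (IH): grayscale brain
slices are contrast-enhanced with an entropy-adaptive variant of CLAHE,
a parametric simulator produces five-frame temporal sequences of a
growing-then-resorbing hematoma, templated clinical narratives are
generated per case, toy vision-transformer and WordPiece text encoders
embed both modalities, a cross-attention module fuses them, and
single-hidden-layer heads classify hemorrhage subtype plus prognosis and
therapeutic sentiment, feeding a structured report. Every stage runs in
seconds to minutes on one CPU with no external data, which makes the whole
chain testable end to end.

The five subtypes follow the compartment taxonomy: ICH (intraparenchymal
blob), SDH (crescent along the inner skull), EDH (biconvex lens at the
skull), IVH (blood inside the ventricles) and SAH (a thin diffuse rim
along the brain boundary). SAH geometry is our own rendering choice: the
class is named in the source taxonomy but its appearance is never
specified beyond "diffuse". The dementia-risk map is fixed:
ICH→High, SDH→Moderate, EDH→Low, IVH→Moderate to High, and SAH→Moderate
as a documented extension.

## Synthetic data: what it emulates and what it does not

A phantom is an ellipse of noisy tissue (default 64×64 px, mean intensity
~120, Gaussian noise sd 8) inside a bright skull ring with two dark
ventricles. Lesions are intensity offsets (default +70..+95, acute blood
being hyperdense) on subtype-specific masks; ICH lesions get a soft edema
halo at a third of the offset. The temporal model multiplies the lesion
radius by a growth factor (default 1.3) for the transitions into frames 1
and 2 and by a shrink factor (default 0.7) afterwards, while the offset
decays by 30% per frame after frame 2 — the classic expand-then-resorb,
hyperdense-to-hypodense course. Four progression regimes (improving,
worsening, stable, static) are cycled across cases and determine the
sentiment ground truth through explicit area rules: prognosis is positive
when the final rasterized lesion area falls below the initial one,
negative when it still exceeds the peak-frame area, neutral otherwise and
uncertain for a static lesion; therapeutic sentiment reflects the shrink
factor alone. These labels are therefore pure functions of the geometry.

Clinical notes are template-based: a structured header naming the subtype
and the dementia-risk category, a qualitative size-trajectory sentence
(enlarged / unchanged / partially resorbed), sentiment-keyed sentences
drawing at least one phrase from the matching lexicon, the risk category
restated twice more in the body — mirroring how risk statements recur in
real documentation — and neutral clinical filler up to 430+ whitespace
tokens (always within 400–900). Two design points matter for what the
benchmark can show. First, the size trajectory is verbalized, not printed
as pixel counts: exact areas would hand the text modality the lesion's
geometry, which the generator deliberately reserves for the image
modality. Second, the risk category is the text modality's subtype
signal, and it is four-valued over five subtypes: SDH and SAH are both
"moderate", so text alone cannot fully separate them, while their image
appearance (localized crescent vs full rim) can. Conversely SDH and EDH
look alike at coarse resolution but differ in risk wording. This is the
planted complementarity that fusion exploits.

None of this imitates MR physics, partial-volume effects, scanner
variation, real report language or class imbalance; passing tests show
the pipeline's algebra and learning machinery work, not that the method
performs on clinical data.

## Entropy-adaptive CLAHE

Each tile's histogram (default 8×8 grid; 2×2 available) is clipped at a
limit derived from its Shannon entropy: the normalized entropy
$h/\log_2 L$ maps affinely onto $[1.5, 4.0]$ multiples of the uniform bin
height. The mapping is our fixed rendering of the stated
entropy-dependence (monotone, bounded, two interpretable knobs). Excess
mass is redistributed uniformly into bins with head-room, integer share
per pass and round-robin for the remainder, conserving total mass
exactly; if every bin saturates the leftover spreads evenly. LUTs use the
CDF-min convention (darkest occupied level → 0); a delta histogram falls
back to the plain-CDF rule and maps to $L-1$. Per-pixel output bilinearly
blends the four neighboring tile LUTs by distance to tile centers, with
edge clamping; tile bounds are half-open, row-major, 0-based, and
non-divisible sizes enlarge the last tile. Gamma correction follows
(fixed 1.25 by default, the empirically favored value; an
entropy-adaptive mode uses $\gamma = 0.5 + 2(1-\bar h/8)$ clamped to
$[0.5, 2.5]$), then a 3×3 box-blur unsharp mask (strength 0.5). The
order CLAHE→gamma→sharpen and the unsharp kernel are our choices; the
source names the steps but not the kernel.

## Encoders, fusion and training

The image encoder is a standard ViT skeleton at toy scale: patchify
(default P=8 on 64×64, so 64 patches), a shared linear projection to
D=32, per-vector standardization, CLS + learnable positions, two 4-head
self-attention blocks with residuals and a two-layer MLP. The text side
is a WordPiece tokenizer (greedy longest prefix, `##` continuations,
whole-word `[UNK]`) over a vocabulary built from the note templates, plus
additive token/segment/position tables. All parameters are seeded
Gaussians (sd 0.02) and stay frozen: they stand in for pretrained
encoders that are out of scope, so the learnable capacity lives in the
classifier heads.

Because the projection standardizes each patch vector, absolute patch
brightness is not linearly recoverable from the frozen embeddings; the
classifier readouts therefore operate on representations that retain it:
the image branch uses the per-patch pooled intensities of all five
enhanced progression frames (a 5×64 temporal descriptor — the pipeline is
temporal by design), and the text branch mean- and max-pools the token
embeddings. Cross-attention takes queries from the text sequence and
keys/values from the encoded patches, with row-stochastic scaled
dot-product weights; the fused representation concatenates the attended
values (pooled over text positions) and the pooled projected queries with
both modality vectors in one shared space — the "concatenating features
in a shared space" reading of the fusion equation. Early fusion is the
pre-encoder concatenation of the per-patch pooled raw image vector and
the mean token-table vector; late fusion averages the class probabilities
of independently trained per-modality heads, which double as the
image-only and text-only baselines.

Heads are single-hidden-layer perceptrons (tanh, hidden 64) trained by
full-batch gradient descent (rate 0.3, 500 epochs, L2 weight decay 1e-3)
on z-scored features, with per-epoch validation tracking and
best-validation checkpointing. Training is bit-deterministic for a fixed
seed; every random draw in the package flows from one run seed through
named substreams. Pufferfish patch-size optimization moves a population
toward the best-known candidate (exploration β) and away from the
worst-fitness position (evasion α), snapping to the discrete candidate
set; the update rule is our rendering of the stated semantics, the
population cycles through all candidates at initialization, and elitism
makes the best-so-far history non-increasing, so on small candidate sets
it provably matches exhaustive search.

## Numerical conventions

PSNR caps at an `Inf` sentinel for identical images; SSIM uses a uniform
window (7, shrunk to fit small images) with stabilizers k1=0.01, k2=0.03;
RMS contrast is the standard deviation of mean-normalized intensities.
ROC curves sweep unique scores with ties grouped and integrate by
trapezoid; degenerate metric denominators yield 0 with a warning.
MSE-based progression-model selection averages over time stamps and
pixels and breaks ties by list order. The clip-and-redistribute step
guarantees exact mass conservation; a bin may end at most one
redistribution unit above the clip limit.

## Problem sizes and defaults

The packaged benchmark generates 525 balanced cases (70/15/20 per subtype
per split) at 64×64 px — about 500 cases, the scale at which the fusion
ordering is a stable statistical tendency while the whole run (generation,
enhancement of five frames per case, embedding, training of all strategy
variants, evaluation) completes in a couple of minutes on one CPU. The
manifest bookkeeping check uses the published per-subtype case counts
(378/73/75 cases, 10 images per case). On the benchmark, joint fusion
reaches ≥90% subtype test accuracy and strictly exceeds the image-only
and text-only baselines; the early/late variants land in between the
baselines and the joint model. Mixed-lesion cases are generated and
counted but excluded from classifier training and evaluation.

## Known limitations

Frozen random encoders mean the ViT/BERT stages add no learned
representation; the sentiment ground truth is a geometric construction,
not clinician judgment; the image baseline sees only coarse pooled
intensities, so its accuracy understates what a trained CNN would do; and
none of the headline numbers transfer to real radiology data — the
package's claims are about the algorithms, their invariants and their
interplay, all of which the test suite checks directly.
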