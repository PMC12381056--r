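# circletOD

Unsupervised localization and segmentation of the **optic disc (OD)** in
retinal fundus photographs.

The OD — the bright, roughly circular region where the optic nerve and the
retinal vessels exit the eye — is the anatomical anchor for automated
screening of glaucoma and diabetic retinopathy. `circletOD` implements a
fully unsupervised pipeline for finding its center and delineating its
boundary, aimed at researchers in retinal image analysis who need a
training-free baseline, and it ships a seeded synthetic fundus-phantom
generator with exact ground truth so the whole pipeline is testable without
downloading any clinical dataset.

## Method

1. **Color-dominance preprocessing.** The blue-channel variance
   σ² = (1/mn) ΣΣ (B(i,j) − μ_B)² classifies the image as red-dominant
   (σ² ≤ θ, default θ = 1500) or chromatic; CLAHE is applied in CIE-Lab space
   to the a\* (red-green) or b\* (blue-yellow) channel accordingly, then to
   the green channel, followed by bilateral smoothing and the linear stretch
   I = α·I_filtered + β with α = 255/(Gray_max − Gray_min), β = −Gray_min·α.
2. **Patch-based Fast Circlet Transform (FCT).** A bank of N = 5
   raised-cosine radial-frequency windows H_j (a partition of unity,
   Σ_j H_j² = 1) is lifted to 2-D filters K_j(ξ) = e^{i|ξ|r_m}·H_j(|ξ|).
   FFT filtering at the optic-cup radii r_m ∈ {10, 20} px (scale j = 2)
   turns circular edges of radius r_m into coefficient-magnitude peaks at
   their centers. The 600×600 analysis field is tiled by 100 patches of
   60×60 px and each patch contributes max |c| per radius.
3. **Vessel entropy.** A Coye-style segmentation (Lab → first principal
   component → CLAHE → background subtraction → ISODATA threshold) yields a
   binary vessel map; per-patch binary Shannon entropy
   H_i = −Σ p_k log₂ p_k measures vascular complexity, which peaks near the
   vessel convergence at the OD.
4. **Adaptive fusion.** Patch scores
   L_i = w₁·MaxCoeff_i^(10) + w₂·MaxCoeff_i^(20) + w₃·H_i are maximized over
   patches. Weights are uniform (1/3) or learned per image by **Minkowski
   weighted K-means**, minimizing
   F(S,C,w) = Σ_k Σ_i Σ_v s_ik w_v^γ |z_iv − c_kv|^γ with deterministic
   anomalous-pattern initialization and silhouette-selected exponent γ. The
   OD center is the brightest pixel of the winning patch.
5. **Segmentation.** Vessels are removed by PDE inpainting
   (∂u/∂t = λΔu + χ_{Ω∖D}(f − u), Neumann boundaries), the channels are
   recombined as I_w = 0.7·R + 0.3·B, and a **Chan-Vese level set**
   initialized at the detected center minimizes
   μ·Length(C) + λ₁∫_in |I_w − α₁|² + λ₂∫_out |I_w − α₂|²; the largest
   connected region of the converged contour is the OD mask.

Evaluation metrics: normalized center distance
(‖pred − gt‖ / √(W² + H²)), Dice coefficient and Jaccard index (IoU).

## Worked example

```r
library(circletOD)

ph  <- generate_phantom(phantom_spec(seed = 3))   # synthetic fundus + truth
res <- segment_od(ph$image, od_config())          # localize + segment
res
#> <od_result> center (308, 309), patch 56, weights (0.449, 0.336, 0.215), gamma = 3
#>   segmentation: ok (area 10579 px)

dice(res$mask$mask, ph$disc_mask)
#> [1] 0.9457897
normalized_distance(ph$center, c(res$center$x, res$center$y), 600, 600)
#> [1] 0.01419116
glance(res)        # one-row tibble: center, weights, gamma, mask area
autoplot(res)      # overlay of center and contour on the enhanced image
```

The printed result means: the fused patch score selected patch 56, the
brightest pixel of that patch is 12 px from the true phantom center (1.4% of
the image diagonal), the MWK-means weights favored the r = 10 circlet
feature, and the Chan-Vese mask overlaps the true disc with Dice 0.946.

A larger experiment mirrors the benchmark-table layout:

```r
phs <- phantom_suite(20, base_seed = 7)
tbl <- evaluate_phantoms(phs, od_config(), segment = TRUE)
summarize_metrics(tbl)   # mean / median / std dev / max / min per metric
```

A thin CLI over the same functions is installed at
`inst/scripts/odpipe.R` (`localize`, `segment`, `evaluate`, `phantom`
subcommands).

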