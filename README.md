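# nactct

Sparse-view CT reconstruction with Split-Bregman optimization and joint
total-variation / non-aliasing contourlet (NACT) regularization, together
with its ART and ART-TV baselines, a simulated parallel pencil-beam
geometry, and RMSE/UQI image-quality evaluation.

## What it does

Reconstructing a CT image $f$ from projections $p = Af$ acquired at only a
few dozen angles is badly underdetermined. This package solves

$$\min_f \ \lVert f\rVert_{TV} + \lVert \Phi f\rVert_1
  \quad \text{s.t.} \quad \lVert Af - p\rVert_2^2 < \sigma^2$$

where $\Phi$ is a non-aliasing contourlet transform: a multiscale,
multidirectional Parseval frame built from anti-aliasing pyramidal
frequency windows ($D_0^2 + L_0^2 = 1$, $D_1^2 + L_1^2/4 = 1$) composed
with directional wedge filters. The optimization alternates Kaczmarz (ART)
data sweeps with inner Split-Bregman iterations: normalized steepest
descent on the quadratic subproblem, positivity clamping, soft-threshold
shrinkage of the gradient and transform coefficients, and Bregman variable
accumulation. Plain ART and a TV-only variant (ART-TV) provide the
baselines, isolating what the contourlet channel adds.

It is aimed at researchers studying iterative reconstruction and
regularization choices on simulated data: everything is generated in
code — a modified Shepp-Logan head phantom, Siddon ray tracing for the
sparse system matrix, an interleaved two-half-turn angle schedule, and
seeded Gaussian projection noise. User-supplied images (PNG/TIFF/CSV) and
sinograms (CSV) can be reconstructed too.

## Worked example

A scaled-down study — 64 × 64 phantom, 20 views, 50 iterations:

```r
library(nactct)
ph <- make_phantom(64)
geom <- projection_geometry(n_views = 20, n_detectors = 64)
A <- build_system_matrix(dim(ph), geom)
p <- project(A, ph)

params <- recon_params()          # lambda = 1000, gamma = 30, mu = 30,
                                  # step 0.2, K = 10, 50 outer iterations
for (alg in c("art", "art-tv", "spbr-nact")) {
  fR <- switch(alg,
    "art"       = art_reconstruct(A, p, params),
    "art-tv"    = art_tv_reconstruct(A, p, params),
    "spbr-nact" = spbr_nact_reconstruct(A, p, params))
  cat(sprintf("%-9s rmse %.4f  uqi %.4f\n", alg, rmse(ph, fR), uqi(ph, fR)))
}
```

prints

```
art       rmse 0.0695  uqi 0.9425
art-tv    rmse 0.0559  uqi 0.9651
spbr-nact rmse 0.0423  uqi 0.9797
```

With only a third of the views classical sampling would need, plain ART
leaves streak artifacts (RMSE 0.070); adding the TV channel removes part
of them; the joint TV + contourlet regularization cuts the error to 0.042
and raises the universal quality index to 0.98 — the same ordering the
method shows at full scale. `run_table1()` runs the full noise-free/noisy
comparison, `run_sweep()` produces metric curves over iteration or view
counts, and `profile_line(fR, 140)` extracts a row profile for visual
comparison. A thin command-line front end lives at `inst/cli/nactct`.

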