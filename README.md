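# anpca

Adaptive nonlinear principal component analysis (ANPCA) for real-time
extraction of the P300 event-related component from multichannel EEG.

## The problem

The P300 is a ~1.5 µV positive deflection peaking about 300 ms after an
attended (target) stimulus, recorded against ongoing EEG whose raw
excursions reach ~300 µV.  Extracting it single-trial — without the
down-sampling and trial averaging that destroy timing information — is a
blind source separation problem: the scalp recording is modeled as a linear
instantaneous mixture

    x(k) = A s(k) + n(k)

of N mutually independent sources through a full-column-rank M×N mixing
matrix, plus white Gaussian sensor noise.  This package is for BCI and ERP
researchers who want that separation to run adaptively, sample by sample.

## The method

ANPCA unmixes in four adaptive stages:

1. **Pre-separation** — multi-stage PCA: spatial whitening
   `x̄ = Λ^(-1/2) Vᵀ x` from the dominant eigenvalues of the sensor
   covariance, then a rotation from the eigendecomposition of the delayed
   covariance of `x̄(k) + x̄(k−τ)` (diagonal `2(1+ρᵢ(τ))` in source
   coordinates).  An online eigenvector tracker (learning rate β = 0.6) is
   the streaming alternative.
2. **Adaptive whitening** — `P ← P + η (I − R̂ᵤᵤ) P` with a
   self-normalizing rate (forgetting factor ξ = 0.01).
3. **NPCA separation** — `y = Wᵀu`, `W ← W + μ f(y)(u − f(y))ᵀ W` with
   `f(t) = tanh(t)`, `W(0) = I`, forgetting factor γ = 0.002, periodic
   symmetric orthonormalization.
4. **Estimation** — `Q ← Q + α (x − Q y) yᵀ`, α = 0.3, recovering the
   mixing columns.

Quality is scored by the separation performance index of the combined
system `C = Wᵀ P V` against the (unit-variance) ground-truth mixing:

    PI = 1/(2(M−1)) Σᵢ [(1 − max_j c²ᵢⱼ / Σ_j c²ᵢⱼ) + (1 − max_j c²ⱼᵢ / Σ_j c²ⱼᵢ)]

PI = 0 for a scaled permutation (perfect separation), 1 for maximal mixing;
it is also reported as `20·log10(PI)` dB.

The package additionally provides: a synthetic oddball-ERP session
generator (seven-stimulus schedules, P300-like source, colored background
and drift-artifact sources, well-conditioned random mixing, sensor noise);
sixth-order 1–12 Hz Butterworth pre-filtering and stimulus-locked epoching;
block-wise target classification; SOBI and single-stage NPCA baselines with
a plug-in registry; a five-layer autoencoder for nonlinear principal
components; EDF and delimited-text I/O; and a small CLI
(`inst/scripts/anpca-tool`).

## Worked example

```r
library(anpca)

sess <- simulateSession(nBlocks = 10, duration = 7000 / 256, seed = 1)
sess$recording
#> Recording: 8 channels x 7000 samples at 256 Hz (27.3 s)
#>   channels: Fz, Cz, Pz, Oz, P7, P3, P4, P8

cfg <- anpcaConfig(seed = 1, passes = 8, filter = list(enabled = FALSE),
                   input = sess$recording, events = sess$events,
                   truth = list(sources = sess$sources, model = sess$model))
res <- runPipeline(cfg)

res$report
#> QualityReport: PI = 0.01999 (-34.0 dB)
#>   epochs run: 8; converged at epoch 2
res$classification
#> ClassificationResult: accuracy 1.000 over 10 blocks (m = 3, window [0.25, 0.45] s)
```

The report says the combined system is 0.02 away (on the 0–1 index; −34 dB)
from a perfect scaled permutation of the four true sources, that the
per-epoch PI trajectory settled by epoch 2 of the replayed 7000-sample
block, and that the target stimulus was identified correctly in every block
from the separated ERP component alone.  `piTrajectory(res$report)` exposes
the full PI-versus-iteration curve (logged every 50 updates);
`res$separated` holds the separated components as a `Recording`.

Baselines on the same session:

```r
compareAlgorithms(algorithms = c("anpca", "sobi", "plain_npca"), seeds = 1:6)
```

tabulates per seed the final PI and the iterations (samples processed) each
algorithm needs to bring PI below 0.1 and 0.05.

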