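# nsctfusion

Multimodal medical image fusion in the nonsubsampled contourlet transform
(NSCT) domain, for R.

## The problem

Clinical imaging modalities are complementary: CT renders dense structures
(bone) with little distortion, MRI renders soft tissue; MR-T1 shows anatomy,
MR-T2 pathology. Image fusion combines one registered pair of single-channel
images `A` and `B` into a single image `F` that keeps the salient content of
both, for use in diagnosis, radiotherapy guidance and treatment planning.
`nsctfusion` is aimed at researchers who need a transform-domain fusion
method with measurable quality, a reproducible synthetic test bed, and the
standard objective metrics, all scriptable from R or a shell.

## The method

Fusion runs in the NSCT domain — an undecimated multiscale, multidirection
decomposition built from a nonsubsampled pyramid filter bank (scales) and a
nonsubsampled directional filter bank (2^l fan wedges per scale). Every
subband has the size of the input and the transform is shift-invariant,
which suppresses the pseudo-Gibbs artifacts that decimated transforms
introduce at fused-coefficient discontinuities.

Given θ-level decompositions `A → {L^A, H^A_{k,l}}` and
`B → {L^B, H^B_{k,l}}`:

- **Low frequencies** are selected by **phase congruency** (PC), a
  contrast- and brightness-invariant feature measure that is large where
  Fourier components are maximally in phase:

      L^F(i,j) = L^A  if PC^A > PC^B;  L^B  if PC^A < PC^B;
                 (L^A + L^B)/2  on ties.

- **High frequencies** are selected by **local Log-Gabor energy**: each
  subband is filtered with a `U x V` bank of Log-Gabor quadrature filters,
  the squared responses are summed, `E = Σ_{u,v} Re(G)² + Im(G)²`, and
  averaged over a `(2M+1)(2N+1)` window; the coefficient with the larger
  windowed energy `LE` wins:

      H^F_{k,l}(i,j) = H^A_{k,l}  if LE^A_{k,l} ≥ LE^B_{k,l};  else H^B_{k,l}.

The inverse NSCT of the fused subbands yields `F`. The widely used
*average-maximum* baseline (average the low band, keep the
larger-absolute-value high coefficient) is included as `ruleSet =
"average_maximum"` for comparison.

Quality is assessed with standard deviation, the Xydeas–Petrović edge-based
similarity `Q^AB/F`, mutual information (MI), histogram cross entropy,
spatial frequency, and PSNR against a reference.

## Worked example

```r
library(nsctfusion)

ph  <- makePhantomPair(size = c(64, 64), seed = 42)  # registered CT/MR-like pair
res <- fuseImages(ph$A, ph$B)                        # proposed rules
base <- fuseImages(ph$A, ph$B, fusionConfig(ruleSet = "average_maximum"))

evaluateAll(ph$A, ph$B, fusedImage(res))
#> Fusion quality report
#>   STD                 67.292
#>   Q^AB/F               0.757
#>   MI (bits)            6.320
#>   cross entropy        3.149
#>   spatial frequency   39.064
evaluateAll(ph$A, ph$B, fusedImage(base))
#> Fusion quality report
#>   STD                 65.591
#>   Q^AB/F               0.721
#>   MI (bits)            5.683
#>   cross entropy        2.567
#>   spatial frequency   37.603
```

The proposed rules transfer more edge information (`Q^AB/F` 0.757 vs 0.721)
and more source information (MI 6.32 vs 5.68 bits) than the
average-maximum baseline on this phantom, with higher contrast (STD) and
detail (spatial frequency). Under 5 % Gaussian noise the gap widens: fusing
the noisy pair and scoring against the clean fusion gives PSNR 25.9 dB
(proposed) vs 19.8 dB (baseline) at seed 42.

The same pipeline is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nsctfuse", package = "nsctfusion"))')
Rscript $CLI demo --seed 42 --out demo/ --size 64   # phantom + fused images + metrics.json
Rscript $CLI fuse A.png B.png -o F.png --rules proposed
Rscript $CLI metrics A.png B.png F.png --json report.json
```

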