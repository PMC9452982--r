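# MIRFusion

Rigid registration and fusion of 2D PET/CT slice pairs by
mutual-information maximization, with cellular-neural-network edge
extraction of the CT reference, high-uptake segmentation, a synthetic
phantom benchmark with known ground truth, and a RECIST response-tally
utility. Intended for researchers in medical image analysis who need a
small, fully deterministic, end-to-end reference pipeline for
intensity-based multimodal slice registration.

## The method

A floating PET slice `U` and a reference CT slice `D` are treated as
random variables over their quantized gray levels. From the co-located
pixel pairs of the overlap region the package estimates the joint
probability `j_UD(u,d) = n_ud / N` and computes the mutual information
(bits)

    I(U, D) = Σ_{u,d} j_UD(u,d) log2 [ j_UD(u,d) / (j_U(u) j_D(d)) ]
            = H(U) + H(D) − H(U,D),

which peaks when the shared anatomy is aligned, regardless of the
(nonlinear) relation between PET and CT intensities. The motion model
is the in-plane rigid transform

    v' = [cos β  −sin β; sin β  cos β] v + (tx, ty),

rotation about the image centre plus pixel translations. Because PET
edges are too blurred to extract reliably, only the CT is edge-lifted:
a Chua–Yang cellular neural network (dynamics
`dx/dt = −x + A∗y + B∗u + z`, output `y = 0.5(|x+1| − |x−1|)`, the
classical edge template) produces a binary CT edge image, and

    u* = argmax_T I(U(T), D_edge)

is found by an exhaustive coarse grid over `(β, tx, ty)` followed by
deterministic coordinate-descent refinement. The registered PET is then
alpha-blended over the CT through a hot colormap, and the
high-metabolism region is segmented by thresholding at a fraction of
the PET maximum.

See `vignettes/mi-registration-methods.Rmd` for the full model,
parameter defaults, the phantom design, and known limitations.

## Worked example

Generate a phantom whose PET is displaced by a known rigid motion,
register it back, fuse and segment:

```r
library(MIRFusion)

ph <- generatePhantom(1, size = 128, beta = 0.1, tx = 4, ty = -3)
ph
#> Phantom (seed 1): 128 x 128, true transform (beta 0.1, tx 4, ty -3),
#>   281 lesion-mask pixels

res <- registerImages(ph@pet, ph@ct)   # default: CT edge reference
res
#> RegistrationResult: u* = (beta -0.14375 rad, tx -3.75, ty 3.75),
#>   MI 0.13889 bits, 1615 evaluations

fr  <- fuseAfterRegister(ph@pet, ph@ct, res)
seg <- segmentHighUptake(fr$petRegistered, "fraction_of_max", 0.4)
round(accuracyMetrics(seg, ph@lesionMask), 4)
#> pixel_accuracy           dice        jaccard
#>         0.9952         0.8364         0.7189
```

The recovered `u*` is the transform that realigns the displaced PET, so
it approximates the *inverse* of the applied motion (for `beta = 0.1,
tx = 4, ty = -3` the realigning truth is `(-0.1, -3.68, 3.38)`);
translations come back within a fraction of a pixel and the rotation
within a few hundredths of a radian, the identifiability limit of
histogram MI on this content. The segmentation scores are computed
against the generator's ground-truth lesion mask.

Tallying RECIST response categories from a records CSV:

```r
csv <- system.file("extdata", "synthetic_response_records.csv",
                   package = "MIRFusion")
tallyResponses(readResponseRecords(csv), 3)
#> EfficacyTally: 27 evaluable patients after 3 cycles
#>   CR:  0 (0%)
#>   PR:  1 (3.7%)
#>   SD: 16 (59.3%)
#>   PD: 10 (37%)
```

A thin command-line front end over the same functions is provided at
`inst/scripts/mirfusion` (subcommands `phantom`, `edge`, `mi`,
`register`, `segment`, `fuse`, `report`).

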