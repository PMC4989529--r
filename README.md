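# hsseg — dedicated segmentation methods for hyperspectral image cubes

Hyperspectral line-scan cameras deliver a cube `L(m, n, i)` — two spatial
axes and 128-odd spectral bands (here 0.4–1.0 µm, 12-bit) — in which every
pixel carries a full emissivity/reflectance curve. For biomedical imaging
(hands, forearms, skin) that curve is the discriminative signal, yet most
segmentation pipelines still threshold single-band brightness and struggle
with two artefacts specific to these cameras: strongly elevated noise in
the first and last bands, and band-to-band drift of the segmented object's
shape. `hsseg` is for image-analysis practitioners who need spectrally
aware segmentation of such cubes, with everything testable offline against
synthetic phantoms with known ground truth.

## The three methods

Writing `L_PAT(i)` for the reference waveform of the target material
(supplied, or averaged over a region of interest, Eq. below), the package
implements:

* **SKE — fast emissivity-curve matching** (`ske_segment()`). Per pixel:
  `L_D(m,n,i) = (L_C(m,n,i) − L_PAT(i)) / L_PAT(i)`, mismatch count
  `L_R(m,n) = Σ_i [|L_D| ≥ p_r]`, grey error map
  `L_V = 1 − |L_R|/max|L_R|`, foreground where `L_V ≥ t`. Purely
  per-pixel, so it runs on the leading rows of a raw BIL file read straight
  from the start of the stream (`read_partial_rows()` reads exactly
  `rows·samples·bands·bytes` bytes) — a screening mode usable during
  acquisition.
* **S3D — whole-sequence 3D segmentation** (`s3d_segment()`). Reference by
  ROI average `L_PAT(i) = (1/(M_R N_R)) Σ_(m,n)∈ROI L_C(m,n,i)`; signed
  difference volume `L_C − L_PAT`; 3×3×3 median filtering (the in-plane
  8-neighbourhood extended across adjacent bands); percent-scale error map
  `L_S(m,n) = 100·mean_i|·|/mean_i L_PAT`; plane median smoothing;
  upper-threshold binarization at nested bounds (default 30/20/10 %:
  accept where the spectral error is *below* the bound). Exactly
  equivariant to 90° rotations.
* **SH — hierarchical segmentation** (`sh_segment()`). Downsample to
  M/8 × N/8 by block means; extract features
  `w_k = |L_C(m,n,i_k) − L_PAT(i_k)|` at the three highest local maxima
  `i_k` of the reference waveform; k-means over `K = 2..5` classes with the
  class count chosen by the minimal *std* criterion (standard error of the
  class means); the cluster nearest the origin is the object; upsample,
  then stabilize each band's mask with **conditional erosion/dilation**
  (17×17 structuring element; erosion only where the local mean brightness
  `p_c ≥ p_dc`, dilation only where `p_c ≤ p_ec`, defaults 0.5) and take a
  majority vote across bands.

Supporting modules: raw BIL/BSQ cube I/O with ENVI-style sidecar headers
(`read_cube()`, `write_cube()`), 3D and band-adaptive median denoising plus
dark/white calibration (`median3d()`, `adaptive_median()`, `calibrate()`),
confusion-matrix scores (`confusion()`, `seg_scores()`: TPR, SPC and
balanced accuracy `ACC = (TPR+SPC)/2`), and a synthetic phantom generator
with band-edge-amplified noise, small artifacts and ground truth
(`phantom_spec()`, `render_phantom()`). The methods vignette
(`vignettes/hyperspectral-segmentation.Rmd`) documents every model choice
and parameter.

## Worked example

Render the default phantom (96×96×32, moderate band-edge noise), preprocess
it, and run all three methods against the generator's ground truth:

```r
library(hsseg)

ph <- render_phantom(phantom_spec())
ph$raw
#> <hypercube> 96 x 96 x 32 (rows x cols x bands), uint16 little-endian BIL
#>   wavelengths: 0.400-1.000 um; dynamic range 12 bit; values in [0, 4095]

lc <- calibrate(adaptive_median(ph$raw), ph$dark, ph$white)

confusion(ske_segment(lc, ph$spectra[[1]], p_r = 0.1, bin_threshold = 0.6),
          ph$truth)
#> <confusion> TP 2192  FP 0  TN 6963  FN 61  (n = 9216)
#>   TPR 97.3 %  SPC 100.0 %  ACC 98.6 %

lev <- s3d_segment(lc, roi = c(40, 55, 42, 57))   # nested 30/20/10 % levels
confusion((lev >= 2) * 1L, ph$truth)              # mask at the 20 % bound
#> <confusion> TP 2245  FP 0  TN 6963  FN 8  (n = 9216)
#>   TPR 99.6 %  SPC 100.0 %  ACC 99.8 %

seg <- sh_segment(lc, pattern = ph$spectra[[1]])
seg
#> <sh_segmentation> 96 x 96 mask, 2153 foreground pixel(s)
#>   K = 2 classes (dispersion 0.006845), object class 1, peak bands 7/15/25, stabilized
confusion(seg$mask, ph$truth)
#> <confusion> TP 2153  FP 0  TN 6963  FN 100  (n = 9216)
#>   TPR 95.6 %  SPC 100.0 %  ACC 97.8 %
```

Here each method recovers the phantom object with balanced accuracy well
above 95 %: the mismatch-count map separates matching from non-matching
spectra (SKE), the percent-scale error map accepts pixels below the 20 %
spectral-error bound (S3D), and the clustering selects K = 2 classes whose
near-origin cluster is the object (SH).

A command-line wrapper with the same functionality ships in
`inst/cli/hsseg` (subcommands `synth`, `preprocess`, `ske`, `s3d`, `sh`,
`eval`; see `hsseg --help`).

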