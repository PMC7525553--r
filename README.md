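# srsaxs

Angular super-resolution retrieval for small-angle X-ray scattering
(SAXS) 2D detector images.

Laboratory SAXS instruments are limited by the direct-beam size (the
instrument point-spread function) and by the detector pixel pitch *l*.
`srsaxs` implements a two-stage computational remedy for users of such
instruments and for methods developers who want a fully simulated
testbed:

1. **Subpixel sampling (SPS)** — frames recorded at detector
   translations of *l/f* are registered by translation-only
   Lucas–Kanade and fused by robust median interlacing onto an *l/f*
   lattice, synthesizing an effective pixel *l/f*.
2. **Constrained multi-deconvolution (CMD)** — *m* exposures taken with
   different slit-engineered beam profiles (known kernels *P_i*) are
   jointly deconvolved by minimizing

   ```
   sum_i ||Y_i - P_i * X||_F^2 / (2 sigma_i^2)  +  nu ||X||_F^2
   ```

   per spatial frequency in closed form (or iteratively, optionally
   with a nonnegativity projection). The per-image weights `sigma_i`
   trade the high SNR of large slits against the resolution of small
   ones; `nu` is a ridge term stabilizing shared spectral zeros.

Running SPS first and CMD second is the full *SrSAXS* retrieval. The
package also ships the forward model that generates all inputs
(Lorentzian rings + reciprocal background + beamstop + slit×Gaussian
PSFs + Poisson counting), instrument geometry and azimuthal
integration, the peak-separation criterion
`delta = (I_p - I_v) / delta_q` with repeat-based uncertainty,
Richardson–Lucy and Farsiu-style baselines, and an equal-exposure
protocol comparison. No external data are required.

## Worked example

Simulate the two-ring doublet (radii 30 and 34 effective pixels, widths
0.9, amplitudes 1 and 0.6), acquire 9 subpixel positions for each of 6
PSFs, retrieve, and score the separation:

```r
library(srsaxs)

pattern <- saxs_pattern(
  rings = data.frame(radius = c(30, 34), width = 0.9,
                     amplitude = c(1, 0.6)),
  background_coeff = 1, beamstop_radius = 5, grid_shape = c(255, 255))

frames <- simulate_acquisition(pattern, default_psf_set(1, sigma = 0.4),
                               f = 3, shifts = shift_grid(3),
                               t_per_frame = 4, seed = 1)
res <- srsaxs_retrieve(frames, nu = 0.01)
prof <- profile_normalize(
  azimuthal_integrate(pmax(res$xhat, 0), center = pattern$center,
                      bin_width = 1 / 3),
  window = c(26, 38))
separation_delta(prof, window = c(26, 38))
#> delta = 0.1681 (I_p=0.6337, I_v=0.2975, dq=2, peaks at 30/34)
```

`delta` is the depth-over-distance score of the resolved doublet on the
unit-maximum profile: the lower peak at radius 34 stands 0.34 intensity
units above the valley, 2 effective pixels away. A single
equal-total-exposure frame with the smallest PSF
(`run_protocol(pattern, "plain", t = 4, ...)`) scores around 0.03 —
the doublet is barely detectable without the two-stage retrieval. Mean
values over seeds are higher than this single draw (about 0.2); see
below to reproduce them.

A thin command-line front-end for shell pipelines is installed under
`exec/`:

```sh
srsaxs simulate --config cfg.json --out frames/ --seed 1
srsaxs retrieve --in frames/ --out xhat.tif --nu 0.01
srsaxs integrate --in xhat.tif --out profile.csv
srsaxs delta --in profile.csv --window 26,38
```

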