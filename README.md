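# smlmhough

Hough-transform inference of line and circle structures from sparse
single-molecule localization microscopy (SMLM) data.

## The problem

STORM/PALM-style localization microscopy yields a table of molecular
positions `(x, y)` acquired serially. Dense spatial sampling — the
prerequisite for rendering a super-resolution image — costs acquisition
time, which caps temporal resolution for dynamic imaging. Many biological
structures, however, are parametric: microtubules and actin fibers are
locally straight lines, clathrin-coated pits are circles. A sparse sample
of localizations constrains those parameters strongly, so the structures
(and quantitative features such as filament orientation angles and vesicle
diameter distributions) can be inferred from a small fraction of the data.

`smlmhough` implements this inference with the classical Hough transform
used as a generative model. Each localization votes for every line
(normal form `rho = x cos(theta) + y sin(theta)`) or circle
(`(x-a)^2 + (y-b)^2 = r^2`) that could have generated it; consensus
structures appear as peaks in the vote accumulator — a 2-d `(rho, theta)`
matrix for lines, a 3-d `(a, b, r)` volume for circles. Voting is robust
to outlier localizations, occlusion and points from other structures.

The package provides:

* `hough_fit()` — the central model-fitting function, returning a classed
  object with `print`, `summary`, `coef`, `plot`, `residuals`, `predict`,
  `fitted` and `simulate` methods (the last samples new localization sets
  from the fitted structures — the generative direction).
* a synthetic-data simulator (`make_line_mask()`, `make_circle_mask()`,
  `make_parallel_line_mask()`, `sample_localizations()`,
  `apply_position_noise()`, `add_outlier_noise()`) emulating stochastic
  activation, Gaussian position noise (FWHM-parameterized) and
  salt-and-pepper outlier noise;
* staged transform operations (`line_transform()`, `circle_transform()`,
  accumulator smoothing, `detect_lines()`, `detect_circles()`) with the
  published parameter presets in `hough_params()`;
* evaluation tools: `cw_ssim()` (complex-wavelet structural similarity of
  reconstruction vs ground truth), `density_sweep()` (reconstruction
  quality vs data density over replicate samplings), `resolution()`
  (minimum inter-line distance on parallel-line targets) and
  `feature_statistics()` (orientation-angle and diameter distributions
  with replicate mean/sd);
* a multi-scale Laplacian-of-Gaussian blob-detection baseline
  (`blob_detect_log()`, `size_filter()`) for comparison;
* localization-table I/O (`read_localizations()`, `rescale_discretize()`),
  a YAML-configured pipeline driver (`run_config()`, `run_pipeline()`)
  and a thin CLI (`exec/smlmhough`).

## Worked example

```r
library(smlmhough)

# ground truth: 12 filaments in a 640 nm x 640 nm field (1 nm/px)
mask <- make_line_mask(seed = 1)

# emulate a short acquisition: 15% of the molecules, 5 px FWHM position noise
locs <- sample_localizations(mask, density = 0.15, seed = 101)
locs <- apply_position_noise(locs, position_fwhm = 5, seed = 102)

fit <- hough_fit(locs, "line", dims = c(640, 640), density = 0.15)
print(fit)
#> Hough line fit: 970 points (640 x 640 px) -> 16 line(s)

head(coef(fit), 3)
#>      rho theta
#> [1,] 150 -15.5
#> [2,] -66 -68.0
#> [3,] 318  -6.0

# score the reconstruction against the ground-truth rendering
ref <- render_shapes(mask$shapes, 640, 640)
as.numeric(cw_ssim(fitted(fit), ref))
#> [1] 0.9533249
```

With only 15% of the localizations and realistic position noise the fit
recovers the 12 filaments (a few are split across sampling gaps, giving 16
segments); each `(rho, theta)` row is a filament's perpendicular distance
from the origin (px) and normal angle (degrees). The CW-SSIM score of 0.95
against the ground truth means ~95% structural agreement — the key
practical point: most of the structural information is already present in
a small fraction of the data, so acquisition can be ~5-10x shorter for
dynamic experiments. `density_sweep()` traces the full score-vs-density
curve, which plateaus near 10-20% density.

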