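---
title: "Non-local means for low-dose CT: model, engines, and cost accounting"
author: "nlmct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-local means for low-dose CT: model, engines, and cost accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmct)
```

## The filter

Low-dose CT (LDCT) slices acquired at reduced tube current carry heavy
mottled noise and directional streak artifacts. Non-local means (NLM)
suppresses both by exploiting structural redundancy: each pixel is replaced
by a weighted average over a large search window, and the weight of a
candidate pixel measures how similar the *patch* around it is to the patch
around the pixel being restored.

For a pixel $p$ and search window $N_p$ of radius $T$ (so $|N| = (2T+1)^2$
candidates), the output is

$$\hat X(p) = \frac{\sum_{q \in N_p} w(p,q)\, Y(q)}{\sum_{q \in N_p} w(p,q)},$$

with patch-similarity weights

$$w(p,q) = \exp\!\left(-\frac{\sum_{\Delta \in [-B..B]^2}
  \lvert Y(p+\Delta) - Y(q+\Delta)\rvert \; G(\Delta)}
  {h^2 (2B+1)^2}\right),$$

where $B$ is the patch radius and $G$ is a distance-dependent kernel with
center value $G(0,0) = 2$ and $G(\Delta x, \Delta y) = 1/(\Delta x^2 +
\Delta y^2)$ elsewhere. Two details of this variant are deliberate and are
**not** "fixed" to match textbook NLM:

* the patch distance uses **absolute** (L1) intensity differences, not
  squared ones;
* the self weight is $\exp(0) = 1$; no maximum-weight substitution is
  applied at $q = p$.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `T` | search radius (window $(2T+1)^2$) | 40 (81×81) | large windows are needed for LDCT artifact suppression |
| `B` | patch radius (patch $(2B+1)^2$) | 4 (9×9) | patches above ~15×15 blur structures |
| `h` | smoothing strength | 10 | same units as the intensities |

`h` is *scale-relative*: the default of 10 is calibrated for display-scale
images in $[0, 255]$. Images on another scale (e.g. raw Hounsfield units)
need `h` scaled proportionally, because the weight exponent divides the
mean absolute patch difference by $h^2 (2B+1)^2 / \sum G$, and $\sum G$ is a
fixed kernel constant (11.1 for $B = 2$).

### Border policy

The filter definition is silent about borders, so the package fixes one
semantics and uses it in every engine (this is what makes bit-level
equivalence testable):

* **window truncation** — candidate partners $q$ outside the image are
  excluded from $N_p$; no invented intensities ever enter the average, and
  the normalization stays well defined;
* **mirror padding for patches** — patch differences are evaluated on the
  edge-duplicating symmetric extension of the image (`pad_symmetric()`), so
  a patch overhanging the border compares reflected real content.

Pixels are addressed as $(x, y)$ with $x$ the 0-based column and $y$ the
0-based row; offsets are enumerated row-major ($i_y$ ascending, then
$i_x$), and the accumulation order is part of the contract, so repeated
runs are bit-identical.

## Three equivalent engines

`nlm_filter_naive()` transcribes the definition literally (triple loop,
no reuse). It exists to be *obviously* correct: every optimization below is
tested against it, case by case, to $10^{-10}$ relative.

`nlm_filter_conventional()` is the straightforward pixel-parallel
formulation: for each window offset, whole-image passes compute the
difference plane, the weight plane, and the running weight / weighted-
intensity sums; a final pass divides. Its charged per-pixel cost is
$(2T+1)^2\,((2B+1)^2 + 2) + 1$, dominated by the $(2B+1)^2$ patch
accumulation repeated for every offset.

`nlm_filter_optimized()` removes the two redundancies:

1. **Row caching.** Within one offset, the $2B+1$ absolute pixel
   differences of a given row pair are shared by every patch whose span
   covers that row — as a patch center moves vertically by up to $B$
   pixels, the same row differences recur. `row_cache_pass()` fetches each
   row pair once ($2B+1$ fresh reads) and stores $B+1$ kernel-weighted row
   sums, one per vertical weight index $a = |\Delta y|$. The cache must
   hold *pre-weighted* sums (an $m \times n \times (B+1)$ tensor): the
   kernel couples $\Delta x$ with $\Delta y$, so raw row sums could not be
   re-weighted after summation. A patch weight then needs only $2B+1$
   cache reads (`patch_weight_from_cache()`) — the same arithmetic as the
   reference weight, re-grouped by rows, which is why agreement to
   $10^{-12}$ is asserted rather than hoped for.
2. **Weight symmetry.** The patch distance is symmetric, so
   $w(p, p+\Delta q) = w(p+\Delta q, p)$ exactly (a bitwise identity here:
   $|a-b| = |b-a|$ and the summation order is shared). Each computed weight
   plane is therefore credited to both ends of the pixel pair
   (`symmetric_accumulate()`), and the offset loop covers only the half
   list — offsets with $i_y > 0$ plus those with $i_y = 0, i_x > 0$,
   exactly $((2T+1)^2 - 1)/2$ of them — plus one explicit self step
   (weight 1). Forward and backward contributions are gated independently
   on their partner lying inside the image, which is exactly what
   reproduces the truncated-window semantics at borders.

## Cost accounting

Wall-clock time is hardware-bound, so the package compares engines by a
counted, memory-bound cost model (`op_counter()`): a unit charge is a fetch
of image data from the (conceptually global) image buffer, cached row sums
are free, and each pass charges its nominal per-pixel cost. The closed
forms are

* serial: $m\,n\,(2T+1)^2 (2B+1)^2$ — `serial_complexity()`;
* conventional: $(2T+1)^2((2B+1)^2 + 2) + 1$ — `conventional_complexity()`;
* optimized: $0.5\,(2T+1)^2 (2(2B+1)+1) + 1$ — `improved_complexity()`.

The optimized accounting treats the window as exactly half of $|N|$
offsets. The engine actually executes $(|N|-1)/2$ half-list passes plus a
self step, so the package's charging convention assigns the self step the
residual half charge $(2(2B+1)+1)/2$; the instrumented total then equals
the closed form *exactly* (half-integers are reported unrounded), and the
counted ratio equals `acceleration_ratio()` identically. The ratio grows
with $T$ at fixed $B$, is bounded by
$((2B+1)^2+2)\,/\,((2(2B+1)+1)/2)$ — about 8.74 for $B = 4$ — and is
approximated by the memorable asymptote $2B+1$ (9 for the clinical 9×9
patch).

```{r cost}
complexity_report(512, 512, T = 40, B = 4)
```

## The synthetic phantom

Clinical LDCT/SDCT pairs cannot ship with a package, so tests and demos run
on a synthetic phantom (`make_phantom()`, `add_low_dose_noise()`):

* **anatomy** — a body ellipse with two lung-like fields, a bright
  spine-like disk, a lesion and a small insert, painted on a $[0, 255]$
  display scale with organ contrasts of 15–70 units. This is the
  low-contrast regime of soft-tissue display windows, where low-dose
  mottle is comparable to the tissue contrast — deliberately so, since
  that is what makes LDCT reading hard;
* **degradation** — seeded Gaussian noise ($\sigma = 15$ by default) plus
  8 additive oriented ridges (~1–2 px wide, amplitude 25, random sign)
  through the image center, standing in for streak artifacts.

What the phantom does *not* emulate: projection/FBP reconstruction physics,
Poisson photon statistics, Hounsfield calibration, detector correlations,
or 3D slice continuity. Passing the behavioral test (filtering a degraded
phantom lowers the MSE to the clean phantom, five seeds out of five, with
$T = 10, B = 2, h = 10$) therefore shows the implementation denoises
structured degradation as intended — it is not a claim about diagnostic
image quality on clinical data.

One scale effect is worth knowing: the search window must stay small
relative to the anatomy. At the default 128² size the 21×21 window sits
well inside the organs; on much smaller images the same window spans a
large fraction of the phantom and the filter oversmooths (the L1 weight at
$h = 10$ discriminates modest contrast steps only weakly, so behaviour
approaches a windowed box mean).

## Numerical choices

* All arithmetic is double precision regardless of input bit depth; the
  kernel table is precomputed once per filter call.
* Engine-equivalence tolerance is $10^{-10}$ relative (reassociation of
  sums is the only source of disagreement); per-weight agreement between
  the cached and reference paths is asserted at $10^{-12}$; bitwise
  identity is asserted where the arithmetic is genuinely identical
  (weight symmetry, repeated runs, contiguous chunking).
* Degenerate inputs have defined behaviour and tests: $1\times1$ images,
  $T = 0$ (identity), $B = 0$ (single-pixel patches), constant images
  (fixed points of all engines), pads wider than the image.
* Test problem sizes: the randomized equivalence suite uses 50 cases with
  $m, n \le 16$, $T \le 4$, $B \le 2$, $h \in \{1, 10, 100\}$ — small
  enough for the deliberately slow naive oracle, while exercising every
  border and parameter regime; instrumented ratio checks run the full
  clinical offset loops ($T$ up to 40, $B = 4$) on tiny images, which is
  sound because charged counts are per pixel and independent of image
  size.
* Float TIFF output stores intensity$/65536$ (an exact power-of-two
  scaling into the writer's $[0,1]$ range), so round trips are exact to
  32-bit float precision; this convention applies to files written by this
  package. The PNG writer is 8-bit; 16-bit output uses TIFF.

## Limitations

* 2D only; no plane-wise 3D extension.
* No GPU execution: the shared-memory argument is represented by the
  counted-access model, which is the point — the algorithmic claim is
  verifiable arithmetic, not timings.
* DICOM is not read directly (no reader available to this package);
  convert slices to 16-bit PNG/TIFF.
* The naive engine at clinical parameters is impractically slow by design;
  use the optimized engine.
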