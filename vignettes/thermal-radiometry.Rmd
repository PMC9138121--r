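---
title: "From raw sensor signal to temperature: the radiometric model behind irproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw sensor signal to temperature: the radiometric model behind irproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irproc)
```

## The measurement problem

A thermal camera does not measure temperature. Each microbolometer
element produces a digital number (DN) proportional to the infrared
radiance reaching it, and that radiance mixes three sources: emission
from the target itself, radiation from the surroundings reflected off
the target's surface, and emission from the air column between target
and lens. Vendor software converts DN to temperature internally but
exposes neither the algorithm nor the intermediate quantities, which is
a poor basis for reproducible research. `irproc` implements the whole
chain in the open, so every step can be inspected, tested and, where
needed, modified.

## The signal model

**Sensor calibration.** Over the camera's spectral band the relation
between the DN-valued signal $S$ emitted by a source at absolute
temperature $T$ (kelvin) and weighted by $w$ is modelled as

$$S = \frac{G\,w}{R\,\bigl(e^{B/T} - F\bigr)} + O,$$

with per-camera constants $G$ (gain), $O$ (offset), $B$ (an exponential
constant in kelvin), $R$ (radiance scaling) and $F$ (a stored
generalization of the literal 1; cameras usually store exactly 1).
These are the "Planck" tags of the camera metadata. `component_signal()`
evaluates this law; `object_temperature()` inverts it,

$$T = \frac{B}{\ln\!\bigl(\tfrac{G\,\varepsilon}{R\,(S_{obj}-O)} + F\bigr)},$$

with the natural logarithm, so the pair is algebraically exact. Writing
$F$ instead of 1 in the inversion keeps it exact for cameras that store
$F \neq 1$.

**Three sources.** The measured total decomposes as

$$S = \tau S_{obj} + \tau S_{refl} + S_{atm},$$

where $\tau$ is the atmospheric transmissivity over the object
distance, $S_{obj}$ uses weight $w = \varepsilon$ (target emissivity)
at the object temperature, $S_{refl}$ uses $w = 1-\varepsilon$ at the
*apparent reflected temperature* (the reading off a near-perfect
reflector such as crumpled aluminium foil), and $S_{atm}$ uses
$w = 1-\tau$ at air temperature. `object_signal()` solves this for
$S_{obj}$:

$$S_{obj} = \frac{S}{\tau} - S_{refl} - \frac{S_{atm}}{\tau}.$$

Because this is the exact algebraic inverse of the composition,
`frame_to_temperature()` recovers a forward-generated temperature field
to better than $10^{-6}$ °C when no quantization intervenes, and to
better than 0.05 °C once the signal is rounded to 16-bit integers (the
DN resolution near room temperature with the default constants is
roughly 0.005 K per DN).

**Atmosphere.** Transmissivity comes from a two-exponential
water-content model: the air water content is

$$H = RH \cdot e^{1.5587 + 6.939\cdot10^{-2} t - 2.7816\cdot10^{-4} t^2 + 6.8455\cdot10^{-7} t^3}$$

($t$ air temperature in °C, $RH$ a fraction), and

$$\tau = X e^{-\sqrt d (\alpha_1 + \beta_1 \sqrt H)} + (1-X) e^{-\sqrt d (\alpha_2 + \beta_2 \sqrt H)}$$

with the camera-stored coefficients $\alpha_i, \beta_i, X$ and object
distance $d$ in metres. $\tau(d=0)=1$ identically. This short-range
model considers water vapour only; it is not appropriate for
kilometre-scale paths where CO₂, ozone and scattering matter.

## Parameters that matter

| Parameter | Units | Default (fixtures) | Meaning |
|---|---|---|---|
| emissivity $\varepsilon$ | – | 0.95 | fraction of black-body emission; ~0.95 for leaves |
| air temperature | °C | 20 | drives $H$ and $S_{atm}$ |
| relative humidity | fraction | 0.5 | values > 1 are treated as percent and divided by 100 |
| apparent reflected temp. | °C | 20 | background radiation reflected off the target |
| object distance | m | 1 | attenuation path length |

Emissivity is the sensitive one: assuming a higher $\varepsilon$ for a
target warmer than its reflected background lowers the inferred
temperature (a property the test suite asserts). Humidity units are a
classic ambiguity: cameras store percent, the water-content formula
wants a fraction, so any ingested value above 1 is interpreted as
percent — the only reading under which both conventions coexist.

## Offset convention and the synthetic camera

The three component signals each include the sensor offset $+O$, so the
composed total carries $O(2\tau+1)$ rather than $O$. The inversion
above undoes this exactly — self-consistency of the forward/inverse
pair is the package's tested contract, and the `verify` workflow exists
to arbitrate any residual convention difference against reference
exports from other software. One practical consequence falls on the
synthetic camera used for testing: with a large *negative* offset the
composed total would go negative for any scene cooler than ~70 °C and
could not be stored as an unsigned 16-bit number. The fixture
calibration therefore uses a positive offset, $O = 2000$ (with
$G = 21106.77$, $B = 1501$ K, $R = 0.012545$, $F = 1$), which keeps the
composed signal inside the converter range for scene temperatures from
−70 to +60 °C. For users reconciling against formulations that keep
components offset-free, `component_signal(..., include_offset = FALSE)`
exposes the radiance-only term.

## What the synthetic generator emulates — and what it does not

`scene_spec()` / `forward_signal()` produce raw frames exactly as the
inversion expects them: rectangles and disks painted over a uniform
background (later objects win on overlap), per-pixel emissivity,
optional seeded Gaussian DN noise, optional 16-bit quantization, and
packaging as sidecar pairs (16-bit PNG payload plus a one-row parameter
CSV) that exercise the byte-order rules of the reader. Default scenes
image a leaf-like target (0.95 emissivity, 20 °C air, 50 % humidity,
1 m distance) at 48×36 to 64×48 pixels — small enough that the full
suite runs in seconds, large enough that region statistics are
meaningful.

The generator deliberately omits optics (vignetting, defocus), dead
pixels, sensor drift and scene-structure artefacts. Passing tests
therefore demonstrate the *algorithmic* correctness of the chain —
exact inversion, byte-order handling, reproducibility — not the
field accuracy of any physical camera, which always depends on its
factory calibration and on honest acquisition parameters.

## Numerical choices

* **Transmissivity clamp.** $\tau$ is clamped to $[10^{-6}, 1]$ with a
  warning; absurd distances otherwise explode the $S/\tau$ division.
  With mixing weights $X > 1$ the model can nominally exceed 1, hence
  the upper clamp too.
* **Undefined pixels.** A pixel whose object signal falls at or below
  $O$ has no temperature under the model. Frame operations map it to
  `NaN`, count it, and continue; scalar calls raise an error. No floor
  or clamp is ever applied to *valid* results — a −70 °C scene inverts
  to −70 °C, where some vendor tools floor at −40 °C.
* **Histogram stretching.** The low/normal/high contrast options
  exclude 0 %, 0.3 % and 3 % of pixels in total. The excluded count
  $m = \mathrm{round}(n f)$ is split $\lfloor m/2\rfloor$ to the cold
  tail and $\lceil m/2\rceil$ to the hot tail (hot outliers, e.g.
  specular sun glint, are the more common nuisance); making the *total*
  exact is the contract, since only the total is meaningful at odd $m$.
  A constant frame is expanded by ±0.5 °C with a warning.
* **LUT mapping.** The display range maps linearly onto 256 LUT bins,
  half-open with the last bin closed; the exact midpoint lands in the
  upper bin (index 128). Decoding a rendered pixel returns its bin
  centre, so decode error is below one bin width.
* **Byte order.** PNG payloads are treated as little-endian (samples
  need swapping on read), TIFF as big-endian; models on the
  user-editable exception list invert the rule. The direction is fixed
  by convention and exercised both ways by the fixtures.
* **Byte-stable outputs.** Temperature CSVs print two decimals with a
  fixed locale-free format; re-running a folder from its saved
  `parameters.csv` reproduces byte-identical CSVs (checksum-tested).
* **Population standard deviation.** Object statistics divide by $n$,
  matching the host image-analysis convention; a one-pixel object has
  `sd = 0`.

## Design choices where the design was open

* **Sidecar fixtures vs JPEG.** Metadata in real radiometric JPEGs is
  read through an `exiftool` subprocess (tag names documented in
  `extract_metadata()`); the sidecar path is a first-class input format
  parsed in pure R, so the entire test suite runs without external
  binaries.
* **Temperature raster format.** 32-bit float TIFF, written by a
  compact dedicated writer, preserves full precision for downstream
  image analysis; the CSV grid is the byte-exact interchange format.
* **Video.** `export_video()` writes an uncompressed RGB AVI: lossless,
  deterministic, and readable everywhere, at the cost of size (a
  247-frame sequence of 320×240 images is ~57 MB). Ten frames per
  second is the default.
* **Batch constants.** Calibration constants are always taken from each
  image's own metadata, even under a global parameter override —
  mixing cameras in one folder is otherwise silently wrong. A
  `compat_first_file` flag reproduces the stricter behaviour of tools
  that extract metadata only once per folder.
* **Mask workflow.** Interactive region drawing is out of scope; masks
  are 8-bit PNG files, and `threshold_to_mask()` converts a thresholded
  binary image into sequentially labelled objects (via EBImage's
  connected components) to mirror the common leaf-measurement workflow.

## Problem sizes

The test suite and acceptance script use 48×36 to 64×64 synthetic
frames, folders of 1–3 images, a 1000-value uniform histogram for the
stretching checks, and a 255-label mask on a 64×64 frame. These sizes
give sub-DN-resolution verification of every contract while keeping a
full run in the tens of seconds on one core.

## Known limitations

* The water-content transmissivity model is short-range only.
* Lens/window transmission and reflections inside the optics are not
  modelled; neither is estimating calibration constants from
  measurements.
* The byte-order exception list ships with synthetic placeholder
  models; real offending camera models must be added by users who own
  such cameras.
* Reference-export dialect detection (separator, decimal comma) is
  best-effort; exotic vendor CSV variants may need manual conversion.
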