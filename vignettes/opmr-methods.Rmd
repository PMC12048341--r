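---
title: "Methods: the opmr patch codec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the opmr patch codec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmr)
```

## The problem

An on-patient medical record stores a small payload — a vaccine identifier,
a dose number, a date bucket — as an N×N pattern of near-infrared
fluorescent deposits left in the dermis by a dissolvable microneedle patch.
Each needle position is one bit. The record must survive two corruption
channels that act on very different axes:

* **temporal**: deposited bits fade or are cleared over weeks to months, so
  some ON bits read as OFF (one-sided loss);
* **spatial**: the record is read from a photograph of skin — tilted,
  scaled, translated, blurred, noisy and in an unknown 90°-multiple
  orientation.

The codec in this package addresses the first channel with a Reed–Muller
error-correcting code and the second with fixed grid geometry (corner
orientation markers plus a rectification/recognition chain that needs no
per-image tuning).

## The Reed–Muller code

RM(r, m) is the binary code whose codewords are the truth tables of boolean
polynomials of degree ≤ r in m variables. Its generator matrix rows are the
evaluations of all k = Σ_{i=0}^{r} C(m, i) monomials of degree ≤ r at the
2^m points; we order rows degree-ascending, lexicographically within degree,
and points in binary counting order (variable 1 most significant). Any fixed
convention works — this one makes encode/decode round-trip-safe and
reproducible. Minimum distance is d = 2^(m−r), so up to
t = 2^(m−r−1) − 1 arbitrary bit errors are always correctable for r < m.

Bit fading is well modelled as independent, non-clustered bit errors, which
is exactly the channel Reed–Muller majority-logic decoding is strongest
against: for each monomial on variable set S, the evaluation points
partition into 2^(m−|S|) cosets of the subspace spanned by S, each coset
contributing one parity-sum vote for the coefficient of S. A corrupted bit
spoils at most one vote per monomial, so a majority survives any error
pattern of weight ≤ t. Decoding peels coefficients from degree r down to the
constant term, XOR-ing each recovered layer out of the residual.

Numerical/tie-break choices:

* **Tied majority votes** (possible only beyond the guarantee) resolve to 0,
  are counted, and raise the `low_confidence` flag.
* **Beyond-radius words** still return a best-effort decode rather than an
  error: downstream decodability scoring is defined as exact match with the
  intended payload, which requires an answer. `low_confidence` is also set
  whenever the residual distance exceeds t.
* `n_corrected` is the Hamming distance between the received word and the
  re-encoded decode, i.e. the number of bits the ECC repaired.

The capacity table (`capacity_table()`) derives every entry — block length,
information units, 2^k encodable patterns, correction radius — from the
constructed generator matrix. Payloads are held as doubles, exact up to
2^53, far above the largest shipped k = 37.

## Grid geometry

`2^⌊log2(N²)⌋` cells carry the codeword; the surplus is reserved for
orientation markers in the four corners, three ON and the bottom-right
distinct, which is asymmetric under every non-trivial 90° rotation. For
generic N the corner block side is the largest s with
4s² ≤ N² − 2^⌊log2(N²)⌋; this reproduces the 3×3 blocks of the 10×10 layout
(36 marker + 64 data cells) and the 2×2 blocks of the 12×12 layout
(16 + 128). The 17×17 layout is special-cased as three 3×3 ON corners plus a
3-row × 2-column OFF block at the bottom-right corner (33 + 256); the
published budget fixes only the count, so the geometry is this package's
declared convention. Codeword bits fill data cells in raster order
(top-left → bottom-right, skipping markers); coordinates are (row, col) from
the top-left, rotations counter-clockwise.

The encryption mask is a fixed, seed-reproducible half-ON/half-OFF pattern
XOR-ed onto the data cells (markers are never masked — they must stay
readable before the mask can be removed). Masking balances ON/OFF counts
regardless of payload, which helps recognition, and acts as a decipher key.
Data-cell bits are i.i.d. Bernoulli(1/2), redrawn until the ON fraction lies
in [0.4, 0.6]. This is obfuscation, not cryptography.

Orientation detection tries all four rotations of an observed grid and
scores marker mismatches; an exact tie is surfaced as an ambiguity error
rather than a guess. Because all marker cells move onto marker cells under
90° rotations, a wrong rotation scores ≥ 2 × (distinct-corner size)
mismatches on intact markers, which is why a few marker-bit losses never
flip the decision.

## The synthetic imaging model

`render_patch()` draws, per image and deterministically from its seed:
rotation in [−5°, +5°], scale factor in [0.95, 1.05], translation within
±4 px, per-spot peak brightness in [0.55, 0.95] (normalized units),
Gaussian background (level 0.08, noise σ 0.02), defocus blur σ in
[0.3, 1.0] px, motion-blur length up to 3 px at random angle, and
gain/exposure in [0.9, 1.1] each, clipping to [0, 1]. ON cells become
isotropic Gaussian spots of width σ = pitch/6 (the simplest point-spread
shape consistent with round intradermal deposits); pitch defaults to
`max(8, floor(200/N))` px — 20 px for 10×10 — inside a 256×256 frame, the
recognition input contract. Rotation, noise and blur magnitudes beyond the
±5° rotation range are not published; the remaining ranges are this
package's declared defaults, chosen so that spots stay well-resolved at the
17×17 pitch while the full chain is still visibly stressed (visible noise
floor, occasional motion streaks).

Temporal degradation removes whole bits: each ON cell survives with
probability equal to the retention level, independently; OFF cells never
turn ON. Dataset generation mixes retention levels 1.00/0.75/0.50/0.25 in
proportions 5/15/60/20% and additionally attenuates surviving spot
brightness by a uniform factor in [0.6, 1.0], since bit loss and per-bit
dimming are tracked separately in longitudinal patch data. An alternative
reading — thinning pixels *within* spots rather than dropping whole bits —
is available through the attenuation knob but whole-bit dropout is the
default, because retention is scored in bits. Impulse augmentation
(salt-and-pepper, erased rectangles, optional blur) reproduces the
corruption family used to harden binarization.

What the simulator does **not** model: physically based light transport,
skin autofluorescence spectra, perspective distortion, sensor-specific
noise, patch deformation from skin growth. Passing tests therefore show the
codec is correct and robust over the declared variation space, not that it
is validated on real skin imagery.

## The classical vision chain

* **Binarization**: pixel ON iff its value exceeds the local mean over a
  window (default two pitches + 1 px, so one spot plus surround) by more
  than an offset of 0.02 — 2% of the dynamic range. A constant image
  therefore reads all-OFF.
* **Cleanup**: connected components below 9 px, or below half the median
  size of the surviving components, are removed. Spots at one pitch are all
  of comparable area while thresholded noise clumps are several times
  smaller, so the relative rule separates them without absolute size
  assumptions; without it, rare blurred-noise clumps inflate the enclosing
  rectangle and shear the cell lattice.
* **Rectification**: minimum-area rotated rectangle of the foreground via
  rotating calipers on the convex hull; the image is rotated by the
  recovered tilt (folded into (−45°, 45°]), cropped to a square 35% larger
  than the rectangle's long side about its centre, and resized (bilinear) to
  256×256. The residual 90° ambiguity is deliberately left to the marker
  stage: markers, not image moments, define orientation.
* **Reading**: the patch occupies the central 1/1.35 of the rectified frame;
  each of the N×N cells is scored by mean intensity over its central 50%
  (guarding against pitch misregistration bleed), and cells are labelled by
  a two-class 1-D 2-means split seeded at the score extremes, ties toward
  OFF. A degenerate (constant) score field returns all-OFF with a warning.

No stage takes a per-image parameter, matching the fully automatic decoding
goal. Learned stages (a U-Net-style binarizer, a convolutional grid reader)
are deliberately not included: the classical chain meets every acceptance
property on its own, and the package's scope is the codec, not model
training.

## Analytics

`signal_retention()` counts detected bits per timepoint (adaptive threshold
→ cleanup → connected components) and reports the percentage of the
baseline transferred total — e.g. 96 for the 10×10 retention patches with
four needles removed from one corner for orientation. `signal_intensity()`
reports the maximum pixel value inside each ON bit's cell; since brightness
is only meaningful at fixed acquisition settings, results carry a settings
id and cross-settings comparisons error unless explicitly overridden.

## Problem sizes used by the test suite

The suite verifies decoding against a brute-force nearest-codeword oracle
exhaustively for RM(0,3), RM(1,3), RM(1,4) and RM(2,4) (every codeword ×
every error pattern of weight ≤ t, ~58,000 decodes), runs 1,000 seeded
flip-and-decode trials at the exact radius for RM(1,6), RM(2,7) and RM(2,8),
decodes 100 rendered payloads end-to-end per grid side in {10, 17} (with a
four-rotation sweep on ten of each), and 100–120 trials of the 1.56%
per-bit-loss longitudinal simulation. Tier-mix composition is checked on a
10,000-sample manifest. These sizes were chosen to give exhaustive coverage
where enumeration is tractable and tight binomial/multinomial tolerances
elsewhere.

## Known limitations

* Marker geometry for 17×17 and the mask bit stream are package conventions;
  patterns fabricated from other implementations of the same published
  budgets will not interoperate bit-for-bit.
* The reader assumes the whole patch is in frame and is the only bright
  structure; overlapping patches and partial crops are out of scope.
* Decode success under heavy loss (retention ≤ 0.5 on 10×10) degrades as the
  channel exceeds t = 15; the evaluation harness reports, but never
  promises, success there.
* Runtime is logged, never asserted: published per-image processing speeds
  are hardware-bound quantities.
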