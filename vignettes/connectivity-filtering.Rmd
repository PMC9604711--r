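---
title: "Connectivity filtering for vessel segmentation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity filtering for vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LSCFilter)
```

## The problem

Multiscale Hessian vesselness filters enhance tubular structures well, but
a fixed gray-level threshold on their response leaves two characteristic
defects: scattered single-pixel responses in background ("salt noise"),
and breaks in genuine vessel branches where the local contrast dips. Both
defects are topological, not photometric, which is why a second threshold
or smoothing pass does not fix them. This package repairs them with two
unsupervised filters built on one primitive: the per-pixel *connectivity
score*.

## Connectivity scores and the CF

For a binary mask and a chosen pixel adjacency, the connectivity score of
a vessel pixel is the number of foreground pixels in its connected
component (the pixel counts itself). Scores are computed by an iterative
worklist flood fill — deliberately not recursion, since a single retinal
vessel tree can span tens of thousands of pixels and would overflow any
call stack. Scores are stored as unbounded integers; the 8-bit clamp
exists only in `renderScores8bit()` for display, because the decision
threshold must act on true counts.

The Connectivity Filter keeps pixels with score strictly greater than
`sMin`. At the default `sMin = 1` this removes exactly the isolated
single pixels and keeps every component of two or more pixels — a
set-identity we test, not just a tendency. `sMin` is exposed because
other regimes (e.g. suppressing all fragments below a minimum plausible
vessel length) are legitimate.

## Adjacency: the Rodrigues distance

Adjacency is defined by thresholding a two-term point distance, a weighted
sum of a Minkowski and a Chebyshev part:

$$d_{w_1,w_2,p}(a,b) = w_1 \Big(\sum_{i=1}^{2} |a_i-b_i|^p\Big)^{1/p} +
w_2 \max_{i=1,2} |a_i-b_i|.$$

With unit weights ($w_1=w_2=p=1$), offsets at distance $\le 2$ are the 4
orthogonal neighbors and $\le 3$ the full 8-neighborhood. The default
radius is 3 (8-connectivity) because vessels run diagonally as often as
not; radius 2 is available for stricter connectivity. Neighbors are
always enumerated in a fixed clockwise order starting at North, ties at
equal angle broken by increasing distance, which makes every traversal in
the package fully deterministic. The momentum variant rotates this cyclic
order so that the direction of the previous move comes first.

## The LS-CF

The local-sensitive filter extends the traversal with a tolerance
heuristic. Conceptually each component sends walkers off the vessel into
background, looking for a different component to re-link:

* a walker's **tolerance score** is its excursion depth — the count of
  consecutive background pixels visited since it left the vessel — and
  may not exceed `maxScore` (default 350);
* every step must stay within `maxDist` pixels of the vessel pixel the
  walker departed from, measured by the Chebyshev term of the traversal
  metric (default 4);
* neighbors are expanded momentum-first, emulating a brush stroke;
* when a walker touches a vessel pixel of a different component, the
  realized path is painted as vessel, recorded in the `bridged` mask, and
  the two components merge; the traversal then continues on the merged
  component, so chains of fragments re-link transitively;
* walkers that exhaust their budget leave no trace.

Final scores are merged-component cardinalities including bridge pixels,
preserving the invariant that one component carries one score. Because
bridges are the only pixels ever added, vessel thickness away from
bridges is untouched, and with `maxScore = 0` or `maxDist = 0` the output
is bit-identical to the CF — both properties are asserted in the test
suite.

### Design choices that were genuinely open

**Excursion realization.** The excursions are implemented as one
multi-source breadth-first wave per component: all member pixels seed the
wave simultaneously and the first contact with another component is
therefore a globally *shortest* admissible bridge. An earlier candidate
design launched an independent walk from each vessel pixel in flood-fill
order; it re-linked the same fixtures, but an interior pixel could reach
the far side first through an equal-length detour that skirted the vessel
body, so the painted bridge was not the geometric gap. The wave
formulation keeps the painted pixels on the gap itself — thin links, not
blobs — which is what the method's figures of merit (bridge-on-path,
thickness preservation) require.

**Budget semantics.** The two budgets could be read as one cumulative
per-component counter. That reading collapses in practice: a radius-4
excursion disk holds ~80 background pixels, so a cumulative budget of 350
would be spent by a handful of failed excursions and bridging would
silently shut off on any realistic tree. Reading the tolerance as
per-excursion depth also matches the observation that the distance cap is
an optional accelerator: the depth cap alone terminates every walk, the
spatial cap only prunes the search.

**Distance units.** The excursion radius is measured in pixels (the
Chebyshev term), not by the full two-term metric. Under the full metric a
straight run of $k$ pixels is at distance $2k$, so the default radius 4
could never span the 2–3 pixel gaps the method is designed to close;
in pixel units the default bridges gaps up to 4 pixels (diagonal or
straight) and provably cannot reach across 6, which is the sharp
behavior the gap-orientation tests pin down.

**Bridges are output, not substrate.** Painted bridge pixels are recorded
and scored but are not themselves used as new excursion anchors within
the same run. This keeps the result a function of the input geometry
rather than of paint order; transitive re-linking still happens because
merged components re-grow their wave.

## The closing baseline

The comparison baseline composes the CF with a morphological closing by
the radius-1 cross structuring element (dilation then erosion); the
alternative order (closing first) is exposed as `closingFirst = TRUE`
because both orderings appear in practice. Closing is evaluated with
plane semantics: the mask is embedded in a background plane (zero padding
by the kernel radius), closed there, and cropped back. The alternative —
clipping the dilation at the image border — silently violates
extensivity: a foreground pixel touching the border gets eroded away, so
the mask is no longer a subset of its own closing. Plane semantics keep
the operator extensive, idempotent and monotone up to the edge, and the
test oracle (independent set arithmetic) uses the same embedding.

A one-pixel-wide line with a one-pixel gap is *not* re-linked by the
cross closing — the erosion removes the painted gap pixel for lack of
transverse support. The re-linking behavior closing is known for needs
structures at least as thick as the element; the tests therefore use
3-pixel bars for the closing cases, while LS-CF re-links the 1-pixel
line directly. This asymmetry is the heart of the comparison: closing is
a global operator that cannot span gaps wider than the element, while
the LS-CF search is local and orientation-free.

## The vesselness front end

No pre-installed R package provides a Frangi-type filter, so the package
ships a standard multiscale Hessian-eigenvalue vesselness: Gaussian
scale space (separable smoothing with replicated borders),
scale-normalized second derivatives by central differences, the classic
blobness/structureness formulation
$\exp(-R_b^2/2\beta^2)\,(1-\exp(-S^2/2\gamma^2))$ with the response
suppressed where the dominant curvature has the wrong sign, and the
maximum over scales. Defaults: scales 1–8 step 1, $\beta = 0.5$,
$\gamma = 15$ (8-bit intensity units), `invert = TRUE` for dark-vessel
modalities (the fundus green channel), `FALSE` for bright-vessel
angiograms. Any user-supplied engine with the same contract (matrix in,
matrix out, larger = more vessel-like) can replace it via the `fun`
argument.

Two conventions matter downstream. The native real-valued response is
linearly rescaled to 8 bits (minimum to 0, maximum to 255; a constant
response maps to zero) before the fixed gray-level threshold — min–max
rescaling is the main source of drift against other implementations of
the same filter, and the threshold (default level 100, strictly greater)
is therefore configurable. Per-modality tuning affects this front end
far more than the connectivity stages.

## The synthetic phantoms

The generator draws correlated random walks: branches of configurable
length and width on one of the 8 principal directions per step, turning
±45° with probability `turnProb`, later branches budding from earlier
ones. `punchGaps()` cuts runs of recorded length along the local branch
direction (so geometric gap length equals nominal length, making the
`maxDist` pass/fail boundary sharp) and records the exact removed pixels;
`addSaltNoise()` injects isolated pixels with an explicit Chebyshev
clearance `margin` from all other foreground. Everything is seeded and
bit-reproducible, and each degradation is recorded in the fixture, so
recovery can be scored exactly.

Two fixture conventions are themselves modeling choices. First, the
composite fixtures place noise with `margin = 6`, beyond the default
bridging radius: they emulate background clutter away from the
vasculature, which is the regime in which noise removal and gap bridging
are separable properties. Noise dropped within the bridging radius of a
vessel would be re-linked by design — the method treats "unsegmented
pixels near highly connected vessels" as probable vessel, and clutter
adjacent to vessels is genuinely ambiguous at this level. Second, the
phantoms are thin (default width 1): they emulate the skeleton geometry
of a thresholded vesselness response, not its caliber profile, contrast
gradients, or the vessel-edge doubling a real response can show. Passing
these tests therefore demonstrates the topological behavior of the
filters, not end-to-end accuracy on any particular imaging dataset —
dataset-scale accuracy additionally depends on the vesselness
parameterization, which is outside the filters themselves.

Problem sizes in the shipped tests and acceptance script — 64×64 random
masks (200 for the labeling cross-check), 96×96 phantoms (50 for the
method comparison), 128×128 for the noise study — were chosen as the
smallest grids on which every phenomenon of interest (multi-component
trees, multiple gaps, >100 noise pixels) occurs comfortably; all
quantities are rates or means that are stable across seeds at these
sizes.

## Evaluation conventions

Metrics are the vessel-literature standard: TP rate (sensitivity), TN
rate (specificity) and accuracy, in percent. A rate whose denominator is
zero is reported as `NA`, never as 0. Field-of-view restriction is
supported but **off by default**, and every report records the resolved
configuration — whether metrics were computed inside an FOV mask changes
specificity materially, so the choice is made explicit rather than
guessed. The identity
$\mathrm{acc} = \mathrm{TPR}\cdot\pi + \mathrm{TNR}\cdot(1-\pi)$ (with
$\pi$ the foreground prevalence) is used as a self-check in the tests.

## Known limitations

* Bridging is purely geometric: a fragment of clutter within `maxDist`
  of a vessel will be re-linked, indistinguishable from a true branch.
* The score threshold is global; the interaction between higher
  connectivity scores and fragment survival under different thresholds
  is left to the user (`sMin` is a free parameter).
* Adjacency and distances are 2-D and isotropic; there is no 3-D
  neighborhood and no anisotropic pixel spacing.
* The built-in vesselness is a faithful but plain implementation —
  no per-dataset parameter sets are bundled, and min–max rescaling ties
  the 8-bit threshold to the image's own response range.
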