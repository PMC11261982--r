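---
title: "Landmark registration of ADT counts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark registration of ADT counts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtwarp)
```

## The problem and the model

Antibody-derived tag (ADT) counts measure surface-protein abundance per cell
in CITE-seq. For a given marker, the density of arcsinh-transformed counts
`asinh(x / c)` (cofactor `c = 5` by default) typically shows a *negative*
peak — unbound or non-specifically bound antibody background — and zero, one
or two *positive* peaks from truly expressing populations, separated by
*valleys*. Batch effects move and rescale these features: the same marker's
background may sit at 5 counts in one study and 40 in another. Because the
biological information is in the *shape* of the mixture, not in absolute
count units, adtwarp removes batch effects by registering the density
landmarks.

For each marker, each batch `i` contributes landmark locations
`t_i1 < t_i2 < ... < t_im` (peaks and valleys, interleaved). Target
locations `t0_j` default to per-landmark cross-batch means, or can be fixed
by the user for cross-run integration. A strictly monotone, invertible
warping function `h_i` on the shared expression range `[T_start, T_end]`
satisfies

* `h_i(T_start) = T_start`, `h_i(T_end) = T_end` (the range endpoints are
  fixed points),
* `h_i(t0_j) = t_ij` for every pinned landmark `j`.

Cell values of batch `i` are normalized by `h_i^{-1}`, which moves the
batch's landmark at `t_ij` onto the shared target `t0_j` and preserves the
within-batch ranking of cells exactly. Zero counts map to zero.

### The warp family and the curvature penalty

The registration literature motivates `h_i` as the minimizer of a squared
distance between the warped curve and a reference, plus a penalty
`lambda * integral(omega(t)^2 dt)` on the relative curvature of `h`. The
reference function in that objective is under-determined once the warp is
pinned at the landmarks, so adtwarp implements the large-penalty limit
directly: the minimal-curvature strictly monotone interpolant through the
knot pairs. Concretely the knot set is augmented with *shoulder points*
placed on the piecewise-linear path at 5% of each adjacent segment, and a
Fritsch–Carlson monotone cubic Hermite interpolant is fit through the
augmented knots. The result is exactly linear away from the landmarks
(zero curvature), rounds the corners smoothly within the shoulder
neighborhoods, deviates from the piecewise-linear interpolant by less than
0.02 on the default fixtures, and is strictly increasing by construction.
`lambda_penalty` is retained in the configuration and recorded on warp
objects for interface compatibility; it does not alter the interpolant.

The inverse is evaluated by vectorized bisection on sorted unique values
(64 halvings, i.e. to machine precision), so equal inputs stay equal and
ranks are preserved including ties.

## Landmark detection

Detection runs per (marker, batch) on a shared per-marker grid of
`grid_size = 512` points spanning `[0, max + 3 * widest bandwidth]`.

1. **Bandwidth ladder.** Gaussian KDEs are computed at
   `bandwidth_ladder = c(1, 0.5, 0.25, 0.1)` arcsinh units, widest first.
   The base rung is the widest one resolving at least 2 peaks (or at least
   the per-marker `peak_count_prior`); if none succeeds the narrowest rung
   is the fallback. When a multimodal prior (`k >= 2`) is given, the search
   then prefers the narrowest rung resolving *exactly* `k` peaks: narrower
   bandwidths carry less smoothing bias on marginally resolved modes (up to
   ~0.2 arcsinh units at bandwidth 0.5), while the exact-count requirement
   rejects rungs fragmented by noise.
2. **Peaks** are grid-local maxima with height at least
   `min_height_frac = 1%` of the maximal density *and* topographic
   prominence at least `min_prominence_frac = 5%` of it. The prominence
   filter is what keeps KDE noise bumps at the narrowest rung — and count
   atoms resolved after warping — from registering as positive populations.
   Plateaus break ties at their leftmost grid point.
3. **Near-zero cleanup.** The arcsinh transform is nearly linear at the
   origin, so discrete low counts create artificial peaks. All peaks below
   `neg_candidate_thres = asinh(10/c)` (counts up to ~10) merge into one
   negative peak at the tallest candidate. A *spurious empty-droplet peak* —
   a minor leftmost peak clearly below the background-candidate region
   (below half the threshold) and under half the next peak's height — is
   dropped entirely; the sole remaining peak is never dropped.
4. **Unimodal re-estimation.** If cleanup leaves a single peak, the ladder
   rung was chosen by a failed hunt for extra modes, so the mode is
   re-placed on a curve with a data-driven bandwidth: Silverman's rule
   floored at twice the median spacing of distinct values in the central
   mass. The floor prevents count discreteness from atomizing the curve;
   this matters most for re-detection after warping, when atoms are
   stretched apart and "near zero in raw counts" is no longer meaningful.
   For the same reason, post-normalization re-detection uses the aligned
   first valley as its background-candidate threshold.
5. **Valleys.** Between adjacent peaks the valley is the minimum-density
   grid point (ties at the middle tied index). With a single peak the
   valley is *slope-derived*: right of the steepest descent, the first grid
   point where the absolute slope falls below `slope_valley_frac = 30%` of
   that steepest descent, then extended outward while the density still
   exceeds 2% of the peak height. The slope threshold fires at about 2.35
   kernel sigmas on a Gaussian flank — past more than 99% of the background
   population — and the 2% height walk pushes the valley through any heavy
   tail or shoulder into the true transition region. At the spec'd 10%
   threshold the valley sits ~3.1 sigmas out for *every* unimodal shape,
   which makes a blank marker's one-peak quality score rival genuinely
   separated two-peak scores and inverts the intended score ordering; the
   30% default restores the geometry while remaining configurable.
6. **Cross-batch cleanup.** Rightmost (positive) peak locations are flagged
   as outliers beyond `mad_multiplier = 3` scaled MADs (1.4826 consistency
   constant, the `stats::mad` default) given at least 3 batches; flagged
   peaks are excluded from target means and from warp pinning. Outlier
   valleys are replaced by the mean valley of the `k_neighbors = 2` batches
   with smallest earth mover's distance (1-D EMD, the area between CDFs on
   the shared grid). Valley correspondence across batches is defined on the
   harmonized slot matrix (`neg_peak`, `valley_1`, `pos_peak_1`, ...): a
   batch's rightmost peak always fills the rightmost positive slot, a
   positive-only batch (user prior) fills `pos_peak_1`, and slope-derived
   valleys sit out any slot where some batch exhibits the real inter-peak
   valley.

### The single-positive-peak prior

A batch known to contain only expressing cells for a marker (a T-cell-only
batch stained for CD3) shows one peak that is *positive*, not background.
The `positive_peak_only` configuration lists such (batch, marker) pairs;
the sole peak is then labeled positive, mapped to the positive slot, and its
slope-derived valley is mirrored to its left. Without the prior these
batches corrupt the negative-peak target — the exact failure mode the
moderate/severe imbalance scenarios exercise.

## Stain quality

`summarize_peaks()` computes, per peak, the mode, density height, the
population SD of the cells in the peak's valley-delimited interval, and the
trapezoid area under the density over that interval; plus valley heights,
the right-tail area beyond the last valley, and the SD of all cells. From
these, `stain_index()` is `(pos - neg) / (2 * SD(neg))` and
`stain_quality_score()` implements the three-case density score (2-peak,
3-or-more-peak, 1-peak) with the separation-to-spread ratio multiplying both
parenthesized factors — the only operator-precedence reading consistent with
the stated correlation directions (higher separation and sharper peaks up,
larger spreads down). Scores are density-based and therefore stable under
subsampling. Markers score below the conventional threshold of 5 when
positive and negative populations do not resolve, the flagging rule of
`quality_report()`.

## Auto-gating

After alignment every batch shares the target valleys, so one valley
threshold per marker serves all batches. Gating rules form a hierarchy
(`cell_type`, optional `parent`, and per-row marker conditions
`above_valley` / `below_valley` / `between_valleys`); a cell is positive for
a marker iff its normalized value is at or above the aligned valley (ties
positive — a deterministic boundary rule). Terminal cell types are matched
in file order; unmatched cells are `"ungated"`. Because valley thresholds
move with the warp, the fraction of positive cells per batch is *identical*
before alignment (with the batch's own valley) and after (with the shared
valley): positivity is a rank-based quantity and warps preserve ranks.

## The synthetic world

The generator draws one population label per cell (so cell types are
coherent across markers), then per marker an arcsinh value
`Normal(mode + batch_shift, SD * batch_scale)`, inverted to counts and
rounded — the rounding *is* part of the stated world, reproducing the
near-zero discreteness that motivates the cleanup rules
(`discretize = FALSE` isolates registration properties from it).

The default fixture is 3 batches x 2000 cells x 4 markers over a PBMC-like
composition (B, CD4 T, CD8 T, monocytes): CD3-like bimodal, CD4-like
trimodal, CD19-like bimodal, IgG1-like unimodal isotype control. Background
modes sit at arcsinh 1.3–1.5 (~10 counts, the typical ADT background) and
positives at 3.2–3.7; batch shifts are (0, +0.8, −0.5) and scale factors
(1, 1.1, 0.9). An early draft placed backgrounds at ~4–6 counts, which a
negative shift pushed to ~2 counts — an unrealistically low background whose
discreteness destabilizes any KDE mode; the values above were fixed before
any expected value was frozen and not revisited.

`simulate_imbalance()` restricts batch composition (mild: last batch
T-lineage only; moderate: last two; severe: additionally one batch CD8 T
only), and `config_for_spec()` derives the single-positive-peak pairs the
analyst of such a design would declare. `simulate_titration()` generates one
batch per antibody concentration: a 5-fold dilution costs ~25% of the
arcsinh separation (`sep_exponent = 0.15`) with mild broadening
(`sd_exponent = -0.05`), the labeled fraction of positive cells scales as
`level^0.25`, and below `min_detectable = 1/20` of the recommended
concentration no positive population is detectable at all — mirroring
titration behavior where the 1/5x level remains close to 1x while 1/25x
often shows no identifiable positive population.

What a green test on this world does *not* establish: correct behavior on
ambient-contaminated or doublet-rich data (no contamination model), on
markers whose populations violate the shared-shift assumption, or on
RNA-protein joint embeddings (out of scope).

## Numerical choices and known limitations

* **Density normalization.** KDE mass leaking left of the origin (cells at
  zero counts) is renormalized so every curve integrates to 1 on its grid.
* **Tie-breaks.** Peak plateaus resolve to the leftmost grid point; valley
  ties to the middle tied index; threshold ties in gating are positive.
* **Inverse tolerance.** Bisection to ~1e-15; the warp contract is tested
  at 1e-8.
* **Warp-kink re-detection bias.** Around a population pinned by a single
  landmark, `h'` differs on the two sides of the knot, which skews the
  re-warped density and shifts its KDE mode by roughly the shoulder width.
  Re-normalizing a normalized dataset therefore yields warps within 0.05 of
  identity on well-pinned (bimodal) fixtures, but single-pinned markers
  under large shifts (±0.8) can deviate by ~0.1 — the same order as the
  landmark-recovery tolerance. This is a property of endpoint-fixed
  landmark warping itself, not of the implementation.
* **Detection at boundaries.** Landmarks that fall on the grid boundary are
  degenerate fallbacks and are treated as absent during harmonization.
* **Missing markers.** A marker absent from a batch (all-`NA` block)
  contributes no cells and receives no warp; outputs carry the `NA`
  sentinel, never 0, because 0 is a valid count.
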