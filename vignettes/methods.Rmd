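---
title: "Methods: tracking pKa values over MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking pKa values over MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpka)
```

## The procedure and its assumptions

`trajpka` treats per-structure pKa prediction as a black box applied
frame-by-frame to an MD trajectory. The pipeline for each sampled frame
is: extract coordinates → normalise residue names → (optionally) apply
alanine pseudo-mutations → hand the structure to the engine → parse the
per-residue predictions. The per-frame results are merged into a frames ×
residues table sorted by frame time, from which all downstream analyses
derive.

Three assumptions are built in:

1. **The ensemble is preprocessed.** Frames are expected to be aligned,
   imaged and chemically complete; the loader only strips waters and ions
   (configurable). No coordinate manipulation beyond side-chain truncation
   is ever performed.
2. **Fixed protonation states.** The input is conventional MD, where
   protonation cannot respond to the environment. The analyses therefore
   flag *inconsistencies* — e.g. a residue whose predicted pKa crosses the
   simulation pH — rather than resolving them; that is the province of
   constant-pH methods, which this package does not replace.
3. **The engine is deterministic per structure.** This is what makes the
   parallel decomposition exact: frames are split into contiguous worker
   ranges, and the merged output is byte-identical for any worker count.

## Engines

External engines are invoked through their command-line entry points
(`propka3`, `pKAI`) on a temporary single-model PDB per frame; both the
snapshot and the engine output are deleted after parsing. Their energy
models are never re-implemented. Model pKa values for external engines are
parsed from the engine's own output.

The built-in engine exists so that every pipeline property is exactly
checkable. Its prediction is closed-form: for ionizable residue $i$,

$$\mathrm{p}K_{a,i} = \mathrm{p}K_a^{\mathrm{model}}(\text{type}_i)
  + 0.1\,d_i, \qquad
  \text{buried}_i = 100\,\max(0, 1 - d_i/20),$$

where $d_i$ (Å) is the distance from residue $i$'s heavy-atom centroid to
the centroid of the *backbone* atoms (N, CA, C, O) of the whole structure.
Using the backbone centroid as the global reference — rather than the
all-atom centroid — is deliberate: side-chain truncation cannot move it,
so pseudo-mutating residue $j$ provably leaves residue $i$'s prediction
unchanged, which turns mutation locality into an exact (bitwise) test
rather than a tolerance test. The prediction is translation-invariant, and
the model table (Asp 3.80, Glu 4.50, His 6.50, Cys 9.00, Tyr 10.00,
Lys 10.50, Arg 12.50) holds typical solution reference values.

## Pseudo-mutation

A pseudo-mutation truncates a residue to the alanine atom set
{N, CA, C, O, CB} (keeping backbone/β hydrogens and OXT when present) with
original coordinates, and renames it ALA. No CB rebuilding, rotamer
sampling or minimisation follows: the feature is a *coordinate-preserving
probe* of a neighbour's contribution to pKa shifts in the wild-type
ensemble, not an estimate of mutant pKa values (which would require
sampling the mutant ensemble). Glycine targets are rejected (no CB);
proline is allowed, its ring atoms simply removed. Two statistics
summarise the effect on a probed residue: the mean shift of its pKa
profile and the fluctuation ratio $\sigma_{\mathrm{mut}}/\sigma_{\mathrm{wt}}$,
which separates a uniform offset from a change in the profile's shape
(e.g. the loss of an intermittent hydrogen bond damps fluctuations).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `stride` | 1 | frames | keep every stored frame; raise to subsample |
| `timestep_ps` | 1 | ps | PDB trajectories carry no time; set to the true sampling interval (e.g. 100 ps) |
| `n_workers` | 1 | — | contiguous block split; output invariant to the choice |
| `reference_ph` | 7.4 | pH | physiological reference for sensitivity flagging |
| `half_width` | 1.0 | pKa units | pH ± 1 spans roughly 10–90 % protonation, the range where both states are significantly populated |
| running-average window | 5 ns equivalent | frames (odd) | converted from a time span via the timestep; even counts rounded up to stay centered |
| histogram `bin_width` | 0.1 | pKa units | fine enough to resolve sub-unit shifts; bins left-closed, aligned at 0 for reproducible counts |
| correlation `method` | Pearson | — | the use case is linear coupling to PC projections; Spearman available |
| correlation `threshold` | 0.5 | — | flags "large" couplings; values are kept signed and ranked by absolute value |

## Clustering design

Features are Z-scored with the **population** standard deviation
(denominator $n$) so that a column's normalised variance is exactly 1;
constant columns carry no information and are dropped with a warning.
Distances between residues use the **minimum heavy-atom distance**, not
centroid distance, because contact formation (salt bridges, hydrogen
bonds) is what shifts pKa values, and closest approach detects it
directly. All methods operate on Euclidean distance in the normalised
space; PCA, when requested, keeps either a fixed component count or the
smallest count reaching a cumulative explained-variance target.

Four algorithms are exposed:

* **k-medoids** via `cluster::pam`; the representative is the medoid, and
  for ≤ 100 frames the test suite verifies medoid optimality by exhaustive
  search.
* **greedy** is the classic leader algorithm: frames are scanned in time
  order; a frame joins the first cluster whose leader is within the
  cutoff, else founds a new cluster. The cited "greedy" scheme is not
  specified in detail anywhere authoritative, so the leader algorithm —
  the standard greedy trajectory-clustering scheme with a single
  hyperparameter (the cutoff) — is used and documented as this package's
  interpretation.
* **DBSCAN** as in Ester et al.: core points have ≥ `min_samples`
  neighbours within `eps`; clusters grow by breadth-first expansion;
  unreached points are noise (label −1).
* **HDBSCAN** implemented as HDBSCAN*: per-point core distances, the
  mutual-reachability graph, its minimum spanning tree, the single-linkage
  hierarchy, condensation at `min_cluster_size`, and excess-of-mass
  cluster extraction by stability. A single root-spanning cluster is not
  selectable (no `allow_single_cluster`), matching common practice.

Silhouette widths score a clustering; noise frames are excluded from the
computation because silhouette is undefined for singleton noise
"clusters", and any result with > 50 % noise is ranked below any cleaner
result in the grid search. Grid-search ties are broken toward fewer
clusters, then grid order, making selection deterministic. A fixed seed is
threaded through every stochastic step, and identical inputs give
identical labels.

## Synthetic fixtures: what they do and do not show

The fixture generators make the whole pipeline testable offline:

* `generate_peptide()` builds an extended chain with 3.8 Å Cα spacing and
  template side-chain heavy atoms — chemically plausible and parseable,
  nothing more. There is no folding, solvent or rotamer realism.
* `generate_trajectory()` displaces atoms along fixed random unit vectors
  with a coherent sinusoidal amplitude. This gives the built-in engine's
  pKa series a deterministic periodic structure that correlation tests can
  detect exactly; it does not emulate diffusive protein dynamics,
  anharmonic transitions or solvent friction.
* `generate_blob_features()` draws $k$ isotropic Gaussian blobs with
  centres `separation_sd` apart along the first feature axis. "Unit
  variance" here is the blob's **total** variance (isotropic covariance
  $I/d$), so the spread of a blob — and therefore what a given centre
  separation means geometrically — does not change with the feature-space
  dimension $d$. With per-axis unit variance instead, the expected mean
  silhouette of well-separated blobs would decay with $d$
  ($\bar s \approx 1 - \sqrt{2d}\,\Gamma((d+1)/2)/\Gamma(d/2)\,/\,
  \sqrt{\text{sep}^2 + 2d}$, ≈ 0.78 at $d = 3$, separation 10), which
  would make "well separated" mean different things in different
  dimensions.

Passing tests on these fixtures demonstrates the *plumbing* — exact
merging, mutation locality, parser fidelity, clustering correctness — not
predictive accuracy on real proteins, which is entirely the property of
the external engine used.

## Numerical choices

* Coordinates are trusted only to PDB precision (3 decimals, Å); all
  structural round-trip comparisons use that tolerance. B-factor values
  round-trip at 2 decimals and must satisfy |v| < 1000 (column width).
* Zero-variance series yield a *missing* correlation coefficient, never 0:
  an undefined quantity must not masquerade as "no correlation".
* Z-scored columns are verified to |mean| < 1e−10 and |sd − 1| < 1e−10;
  full-rank PCA conserves total variance to 1e−8.
* Property series are matched to frames by row order when lengths agree,
  else by nearest time within half a timestep (PC-projection files
  commonly carry no time column).
* Engine failure on a frame drops that frame into a failure manifest and
  continues; only an all-frame failure aborts. Downstream time axes stay
  explainable because gaps are recorded, not silently removed.
* The problem sizes exercised by the test-suite and the acceptance script
  — 10–20-frame trajectories of a 9-residue peptide, 90-frame blob
  fixtures, n = 1000 correlation draws — were chosen as the smallest sizes
  at which each property is non-trivially testable (e.g. ≥ 3 worker
  splits, exhaustive medoid search still feasible).

## Known limitations

* Input formats are PDB (single/multi-model) topologies and multi-model
  PDB or DCD trajectories; GRO/PSF/XTC/TRR readers are not provided.
* Trajectory PCA is not computed; projections are user-supplied.
* No significance testing accompanies correlation scans; coefficients are
  descriptive.
* The pseudo-mutation probe deliberately does not relax the structure;
  its numbers must not be read as mutant pKa predictions.
* Buried ratios are only available from the empirical engine (or the
  built-in one); requesting them with the deep-learning engine is a
  validation error, not a silent omission.
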