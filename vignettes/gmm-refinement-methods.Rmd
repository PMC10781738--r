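---
title: "Gaussian-mixture refinement of atomic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-mixture refinement of atomic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryofit)
```

## The mixture model

`cryofit` describes a cryo-EM map as a mixture: every atom contributes a
spherical Gaussian

$$P_i(\mathbf v) = A_i \exp\!\left(-\frac{|\mathbf v-\mathbf x_i|^2}{B_i^2}\right),$$

and a uniform background term $E$ absorbs whatever intensity no atom
explains, so the simulated map is $M_s(\mathbf v)=\sum_i P_i(\mathbf v)+E$.
The width $B_i$ (angstrom) is the package's "B-factor": the scale of the
atom's density spread, not the crystallographic $8\pi^2\langle u^2\rangle$
(conversions are provided by `sigma_to_bcryst()` / `bcryst_to_sigma()`).
Note the exponent convention: $B^2$ enters directly, so the per-coordinate
variance of the component is $B^2/2$.

### Why amplitudes are mass-preserving by default

Two amplitude conventions are implemented. The bare convention sets
$A_i=Z_i$: the peak intensity equals the atomic number whatever the width.
The default sets $A_i = Z_i/(\pi^{3/2}B_i^3)$, so the *integral* of the
component equals $Z_i$: blurring an atom redistributes its mass but does
not create any.

The choice matters for the width update. Expectation-maximisation
re-estimates each width from the responsibility-weighted variance of the
experimental density. Under the bare convention a component that is too
wide pays no amplitude penalty: its tail responsibility stays proportional
to its own wide profile wherever the background or neighbours dominate, so
the weighted variance reproduces the current (wrong) width and the update
is self-trapping. We verified this numerically: on a 160-atom toy system
with 5 % background, width estimates started at 0.5–5 times the truth
drift to 30–75 % median error and stay there. Under the mass-preserving
convention the same experiment is well behaved — truth is a stable fixed
point and a 5x mis-set start recovers to a few percent median error within
25 iterations — because an over-wide component's amplitude shrinks as
$B^{-3}$ and the data reclaim its excess territory. Since the whole point
of the width update is that it converges from poor starting values, the
normalised form is the default everywhere (simulation, responsibilities,
synthetic generation); `normalise = FALSE` retains the bare form for
comparison.

### The width update and its fixed point

The maximisation step computes, per atom, the weighted variance
$\mathrm{var}_i=\sum_v W_i(v)\,|\mathbf r(v)-\mathbf x_i|^2/\sum_v W_i(v)$
with $W_i = M_e\,\gamma_i$. For the component above, the 3-D second moment
at self-consistency is $\tfrac32 B_i^2$, so the stored width is the
maximum-likelihood value $B_i' = \sqrt{\tfrac23\,\mathrm{var}_i}$. With
this mapping the update is an exact fixed point when the experimental map
is the model's own simulated map — a property the test suite checks both on
fine grids and against a dense brute-force oracle.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `b_floor` | 0.25 | Å | lower clamp on widths; also prevents variance collapse onto single voxels |
| `b_cap` | 2.5 (1.5 membrane) | Å | upper clamp on widths |
| `b_only_iterations` | 25 | — | width-only iterations before any positional update |
| `residue_blend` | 0.5 | — | weight of the residue-average width restraint |
| `k_gmm` | 1e5 | energy | saturation of the positional fitting potential |
| `cutoff_sigma` | 4 | — | per-atom support radius in units of the width |
| `patience` / `max_iterations` | 5 / 300 | — | convergence rule on the global-width CCC |
| `k_ens` | 1000 | energy | ensemble anchoring constant |
| `k_dens` | 50 (5–200 useful) | energy | density-guided force; map-dependent |
| `b_shift_floor` | 0.25 | Å | minimum of the shifted widths used for sampling |

The background starts from the mean intensity outside the model's
$4\sigma$ support (10 % of the map mean if there is none) and is floored at
$10^{-6}\times\max M_e$: the update multiplies by the current $E$, so zero
would be absorbing.

Two CCC conventions appear in one refinement. The convergence score follows
the method's prescription — a map simulated with one global width equal to
the stated resolution — but that score is constant while positions are
fixed, so during the width-only phase the history records the CCC under the
model's own widths (the only non-vacuous monitor there). `print()` and
`summary()` label the two phases accordingly.

## The residue restraint is a prior, not an estimator

`restrain_bfactors()` blends each width half-way (by default) towards its
residue mean every iteration. At the fixed point this keeps only half of
an atom's deviation from the residue mean. On real data, where widths vary
smoothly along the chain, this suppresses noise; on the synthetic recovery
experiment, where truth widths are drawn independently per atom, it
deliberately biases per-atom estimates (about 20 % median error instead of
5–7 % without it). The width-recovery acceptance experiment therefore runs
with `residue_blend = 0`: it measures the estimator, not the prior.

## What the synthetic generator emulates

`make_toy_model()` grows a self-avoiding bonded random walk (bond length
1.5 Å, non-bonded exclusion 1.6x bond — about the tightest van der Waals
contact seen in real structures), names atoms N/CA/C/O so residue-anchored
scores apply, alternates C/N/O atomic numbers and draws widths uniformly
from `b_range`. Ground-truth maps are the model's own simulated density
plus a uniform background (`noise_level` times the peak) and optional
seeded voxel noise. Two-conformer blends displace a contiguous segment and
average the two conformer maps; component sets split the chain into
overlapping windows blurred towards their edges.

What this does *not* emulate: secondary structure, side-chain branching,
solvent, the contrast transfer function, resolution anisotropy, or
correlated noise. Passing tests on these fixtures demonstrates the
estimator's internal consistency and its behaviour under known
heterogeneity — not performance on deposited maps.

Problem sizes were chosen so the whole suite runs in minutes on one core:
recovery experiments use a 40-residue (160-atom) chain on roughly
$40^3$ 1 Å voxels; oracle comparisons use $\le16^3$ grids with $\le5$
atoms; ensembles use 20–50 members of a 20-residue chain.

## Positional refinement: accuracy limits

Positional updates are responsibility-weighted means, so truth is an exact
fixed point; but in a densely bonded chain the update only partially
contracts towards it. Collective modes (a segment sliding along its own
density) are weakly identified at 1 Å voxels with widths up to 2 Å, and
the global-width convergence CCC saturates before they resolve. On the
standard fixture, displacements of up to 1 Å (RMSD 0.58 Å) contract to
about 0.22–0.32 Å RMSD rather than to zero. Users fitting into real maps
should treat direct-mode positional refinement as a polisher for
sub-angstrom errors, and use the relaxer mode (or an external engine via
the `relaxer` contract) when stereochemistry must be enforced.

## Ensembles: what the experiment shows

Ensemble members are drawn atom-wise from isotropic Gaussians whose
per-coordinate variance is the shifted width (minimum anchored at 0.25 Å;
a flag switches to the standard-deviation reading, since the source of the
rule does not state units), then relaxed by L-BFGS under the anchoring
potential, harmonic bonds and a density force $-k_{dens}M_e(\mathbf x_i)$
with analytic trilinear gradients. The ensemble map is the voxel mean of
the members' simulated maps.

On a two-conformer fixture the ensemble map scores a higher support CCC
than the anchor model it was built from and than every individual member —
consistently across seeds. Two subtleties deserve honesty. First, a single
model whose widths were EM-refined against the heterogeneous map already
encodes much of the heterogeneity in its width field, and in global CCC it
can tie with the ensemble map: member spread and member widths both carry
the same variance, so the ensemble map is slightly over-blurred. Second,
width inflation around one conformation raises the mixture's mass-matching
objective but can *lower* CCC relative to a sharp single-conformer model;
whether the ensemble also beats the sharp generating conformers is
therefore fixture-dependent. The acceptance experiment reports the robust
comparison (ensemble versus the models of its own pipeline), which is also
the comparison the ensemble-representation idea is about. `k_dens` is
map-dependent by design; the heterogeneity experiment uses 200, the top of
the useful range, because the displaced segment must be reachable against
the anchoring force.

## Composite maps

Component simulated maps keep a shared atom (matched by chain, residue
index and atom name against the consensus) only in the component where its
width is smallest — ties go to the first component by input order, so
results are order-stable. Responsibilities $\gamma_c = M_c/\sum_c M_c$
then blend the (trilinearly resampled) experimental maps; at every included
voxel the composite is a convex combination, which is what removes seam
artefacts. Voxels where all components simulate zero are excluded and
report zero.

## Local scores

LoQFit masks both maps with a soft-edged sphere (diameter five times the
global resolution, raised-cosine falloff over three voxels — the standard
choice that suppresses mask-induced FSC ringing) centred on each residue's
C$\alpha$ (C1′ for nucleotides), and reports the resolution at which the
shell-wise FSC first crosses 0.5, linearly interpolated; perfect agreement
is censored at the Nyquist resolution $2\times$ voxel size. SMOCf computes
the Manders overlap $\sum ab/\sqrt{\sum a^2\sum b^2}$ between simulated
and experimental density over the voxels within $4\sigma$ of a sliding
9-residue window (window length is a flag; its source reference gives no
size).

## Numerical choices and degenerate inputs

* Accumulation is double precision; MRC files are written float32.
* Per-atom supports are hard-truncated at `cutoff_sigma` x width; the
  truncation error is bounded by $e^{-\mathrm{cutoff}^2}$ times the
  amplitude.
* Atoms with non-positive total weight (empty or negative density) keep
  their parameters and are flagged rather than producing NaNs.
* A width update from a single bright voxel clamps to `b_floor`; without
  the residue restraint a few atoms can collapse to the floor on noise-free
  maps (the classic mixture variance degeneracy — one reason the restraint
  exists).
* "No improvement" means a CCC gain of at most $10^{-6}$, a float-noise
  guard.
* The relaxer halves its step on any energy increase and stops with a
  diagnostic if the step collapses below $10^{-10}$.
* Ties in composite retention and in the FSC 0.5 crossing (first bracket
  from low frequency) are resolved deterministically.
* Refinement is fully deterministic; only ensemble sampling consumes
  randomness, each member from its own seed.

## Known limitations

Single-Gaussian atoms (no multi-Gaussian scattering factors), no
resolution-dependent filtering of simulated maps, no symmetry handling,
no map alignment (composites assume pre-aligned inputs), isotropic
per-atom widths, and the built-in relaxer enforces only bonds and a
soft-sphere exclusion — real force-field work should attach an external
engine through the `relaxer`/member-relaxation contracts.
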