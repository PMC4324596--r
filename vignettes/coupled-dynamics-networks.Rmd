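---
title: "Coupled-dynamics networks: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-dynamics networks: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnet)
```

## The model

`cdnet` treats a protein's internal dynamics as a weighted network. The
input is a conformational ensemble: `F` snapshots of the same atoms.
Because absolute coordinates mix internal motion with rigid-body tumbling,
every analysis starts (unless disabled) from an iterative least-squares
superposition: each frame is Kabsch-fitted on the Cα selection to a
reference that begins as the raw mean structure and is re-estimated as the
mean of the fitted frames until it moves less than `tol`. Initialising
from the mean rather than from frame 1 makes the operation idempotent: an
already-aligned ensemble passes through unchanged. When frames are so
strongly rotated against one another that their raw mean collapses (the
radius of gyration of the mean falling well below the frames' own — a
degenerate reference that can trap the iteration), the initial reference
falls back to frame 1. One caveat is inherent to any superposition: a
nearly collinear or planar structure leaves the fitted rotation
under-determined about its degenerate axis, and fluctuation statistics
then depend on that arbitrary gauge; this is a property of the input, not
of the algorithm.

On the aligned ensemble, with `Δr_i(t) = r_i(t) − ⟨r_i⟩`:

* `RMSF_i = sqrt(⟨|Δr_i|²⟩)` — per-residue flexibility in Å;
* `C_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` — the scalar-product
  dynamic cross-correlation, in `[−1, 1]`.

The scalar-product convention is a deliberate choice: the literature also
contains per-component (3N×3N) covariance analyses, but the network
construction needs one number per residue pair on a bounded scale, and the
scalar-product form is the standard dynamic cross-correlation map. A
residue with zero fluctuation has no defined correlation; such entries are
reported `NA` and never become edges — reporting 0 would fabricate
"no coupling" where there is simply no signal.

### The coupling graph and its critical cutoff

All residue pairs form a complete graph weighted by `|C_ij|`
(anti-correlated motion is still coupling; the signed variant is available
via `use_abs = FALSE`). Edges below a cutoff are eliminated — retention is
inclusive, an edge exactly at the cutoff survives — and the cutoff is
chosen where the largest connected component first comprises at most half
of all residues. Operationally: candidates are the distinct edge weights,
`f(c)` is the largest-component fraction with edges `≥ c` retained
(computed for all candidates in one union-find sweep, so `f` is exactly
non-increasing), and the selected cutoff is the smallest candidate with
`f(c) ≤ 0.5`. This sits at the connectivity transition of the network and
involves no free parameter. Two warnings guard the corner cases: if no
candidate reaches the target the largest candidate is selected under
protest, and if `f` jumps by more than 0.25 across the selected candidate
the transition is flagged as sharp — in such systems (weakly coupled
ensembles are the known example) the network composition is sensitive to
the cutoff and the returned scan deserves manual review. The full scan is
part of every result object and manifest for exactly that reason.

### Critical nodes

Within the largest component, every node is removed in turn and the
remaining components measured. A node is *critical* when at least two
remaining components have at least `min_component = 10` residues: the node
was the only conduit between sizeable regions. Every critical node is an
articulation point, but articulation points shedding only a small fragment
(e.g. positions 2–10 of a 25-residue chain) are deliberately not critical
— the size rule separates "carries a region" from "dangles a tail". Ties
and orderings are deterministic throughout: the largest component breaks
size ties toward the smallest contained residue id, and reports are sorted
by (chain, residue number).

### Optimal coupling paths

Dynamic coupling is carried by physical contact, so path analysis first
drops all edges between residues whose Cβ atoms (Cα for glycine) are
within 7.5 Å in fewer than half of the frames (`ω_c ≥ 0.5`, boundary
inclusive). Remaining edges get length `1 − |C_ij|`: perfectly correlated
pairs transfer for free, uncorrelated pairs cost 1. Dijkstra's algorithm
(zero-weight edges are fine; negative weights impossible by construction)
gives minimum-cost paths for every source–target pair of a region query.
Among equal-cost optima the path with fewer hops, then the
lexicographically smallest residue sequence, is reported, so outputs are
reproducible. Because "which residues mediate the coupling" matters more
than any single path, a census counts how often each residue (endpoints
included) appears across all per-pair optimal paths; both the best pair
and the full pair matrix are returned.

### The static contrast network

`build_static_contact_graph()` applies the same machinery to a single
structure, weighting residue pairs by their heavy-atom contact count
within 4.5 Å (the standard heavy-atom contact convention; the distance is
configurable) normalised by the maximum count. Comparing its paths with
the dynamic ones shows what correlated motion adds over mere adjacency.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `contact_distance` | 7.5 | Å | Cβ–Cβ contact definition (Cα for Gly) |
| `min_freq` (ω_c) | 0.5 | — | minimum contact frequency for path edges |
| `target_fraction` | 0.5 | — | largest-component target for the cutoff |
| `min_component` | 10 | residues | size rule for critical nodes |
| `use_abs` | TRUE | — | weight edges by `|C_ij|` |
| superposition `tol` | 1e-8 | Å | mean-structure convergence |
| superposition `max_iter` | 200 | — | iteration cap |
| static `contact_distance` | 4.5 | Å | heavy-atom contact count |

The first four are the published analysis conventions and are recorded in
every run manifest. The superposition defaults are the package's own: on
well-conditioned structures the mean-structure iteration converges in a
handful of rounds, but an under-converged fit leaks rigid-body motion into
the correlations far above the 1e-6 reproducibility this package commits
to, so the iteration cap is set generously past any observed convergence
point. Tightening `tol` below ~1e-8 buys nothing: the iteration hits its
floating-point floor.

## The synthetic generator

`synthetic_spec()` defines a Gaussian factor model. Community `k` has a
latent factor `g_k(t)`; a residue of community `k` with coupling level ρ
displaces as `sqrt(ρ)·g_k + sqrt(1−ρ)·ε` per Cartesian axis (isotropic
loadings, independent innovations), and a bottleneck bridging communities
`S` at level ρ_b as `sqrt(ρ_b/|S|)·Σ g_k + sqrt(1−ρ_b)·ε`. All variances
are 1, so the implied covariance *is* the correlation matrix, is positive
semidefinite by construction, and is available in closed form
(`implied_correlation()`): members of one community correlate at
`sqrt(ρ_i ρ_j)`, a bottleneck correlates at `sqrt(ρ_b/|S|)·sqrt(ρ_in)`
with each bridged community, and cross-community correlations are exactly
zero. Because the loadings are isotropic, the scalar-product DCCM of
sampled frames converges to this matrix — clean ground truth for every
pipeline stage, at the usual `1/sqrt(F)` Monte-Carlo rate.

The default specification is two 30-residue communities at ρ = 0.7 joined
by one bottleneck at ρ_b = 0.6, embedded among 63 residues attached to
community 1's factor at ρ = 0.06 (pairwise ≈ 0.2 with community-1
members). The remainder residues are not decoration: a real domain has a
strongly coupled core *inside* a weakly coupled rest, and the ~50% rule
presupposes that structure. With the assembly at exactly half of N = 124,
the automatic cutoff lands just above the 0.2-attachment band — far above
the sampling-noise floor (≈ 0.06 at F = 5000), so no spurious
cross-community edge survives, and just below nothing that would sever the
assembly. Bottleneck recovery is then a property of the design, not luck:
the largest component is the full two-community assembly (plus at most one
attached remainder residue, which is why the component fraction lands on
0.50 exactly) and the planted bottleneck is its only critical node.

Geometry is a stretched linear chain: Cα at 3.8 Å intervals along x,
pseudo-Cβ offset 1.53 Å, displacements applied rigidly per residue, no
rigid-body motion added (hence `superpose = FALSE` for synthetic runs).
Chain neighbours sit at 3.8 Å and next-nearest pairs at 7.6 Å — just
outside the 7.5 Å contact cutoff — so the contact-filtered path graph is
the chain itself and the intended inter-community path crosses the
bottleneck by construction. The per-axis displacement amplitude of 0.3 Å
(RMSF ≈ 0.5 Å, a typical folded core) is chosen so that fluctuations
cannot push next-nearest pairs into apparent contact more than ~40% of the
time, keeping the designed topology stable across seeds.

What the generator does *not* emulate: anisotropic and collective
backbone modes, distance-dependent correlations, realistic side-chain
packing, or non-Gaussian (multi-basin) dynamics. Passing the recovery
tests therefore demonstrates that the network machinery identifies planted
coupling structure through the full I/O–statistics–graph stack; it does
not certify performance on any particular real protein, where correlation
spectra are continuous and the sharp-transition warning deserves
attention.

## Numerical choices and degenerate inputs

* Cutoff candidates are exact edge weights; no binning. The union-find
  sweep guarantees monotone `f(c)` to machine precision.
* An all-equal-weight map has a single candidate whose `f` is 1 under
  inclusive retention; the rule then selects that candidate with both the
  no-target and sharp-transition warnings rather than failing.
* Residues with undefined correlations propagate as missing edges through
  graphs, paths and difference maps; difference maps flag unmapped
  (deleted) residues instead of dropping them.
* Superposition requires ≥ 3 selection atoms (the rigid fit is otherwise
  under-determined); ensembles must have ≥ 2 frames except for the static
  contact network, which requires exactly 1.
* Insertion codes are rejected at parse time: residue identity is
  (chain, residue number) throughout.

## Validation design and problem sizes

The test suite checks every statistic against independent brute-force
re-implementations (double/triple loops, 100 random 5-residue, 50-frame
fixtures, agreement ≤ 1e-10), Dijkstra against exhaustive simple-path
enumeration (100 random 8-node graphs), critical nodes against brute-force
node removal with BFS components plus a DFS articulation-point oracle (100
random graphs ≤ 40 nodes), and the cutoff scan for monotonicity (100
random maps). Planted-bottleneck recovery and the single-community null
run 20 seeds each at F = 5000; sampling convergence is checked at
F ∈ {500, 5000, 50000} (N = 20) against the closed-form matrix with the
headline bound max-abs < 0.05 at F = 20000. These sizes keep the full
suite around two minutes while leaving each property's failure modes
plenty of room to show; `scripts/acceptance.R` recomputes the same
quantities from scratch on fresh seeds.

## Known limitations

* Only the multi-model PDB dialect is parsed; binary trajectory formats
  would need conversion upstream.
* The ~50% criterion is applied to the unfiltered correlation graph, and
  the contact filter only to path analysis; if coupling and contact
  topology disagree strongly, the two stages can tell different stories —
  the static contrast network helps diagnose this.
* Signed-correlation networks (`use_abs = FALSE`) discard anti-correlated
  coupling below the cutoff; the default absolute-value convention is
  recommended unless the sign structure is itself of interest.
* Critical-node detection is O(|component|²) in edges; fine for domains
  (hundreds of residues), not tuned for ribosome-scale assemblies.
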