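---
title: "Decomposing disordered-peptide ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing disordered-peptide ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembledecomp)
library(dplyr)
```

Intrinsically disordered peptides populate broad conformational
ensembles, and ensemble averages blur structurally distinct
sub-populations together. This package's central operation splits an
ensemble into conformation classes *before* computing summaries. This
vignette explains the model behind each module, the tunable parameters
and their defaults, the numerical choices, and the limits of what the
built-in synthetic data can demonstrate.

## The conformation parameter

Each frame $i$ is scored by

$$X_{conf,i} \;=\; \alpha\left(\frac{R_{g,i}}{R_{g,\mathrm{ave}}} +
\frac{R_{ee,i}}{R_{ee,\mathrm{ave}}} +
\frac{\mathrm{SASA}_i}{\mathrm{SASA}_\mathrm{ave}}\right),$$

where the averages are arithmetic means over all frames supplied to
`conformation_parameter()`. The premise is empirical: in disordered
ensembles the radius of gyration, end-to-end distance and
solvent-accessible surface area are mutually positively correlated, so
their normalized sum is a single compactness axis. Two exact identities
follow from the construction and are asserted in the tests: each ratio
averages to 1, so $\langle X_{conf}\rangle = 3\alpha$ to machine
precision, and doubling $\alpha$ doubles every value without reordering
frames.

**Resolution $\alpha$** (default 5, dimensionless) only sets how many
integer groups the values spread over; it has no physical content. At
$\alpha = 5$ the mean group is 15 and a typically heterogeneous ensemble
populates roughly groups 8–25. Grouping is round-half-up to the nearest
integer. The half-up rule is a pinned convention: integer group labels
require *some* tie rule, and half-up keeps the assignment monotone and
matches the brute-force histogram oracle in the tests. If averages are
computed over pooled trials, decomposition is relative to the pooled
ensemble; per-trial decomposition would renormalize each trial to its
own mean — the pooled convention is the default because the analysis
compares conformations, not trials.

Per-group summaries are then plain restrictions: secondary-structure
fractions (`group_ss_fractions()`, fractions over all residue-frame
slots in the group, summing to 1), hydrogen-bond maps
(`group_hbond_maps()`; the size-weighted sum of the group maps equals
the whole-ensemble map exactly, which the suite asserts as a partition
check), and mean minimum pair distances laid out with pair rows and
group columns (`group_pair_distance_table()`).

## Descriptors

* **Radius of gyration** is mass-weighted by default (the convention of
  trajectory tools); the unweighted variant exists because polymer-model
  closed forms (rod, ideal chain) are stated for unweighted chains.
* **End-to-end distance** defaults to first-residue N to last-residue C.
  Backbone termini are one of several defensible choices (C-alpha ends,
  heavy-atom termini); the selector interface makes the choice explicit
  and overridable.
* **SASA** uses the Shrake–Rupley construction: quasi-uniform test
  points (a deterministic golden-spiral set, default 960 per atom) on
  each atom's expanded sphere ($r_{vdw} + r_{probe}$, Bondi radii, probe
  1.4 Å for water), counting points not buried inside any neighbour's
  expanded sphere. Burial uses `<=` so coincident identical atoms fully
  occlude each other. 960 points reproduce a 10⁴-point reference
  integration within 2% on random clusters; the single-atom closed form
  $4\pi(r+1.4)^2$ is exact to the point-count discretization.
* **RMSF** superposes all frames onto a twice-iterated mean structure,
  fit on backbone N/CA/C by default, then averages per-atom fluctuations
  within residues. The fitting group matters near flexible termini,
  which is why it is exposed.
* **Hydrogen bonds** use the geometric criterion donor–acceptor
  $\le 3.5$ Å and H–donor–acceptor angle $\le 30°$ (the common
  trajectory-tool default), donors being N/O atoms with a covalent H
  (detected at 1.25 Å in the first analyzed frame), acceptors N and O.
  Intra-residue pairs are excluded; the map rows are donor residues
  unless symmetrized.
* **Minimum-distance maps** record the global minimum over frames per
  residue pair; `mean_min_pair_distance()` instead averages per-frame
  minima — the two deliberately answer different questions (ever-contact
  vs typical approach).

## Free-energy landscapes

Dihedrals are computed from backbone quadruples and featurized as
sin/cos pairs, removing angular periodicity; every defined $\phi$ and
$\psi$ contributes, giving $4(n-1)$ columns for an $n$-residue chain.
PCA is the centered eigendecomposition with a deterministic sign
convention (largest-magnitude loading positive). tICA solves
$C(\tau)v = \lambda C(0)v$ on mean-free features with the lagged
covariance symmetrized and a ridge $\varepsilon = 10^{-6}$ on $C(0)$;
symmetrization keeps eigenvalues real and bounded by 1, and the ridge
makes the Cholesky reduction well-posed for collinear features (sin/cos
pairs are nearly collinear at tight basins). The lag (default 50
frames) is a raw frame count: no physical-time claim is attached,
because the frame saving interval is a property of the input, not of
the method. Validation is by construction: a planted two-state Markov
process is recovered with $|r| > 0.9$ against the true state sequence,
a lag-1 analysis of an AR(1) series recovers its coefficient, and white
noise yields near-zero eigenvalues.

The landscape is a 2D histogram (default 64×64 over the bounding box)
converted by $\Delta F_i = -k_B T \ln(n_i/n_\mathrm{max})$, $T = 298$ K
by default, in $k_BT$ or kJ/mol. Occupied bins are non-negative with
the most-populated bin at exactly 0; the optional shift subtracts the
maximum occupied value so the least-populated state sits at 0 and
everything else is negative. Empty bins are masked (`NA`, serialized as
a sentinel token), never infinite.

## Clustering and representatives

K-means uses k-means++ seeding with 10 seeded restarts and Lloyd
iterations; given a seed the whole pipeline is bit-reproducible. The
elbow criterion computes the discrete curvature of **log** inertia
versus k. The log matters: on raw inertia the absolute drop from k=1 to
k=2 dominates any curve, and the maximum-curvature rule then always
answers 2 — on every well-separated 4-blob layout we generated, under
20 seeds each. On log-inertia the curvature responds to relative drops;
it selects the planted 4 in all those layouts, degrades to the smallest
interior k under linear decay, and picks the low end of the range for a
single structureless blob. Cluster representatives are **medoids** (the
member minimizing mean pairwise superposed RMSD), not coordinate
averages: an average of distinct conformations is generally not a
physically valid structure, while a medoid is always a real frame.
Pairwise RMSD is brute force up to 2000 members and seeded subsampling
above.

## SAXS utilities

Rebinning joins consecutive blocks (default 10) by arithmetic means,
propagating $\sigma$ as $\sqrt{\sum\sigma^2}/n$; a trailing partial
block is averaged as-is. The model-comparison statistic is the
model-denominator form $\chi^2 = \sum_i (E_i - S_i)^2 / S_i$ — exactly
as used for the curve comparisons this package mirrors, with no
division by N and no measurement $\sigma$; a conventional
$\sigma$-weighted reduced variant is provided as a clearly separate
option. Since the statistic assumes identical grids,
`chi_squared_protocol()` normalizes both curves by their own $I(0)$,
rebins the experimental curve, and linearly interpolates the model onto
the rebinned grid.

The Guinier fit regresses $\ln I$ on $q^2$ over a window grown/shrunk
iteratively until $q R_g \le 1.1$ is self-consistent, starting from the
5 lowest-q points. One systematic property deserves a number: for an
ideal Gaussian chain (the Debye function), $\ln I$ has curvature
$+x^2/36$ in $x = (qR_g)^2$, so an unweighted fit spanning
$qR_g \in [0, 1.1]$ underestimates $R_g$ by about 4%, and the
self-consistent window (which closes at $qR_g^{fit} \approx 1.1$,
i.e. slightly beyond 1.1 in true units) by about 5%. This is a property
of the Guinier approximation on flexible chains, not of the fitting
code: on exact Guinier-shaped input the same code recovers $R_g$ to
0.1%, and on compact rigid clusters (via the Debye calculator) to
0.02%. The tests assert the chain-curve recovery at the theoretically
supported 5%.

The Debye calculator uses unit form factors,
$I(q) = \sum_{ij}\mathrm{sinc}(q r_{ij})$, so $I(0) = N^2$. It is a
deliberately minimal model curve — no atomic form factors, no hydration
shell — sufficient as an internal oracle for Guinier/Kratky/χ²
plumbing, not as a predictor of measured spectra. The normalized Kratky
transform $(qR_g)^2 I(q)/I(0)$ has two analytic landmarks used in
tests: a peak at $(\sqrt{3},\, 3/e)$ for Guinier-shaped input and a
plateau at 2 for an ideal chain.

## Sequence parameters

Charges are K/R = +1, D/E = −1, histidine neutral by default (matching
both the sequence-analysis convention and neutral-pH simulation
protocols; a flag flips it). Kappa follows the blob formulation: local
charge asymmetry $\sigma = (f_+-f_-)^2/(f_++f_-)$ in sliding blobs of
width 5 and 6, $\delta$ = mean squared deviation from the
whole-sequence $\sigma$, each blob width normalized by the
$\delta_{max}$ of the most patterning-prone arrangement of the same
composition, and the two widths averaged.

The $\delta_{max}$ construction is the one genuinely open design point.
Exhaustive enumeration over all arrangements (feasible up to ~23
residues) shows the maximizer keeps each charge sign in one contiguous
block but lets both blocks float freely in the neutral background —
for net-charged compositions the optimum often sits in the interior,
not against a terminus. We therefore scan all $O(L^2)$ placements of
the two contiguous blocks, both sign orders. At length 12 with blobs of
width 5/6 this matches exhaustive enumeration to $10^{-12}$ over all
compositions tested; for very short sequences whose blob width
approaches the sequence length the true maximizer can split a charge
run and exceed the two-block family slightly — irrelevant at peptide
lengths. On five published membrane-active peptides the construction
reproduces reference kappa values to 0.002 or better (Histatin 1:
0.179).

Hydropathy is the Kyte–Doolittle scale shifted by +4.5 onto 0–9;
the disorder-promoting set is {T, A, G, R, D, H, Q, K, S, E, P};
window profiles are unweighted means over odd windows, reported at
window centers (Kyte–Doolittle and Zhao–London trans-membrane tendency
scales are built in). Phosphorylated residues are outside the 20-letter
alphabet: analyses of phosphopeptides use the wild-type sequence, by
convention.

## The synthetic generator

`gen_backbone_ensemble()` builds peptide backbones residue-by-residue
from sampled $(\phi,\psi)$ with ideal geometry (N–CA 1.458, CA–C 1.525,
C–N 1.329 Å, trans $\omega$), placing N, CA, C, O, amide H (from
residue 2) and a C$\beta$ stub. Dihedrals mix two basins: helix-like
$(-60°, -45°)$ and extended/PPII-like $(-70°, +145°)$, with Gaussian
jitter ($\sigma = 15°$ by default); the per-residue basin choice is
Bernoulli in the frame's compactness. `gen_heterogeneous_ensemble()`
draws per-frame compactness from Beta(2, 2) — broad, symmetric, and
empirically sufficient to make Rg/Ree/SASA pairwise correlations exceed
0.5 and to populate several integer groups at $\alpha = 5$, which is
the premise the decomposition needs. Ground-truth dihedrals, basin
assignments and state sequences are returned so analyzer round-trips
are exact oracle tests (builder vs analyzer agree to $10^{-6}$
degrees).

Synthetic secondary-structure labels draw classes with probabilities
tilted by the frame's extension percentile — PPII enriched in extended
frames, compensated by the unassigned class — with base fractions
chosen for a disordered peptide (bends/turns/PPII dominant, helix 2%,
strand 3%); planted helix spans are always labeled H.

What the generator does **not** emulate: excluded volume (self-clashes
are not resolved), side chains beyond C$\beta$, solvent, energetics, and
realistic kinetics (frames are independent draws except for the
two-state tICA fixture). Passing tests therefore demonstrate
correctness of the *analyses* — formulas, partitions, projections,
fits — on ensembles with the right correlation structure; they do not
validate force fields or sampling, and contact/H-bond statistics on
synthetic data are structurally plausible rather than physically
calibrated.

## Numerical choices and degenerate inputs

* Internal length unit is Å throughout; residue numbering is 1-based.
* Round-half-up grouping; empty groups are dropped from outputs.
* Landscape bins anchored on the data bounding box; all-identical
  points degrade to a single occupied bin with a warning.
* KDE bandwidths follow Scott's rule per axis
  ($\mathrm{sd}\cdot n^{-1/6}$), and the grid extends beyond the data
  range by one full kernel support so the density integrates to 1
  within 1%; a zero-variance axis is an explicit error, not NaN.
* Zero-variance feature matrices short-circuit PCA to a constant
  component; k = 1 k-means is the closed-form centroid.
* The Gaussian-chain curve switches to its series expansion below
  $x = (qR_g)^2 < 10^{-3}$, where the closed form cancels
  catastrophically.
* Errors are classed conditions (`ensembledecomp_error_*`), so callers
  and tests can distinguish topology, selection, format and degeneracy
  failures.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
desk scale: heterogeneous ensembles of 38 residues × 1000–2000 frames
(SASA at 120–240 sphere points there; the 960-point default is for
analyses, and the two resolutions agree within the documented 2%
envelope), 10⁴-frame scalar series for partition checks, 10⁵-point
landscapes, 5000-frame tICA fixtures over 20 seeds, and 50-seed medoid
checks. These sizes were chosen so each property is measured with
comfortable statistical margin.

## Known limitations

* The Guinier-window bias on flexible chains (~4–5% at
  $qR_g \le 1.1$) is inherent to the approximation; compare like with
  like (fit both model and experiment the same way) rather than reading
  the fitted $R_g$ as the ensemble $R_g$.
* The Debye calculator's unit form factors make its absolute intensity
  scale arbitrary; only normalized comparisons are meaningful.
* kappa's $\delta_{max}$ is pinned to the two-block family; alternative
  reference implementations differ in the third decimal for some
  compositions.
* The elbow rule, like all elbow rules, is a heuristic; the full
  inertia curve is returned so the choice can be inspected.
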