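---
title: "Free-energy analysis of ion permeation: methods and design notes"
author: "ionpmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy analysis of ion permeation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpmf)
```

# What this package computes

`ionpmf` reconstructs potentials of mean force (PMFs) for ion permeation
through a channel's selectivity filter from umbrella-sampling window data,
and extracts from them the quantities such studies report: free-energy
differences between ion-binding configurations, barriers along the minimum
energy path between basins, and block-average error bars. The reaction
coordinates are axial distances between a permeating ion and the center of
a ring of carbonyl oxygens (d1 for the inner ion against the Thr175 ring,
d2 for the outer ion against the Leu176 ring, in the NavAb numbering of
the TLES filter); the package itself is agnostic about what the one or two
coordinates physically are.

The full chain is: harmonic bias windows (`umbrella_setup`) → biased
sample series → histogramming and the self-consistent weighted histogram
analysis method (`wham`) → C¹ interpolation and the string method on 2D
maps (`mep`) → consecutive-block repetition for uncertainties
(`uncertainty`). A synthetic-data module generates analytic landscapes and
Langevin window series with the statistical structure the analysis
assumes, so each stage is validated by parameter recovery against a known
ground truth. Snapshot analyses (coordination shells, off-axis
displacement, cavity water counts) operate on role-tagged frames and are
independent of the free-energy chain.

# The umbrella-sampling model

Each window holds the reaction coordinate(s) near a center $c_i$ with a
harmonic restraint $U_i(x) = \tfrac{1}{2} k (x - c_i)^2$ applied per
component. The protocol defaults are fixed throughout the package:

| parameter | default | unit | note |
|---|---|---|---|
| temperature | 300 | K | $kT = 0.0019872041\,T \approx 0.596$ kcal/mol |
| force constant $k$ | 10 | kcal mol⁻¹ Å⁻² | with the ½ convention above |
| window spacing | 1.0 | Å | 20 windows (1D), 18 × 15 = 270 (2D) |
| window duration | 500 | ps | first 50 ps discarded as equilibration |
| sample stride | 1 | ps | 450 retained samples per window |
| WHAM bins | 0.1 / 0.25 | Å | 1D / per-axis 2D |
| WHAM tolerance | 1e-7 | kcal/mol | on max $|\Delta f_i|$ |
| string nodes | 200 | — | stop at RMS displacement < 1e-3 Å |
| blocks | 3 × 150 | ps | mean ± sample (n−1) sd |
| coordination cutoffs | 2.8 / 3.2 | Å | Na⁺ / K⁺, strict "closer than" |
| snapshot stride | 20 | ps | after the equilibration period |

The ½-factor in the bias is a convention choice (engines differ); it is
fixed here and used identically in the sampler, the WHAM bias energies and
the file formats, so any consistent pair of producer and consumer agrees.

# WHAM

With $H_{ij}$ the count of window $i$ in bin $j$, $N_i$ the window totals
and $c_{ij} = e^{-U_i(x_j)/kT}$ evaluated at bin centers, the solver
iterates the standard coupled equations

$$p_j = \frac{\sum_i H_{ij}}{\sum_i N_i\, e^{f_i/kT} c_{ij}},
\qquad e^{-f_i/kT} = \sum_j c_{ij}\, p_j,$$

to self-consistency (max $|\Delta f_i|$ < 1e-7 kcal/mol, up to 1e5
iterations) and reports $F_j = -kT \ln p_j$ shifted so the minimum over
masked bins is zero. Bins with fewer than a configurable number of total
counts (default 1) are masked and never extrapolated; bias energies use
the mid-point approximation at bin centers. Window coverage must be
connected through shared occupied bins; disconnected components are an
error listing the components rather than a silently arbitrary offset.
No autocorrelation correction is applied inside WHAM: statistical
inefficiency is handled by the block procedure instead, which repeats the
entire analysis on consecutive time slices.

The solver is checked two independent ways in the test suite: against
direct minimization of the equivalent multinomial likelihood by a
quasi-Newton optimizer on small histograms (agreement < 1e-6 kcal/mol,
self-consistency residual < 1e-9), and by parameter recovery on synthetic
landscapes.

# The string method

2D PMFs are interpolated with a tensor-product Catmull–Rom scheme: C¹
across cells, exact at bin centers, and exact for polynomials up to degree
two (boundary cells fall back to linear ghost extrapolation; accuracy
there is first order). Masked-out holes are filled only to support the
4 × 4 stencil near the mask boundary — queries over unmasked cells still
raise. A bilinear scheme is available as a fallback.

The simplified string iteration starts from the straight segment between
the two basin minima (endpoints relaxed to the nearest local minimum by
backtracking gradient descent, then clamped), discretized with 200 equally
spaced nodes. Each iteration moves every interior node by $-\eta \nabla F$
with $\eta$ adapted so the largest node displacement is at most 0.2 bin
widths (stability on noisy reconstructed surfaces), then reparametrizes
the polyline to equal arc length; reparametrization passes repeat until
node gaps are uniform to 1e-9 relative. Convergence is declared when the
RMS displacement between successive iterations drops below 1e-3 Å. Moving
nodes by the full gradient rather than only its transverse component is
equivalent at convergence — the tangential component is removed by the
reparametrization — and more robust far from the path.

Along the converged path, local minima are nodes lower than both
neighbors, merged when the separating excursion is below a prominence of
0.25 kcal/mol (below the smallest uncertainty such studies report, so no
genuine feature is merged away). For each adjacent pair the forward
barrier is the intervening maximum minus the first minimum, the backward
barrier the same maximum minus the second, and ΔG is computed literally as
forward − backward so the identity holds to the last bit.

# Error bars by block analysis

Each window's retained 450 ps is split into three consecutive 150 ps
blocks; the complete analysis (WHAM, and the string method when the
quantity is a barrier) is repeated per block, and a quantity is reported
as the full-data value ± the sample (n−1) standard deviation among the
three block values. Because block surfaces are noisier and their features
drift, block quantities are read at the local feature nearest the
full-data basin within 1.5 Å (`pmf_well_value`, `pmf_barrier_value`)
rather than at fixed bins.

Calibration on synthetic data (10 independent seeded repeats of the full
1D protocol) shows the block sd sits within a factor of three of the
true seed-to-seed spread for the feature-matched quantities the analysis
is designed to report (well-to-well ΔG, forward and backward barriers).
A known limitation: long-range *fixed-coordinate* PMF differences between
weakly coupled regions show heavier-tailed block noise — with 150 samples
per window the overlap between adjacent windows is sparse and the
per-window constants occasionally jump — so block error bars for such
quantities can understate by more than that factor. They are not among
the readouts the analysis reports by default.

# The synthetic-data module

Landscapes are sums of inverted isotropic Gaussian wells on a weak
confining quadratic background (default 0.05 kcal mol⁻¹ Å⁻²): smooth,
analytic gradients, and direct control of the topology. The constructors
calibrate the two well depths by a damped Newton solve so the requested
barrier and well asymmetry are matched exactly after min-zero
normalization; construction fails loudly if the requested geometry cannot
produce two minima and one saddle. For the 2D family both wells and the
background center lie on the line joining the minima, so every stationary
point lies on that line and the saddle of a symmetric instance is exactly
the midpoint — which is what makes the string-method tests sharp.

Window series are generated by overdamped Langevin (Euler–Maruyama)
dynamics on landscape + bias:
$dx = -(D/kT)\nabla(F + U)\,dt + \sqrt{2 D dt}\,\xi$, with D = 0.1 Å²/ps,
dt = 0.01 ps, recording every 1 ps, reflecting walls at the domain bounds,
and an abort if a step overshoots the domain by more than a margin
(an unstable time step should fail, not fold back silently). The
integrator runs in compiled code but draws from R's RNG, so every series
is a pure function of the seed (default 2012, recorded in window file
headers). Successive retained samples have a correlation time comparable
to the 1 ps stride under a k = 10 bias (relaxation time $kT/(Dk) \approx
0.6$ ps), emulating the mildly correlated character of real
collective-variable traces.

What the generator does *not* emulate: multidimensional orthogonal
degrees of freedom relaxing on slow timescales, non-Markovian memory from
solvent, force-field specifics, and any absolute energetics of a real
channel. Passing recovery tests therefore demonstrates the correctness of
the estimators under the statistical model the analysis assumes — not
that a given molecular system is converged. The study-scale defaults
(barrier 3.0 kcal/mol with 1.0 asymmetry on wells 6 Å apart for 1D;
barrier 3.5 with asymmetry 1.2 on basins at (4,4) and (12,10) for 2D)
were chosen once to match the barrier magnitudes and two-basin topology
typical of filter permeation maps, with well widths (1.2 / 1.5 Å) that
keep the saddle region smooth at the window spacing.

# Resolution limits of the protocol itself

A point worth stating explicitly because the recovery tests quantify it:
with k = 10 kcal mol⁻¹ Å⁻² at 300 K each window's samples have sd
$\sqrt{kT/k} \approx 0.24$ Å, so windows 1.0 Å apart overlap only in
their ~2σ tails, and with 450 retained samples a 0.1 Å bin can collect at
most ~90 counts. The per-pair uncertainty in the window constants $f_i$
is then 0.1–0.2 kcal/mol and accumulates as a random walk along the
ladder: reconstructions at this sampling depth carry point errors of
several tenths of a kcal/mol (the acceptance script measures 0.4–0.9
max over well-sampled bins, falling as $1/\sqrt{n}$ with more sampling;
the 2D grid is better conditioned because its loops average the drift,
giving RMS errors well under 0.4). This is a property of the protocol's
information content, not of the estimator — the same solver reaches
< 0.3 kcal/mol everywhere when windows are 10× longer — and it is
consistent with the few-tenths error bars such studies report.

# Problem sizes in the tests and acceptance script

The suite runs entirely on synthetic data generated at test time: the
full 1D protocol (20 × 450 samples) in several tests, one full 2D
protocol (270 × 450), 10 repeats of the 1D protocol for the block
calibration, 10⁵-sample sampler distribution checks, and brute-force
minimax oracles on 0.05 Å grids. These sizes keep every stage's
statistics meaningful while completing in minutes on one CPU.

# Open choices made here

* **1D window range** [−5, 14] Å about the inner carbonyl ring: spans a
  cavity-to-extracellular ladder of 20 windows at the 1.0 Å spacing; only
  the count and spacing are protocol-fixed, not the endpoints.
* **2D grid factorization** 18 × 15 = 270 over [0, 17] × [0, 14] Å: a
  rectangular grid consistent with the printed window total; a mask
  predicate allows non-rectangular coverage.
* **Endpoints of the string** are relaxed to their basin minima and then
  clamped, anchoring barrier readouts to the basins; letting endpoints
  drift during iteration would mix basin identification into convergence.
* **Sample timing** $t_i = t_0 + i \cdot \text{stride}$ with $t_0 = 0$,
  so "discard t < 50 ps" removes exactly 50 of 500 one-ps samples.
* **n−1 standard deviation** for the 3 block values; with 3 blocks the
  population variant differs by √(3/2) and can be toggled by recomputing
  from the stored per-block values, which every report retains.
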