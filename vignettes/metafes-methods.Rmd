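---
title: "Methods: free energy surfaces from metadynamics hills"
author: "metafes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free energy surfaces from metadynamics hills}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafes)
```

## The model

Metadynamics accelerates molecular dynamics by depositing repulsive
Gaussian "hills" along a few collective variables (CVs) $s$, accumulating a
bias potential

$$V(s, t) = \sum_{k:\,t_k \le t} h_k
  \exp\!\Big(-\sum_j \frac{\Delta_{jk}^2}{2\sigma_{jk}^2}\Big),$$

where $\Delta_{jk}$ is the displacement from hill $k$'s center along CV $j$
(minimum-image for periodic CVs such as dihedral angles) and $h_k$,
$\sigma_{jk}$ are the hill's height and widths. Because the most stable
states accumulate the most bias, the free energy surface (FES) is estimated
as the negative of the accumulated bias, $F(s) = -V(s)$. In well-tempered
metadynamics the deposited heights decay with the local bias,
$h_k = w\,e^{-V(s_k,t_k)/((\gamma-1)k_BT)}$ with bias factor $\gamma$, and
the converged bias is a $(1-1/\gamma)$-scaled negative image of $F$. Plumed
writes the heights in its HILLS files already multiplied by
$\gamma/(\gamma-1)$, so plain summation of the file's heights again yields
$-F$; `fes()` therefore uses heights exactly as stored. For files holding
unscaled heights, `fes(..., scale_biasfactor = TRUE)` applies the
$\gamma/(\gamma-1)$ factor — the package does not guess which convention a
file uses, it follows the Plumed default and exposes the switch.

## Hill summation

`fes()` tabulates $-V$ on a regular grid. Periodic dimensions span
$[lo, hi)$ with spacing $(hi-lo)/r$ (the wrap node is not duplicated, so
the implied function is continuous across the seam); non-periodic
dimensions include both ends with spacing $(hi-lo)/(r-1)$. Defaults: 256
nodes per CV (64 in 3D, for memory), the period bounds for periodic CVs,
and the hill-center range padded by three mean hill widths otherwise.

Two summation paths are provided:

* **exact** — every hill's Gaussian is evaluated at every node (separable
  per-dimension factors, minimum-image distances). No truncation. This is
  the quantitative path.
* **fast** — one kernel is precomputed on the grid spacing, truncated where
  the Gaussian exponent exceeds 6.25 (3.53 $\sigma$, where the Gaussian is
  $1.9\times10^{-3}$ of its peak), and stamped at the node nearest each
  hill center with periodic wrap-around. It requires a single width per CV
  (the common Plumed case; otherwise it refuses and points to the exact
  path). The truncation plus nearest-node placement error is
  regression-tested against the exact path: $\le 0.01\,h$ for a single
  hill at resolution 256, and $\le 1$ kJ/mol on a 10,000-hill 2D run whose
  landscape is $\sim$65 kJ/mol deep.

Floating-point addition is not associative, so to make results
reproducible regardless of how a HILLS file was assembled (restarts,
concatenation), both paths accumulate in a canonical hill order (sorted by
time, then centers, widths, heights). Reordering the input hills therefore
gives bit-identical surfaces.

Surfaces support `+`, `-` and scalar `*` (e.g.
`fes_scale(f, 0.239006, "kcal/mol")` for unit conversion),
`fes_normalize()` (global minimum to zero) and `marginalize()`, which
removes CVs by Boltzmann marginalization
$F'(s_{keep}) = -k_BT \log \sum_{removed} e^{-F/k_BT}$, computed with
log-sum-exp stabilization and normalized. The thermal energy defaults to
$k_BT = 2.494339$ kJ/mol (300 K with $R = 0.0083144621$ kJ/mol/K) and is
settable everywhere it appears.

## Minima, basins and state free energies

`find_minima(mode = "precise")` declares a node a local minimum iff it is
strictly lower than its full Moore neighborhood ($3^d-1$ nodes; periodic
wrap where applicable; missing neighbors at non-periodic edges count as
$+\infty$, so edge nodes can be minima). The Moore neighborhood is
stricter than face-only adjacency and avoids saddle false positives.
Basins are assigned by steepest descent: each node hops to its lowest
neighbor (ties to the smallest row-major index) until it reaches a
minimum; this is a watershed partition, fully deterministic. The boundary
mask marks nodes with a face neighbor owned by a different basin. Exact
plateaus are resolved by the same lexicographic (value, index) rule; a
plateau bottom is not a *strict* minimum, and in the measure-zero case
where one occurs its basin is merged into the nearest strict minimum —
surfaces built from sums of Gaussians never tie exactly unless a well sits
exactly midway between two nodes.

State free energies account for basin width as well as depth: every node
contributes $p_i \propto e^{-F_i/k_BT}$, probabilities are summed per
basin, and $g_m = -k_BT \log P_m$, shifted so the most populated state is
zero (log-sum-exp throughout; all nodes participate, no energy cutoff).
A wide shallow basin can therefore outrank a narrow deep one — the unit
tests exercise exactly that case against a fine-quadrature oracle.
Minima are lettered A, B, C, ... (then AA, AB, ...) in ascending $g$,
ties broken by row-major grid index.

`find_minima(mode = "grid")` is the coarse search for rugged landscapes:
the CV range is divided into 8 (1D), 8×8 (2D) or 8×8×8 (3D) cells by
default, each cell's lowest node is kept if it is a strict local minimum
of the full grid, and duplicates found from adjacent cells are collapsed —
at most 64 minima for a 2D surface at defaults. Grid mode returns no
basin assignment, so population free energies are undefined there; its
minima are labelled in ascending depth (row-major ties) and
`g_population` is `NA`.

## Convergence diagnostics

`convergence_profile()` rebuilds the FES from growing hill prefixes
(checkpoints spaced by hill count, which is robust to irregular deposition
strides) and evaluates the population free energy of every state at each
checkpoint. The minima and basins are detected once, on the
full-simulation surface, and held fixed: this keeps each state's series
well defined even when early surfaces lack some minima (an unexplored
state simply shows a high free energy). Each row is shifted to its own
global minimum. `marginal_evolution()` does the analogous thing for
lower-dimensional profiles. Stability of these series over the late
checkpoints is one indicator of convergence, not proof of it.

## Error analysis

Each hill center is a CV sample at its deposition time;
`occupancy_series()` maps samples to basins of the reference surface,
giving one 0/1 series per state. `autocorr_stats()` estimates the
integrated autocorrelation time $\tau = \tfrac12 + \sum_k \rho(k)$ with
the initial-positive-sequence (Geyer-style) truncation — the sum stops at
the first non-positive pairwise sum $\rho(2m-1)+\rho(2m)$ — then
$n_{eff} = n/2\tau$ and $se = sd\sqrt{1/n_{eff}}$, with $\tau$ floored at
$1/2$ so the error bar never undercuts the independent-sample one.
`dg_error()` converts two occupancy means into
$\Delta G = -k_BT\ln(p_a/p_b)$ with first-order error propagation.

Two limitations are documented deliberately. First, the samples come from
the progressively flattened (biased) ensemble and are not reweighted, so
the occupancy $\Delta G$ estimates the biased-ensemble free-energy gap,
not the physical one. Second — measured by this package's own acceptance
suite on synthetic double-well runs — the hill-deposition feedback
actively anticorrelates basin occupancy, which makes occupancy series
*more* stable across replicates than their own autocorrelation error bar
suggests, while the FES-based $\Delta G$ carries an additional
bias-fluctuation error that occupancy statistics cannot see. Both errors
shrink as $1/\sqrt{T}$, so their ratio is insensitive to run length: on
20-replicate synthetic benchmarks the nominal $\pm 2\,se$ interval around
the FES $\Delta G$ covers the true value in roughly half the replicates
rather than 95%. Treat `dg_error()` as a lower bound on the uncertainty
of metadynamics free-energy differences; a bias-aware error model is
future work.

## The synthetic generator

`simulate_metad()` integrates overdamped Langevin dynamics
(Euler–Maruyama, $s \leftarrow s - \nabla(U+V)\,dt + \sqrt{2k_BT\,dt}\,\xi$)
on analytic potentials, depositing hills every `stride` steps with the
standard well-tempered height rule, and records heights pre-scaled by
$\gamma/(\gamma-1)$ as Plumed does. It is a position-only toy engine —
deliberately so: it exercises every analysis path with known ground truth
(`analytic_fes()`, quadrature oracles), reproduces byte-identically under
a fixed seed, and costs seconds. It does not emulate inertia, thermostat
artifacts, hidden slow degrees of freedom orthogonal to the CVs, or
CV-dependent diffusion — passing tests on it validate the estimators, not
the behavior of real MD data.

Default conditions and why:

* `double_well_1d`: $U = B(x^2-1)^2 + ax$ with $B = 8$, $a = 1.5$ — a
  3.2 $k_BT$ barrier and a free-energy gap of $\approx 2.76$ kJ/mol
  between the wells (by quadrature), the scale at which error analysis is
  interesting. $dt = 0.001$ ps keeps Euler–Maruyama stable against the
  stiffest curvature ($dt \ll 2/U''_{max}$).
* `four_well_2d`: $B = 15$, four equivalent wells; with well-tempered
  filling the reconstructed landscape is $\sim$65 kJ/mol deep, a realistic
  magnitude for conformational surfaces. $dt = 5\times10^{-4}$ ps.
* `periodic_cosine_1d`: $A = 5$, a 10 kJ/mol torsion-like periodic
  profile. A shallower setting (4 kJ/mol) proved smaller than the
  reconstruction noise of a desk-scale run and made recovery benchmarks
  uninformative, so the default is the realistic torsional scale.
* Hills: height 1 kJ/mol ($\approx 0.4\,k_BT$), width about half the
  thermal basin width, one hill per 25 steps, bias factor 10 — common
  practice for toy benchmarks.

Benchmark problem sizes used by the test and acceptance suites: 50,000
steps (2,000 hills) per double-well replicate, 100,000 steps (10,000
hills) for the 2D fast-vs-exact comparison, 80,000 steps for the periodic
recovery check, grids of 64–512 nodes per CV. At these sizes the whole
suite runs in about a minute on one CPU.

## Numerical and design choices

* Log-sum-exp for every Boltzmann sum; populations sum to 1 to $10^{-12}$.
* Canonical hill ordering (above) makes summation permutation-invariant;
  accumulation is plain double precision.
* Text I/O (HILLS, FES grids) prints 9 significant digits; a
  read-write-read cycle is the identity at printed precision and a second
  write is byte-identical. Period bounds equal to $\pm\pi$ are written as
  the `pi`/`-pi` tokens, as Plumed does.
* Indices are 1-based and ranges inclusive (`slice_hills(h, first, last)`),
  the R convention.
* In plots, minima letters switch between black and white by the Rec. 709
  relative luminance of the underlying fill color (white below 0.5, black
  at or above), so labels stay readable on any palette; palettes come from
  `hcl.colors()` and default to viridis with solid contours every
  10 kJ/mol and dotted basin-boundary nodes.
* The command-line front end (`inst/scripts/mdm.R`) is a thin `Rscript`
  wrapper over these functions for shell pipelines; the package API is the
  primary interface.

## Known limitations

Reweighting-based FES estimation (combining bias and sampled populations)
is out of scope; the bias-summation estimator is the one implemented.
Three CVs are supported for summation and minima analysis but not for
plotting (marginalize first). The error model's coverage limitation is
described above. The generator's plain-Langevin character means
friction/timestep are effective, not physical, parameters.
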