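---
title: "Population landscapes and conformer statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population landscapes and conformer statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscape)
```

## The scientific problem

Stearoyl-CoA desaturase-1 (SCD1) inserts a cis double bond at the Delta-9
position of stearoyl-CoA. Its substrate-binding tunnel is kinked, and the
kink has been attributed to hydrogen bonding among three residues that
line the tunnel: Gln147 interacts with both Trp153 and Thr261.
Desaturation further requires the substrate's C9-C10 bond to adopt a
negative gauche torsion near -60 degrees (the *actionable* conformation),
whereas the crystallographic substrate conformation is non-gauche
(-111.1 degrees about C8-C9-C10-C11).

`mdscape` quantifies this coupling from molecular dynamics (MD)
trajectories through four statistics:

1. a **2D free-energy landscape** over the paired distances
   d1 = Gln147(OE1)...Trp153(HE1) and d2 = Gln147(HE22)...Thr261(OG1);
2. a **torsion distribution and free-energy profile** for the substrate
   chi = C8-C9-C10-C11 dihedral;
3. **conditional conformer statistics**: the actionable fraction of chi
   given whether the triad satisfies a geometric hydrogen-bond criterion;
4. a **grid-based pocket volume** in a sphere following the ligand's 5th
   tail carbon.

## Estimators

### Landscape

Every paired observation (d1, d2) is grouped into half-open bins
[edge, edge + w) of width w = 0.1 A whose edges sit at exact multiples of
w (anchored at zero). Anchoring at absolute multiples is what makes
per-replicate histograms poolable by addition: grids align by edge value,
never by index. The free energy of bin i is the Boltzmann inversion of
its population,

  dG_i = -ln(rho_i / rho_max)   (in kT),

where rho_i = n_i / N and rho_max is the most populated bin's share. The
argmax bin is exactly 0 kT by construction. Bins with no observations
receive a sentinel of 10 kT; the sentinel marks "unsampled", is excluded
from any averaging, and acts only as the plot ceiling.

The kT-level table reports the percentage of **observations** (not bins)
whose bin's dG falls in (n-1, n] kT, with dG = 0 included in level 1.
Because unsampled bins hold zero observations, the level percentages sum
to 100 exactly. Counting observations rather than bins is the only
reading under which a level table is a partition of the data; it also
makes the minimum bin's share a lower bound on level 1.

Reported minimum coordinates are ambiguous between a bin's start and its
center when quoted to one decimal; both are exposed (`x`/`y` centers and
`x_start`/`y_start`) and the CSV carries bin starts. Ties for the argmax
bin are broken toward the smallest x, then y, with a warning.

Pooling uses a single pooled rho_max (combined-model normalization);
per-replicate surfaces are also produced, each normalized to its own
rho_max.

### Torsion profile and conformer classes

chi values live in (-180, 180] (IUPAC sign convention: cis = 0; looking
from C9 to C10, clockwise rotation of the far bond is positive — this is
what makes "negative gauche" a *negative* number). The distribution
rho(chi) uses 5-degree bins tiling the circle, right-closed and anchored
at -180 so the periodic boundary lies inside a bin; the figure-level
resolution of the underlying study is not stated, so the width is a
configurable default. The profile is

  phi(chi) = -0.6 ln rho(chi)   (kcal/mol),

with 0.6 kcal/mol ~ RT near 300 K. phi is deliberately **unshifted** (no
minimum subtraction), exactly as defined; unsampled bins carry `NA`,
never 0, since a zero would masquerade as a free-energy minimum.

Conformer classes partition the circle: negative gauche (|chi + 60| <=
30), positive gauche (|chi - 60| <= 30), trans (|chi| >= 150), otherwise
`other`. The actionable window is a separate tolerance: +/-5 degrees for
the conditional statistic, +/-10 degrees for the broader description;
both are parameters.

### Hydrogen-bond criterion

The triad is "bonded" in a frame when **both** pair distances are at or
below 2.5 A. The literature description of the cutoff is internally
inconsistent (a ">2.2 A" reading contradicts its own usage), so the
criterion is an explicit, documented interpretation: 2.5 A on
hydrogen-acceptor distances is the standard geometric criterion and
brackets the observed landscape minima (2.0-2.3 A). It is a config
parameter, not a constant. Requiring both pairs (rather than either)
matches the notion of all three residues being in bonding range.

### Pocket volume

A cubic grid of spacing h (default 1.0 A; 0.5 A in validation runs) is
anchored at the per-frame position of the center atom. Grid points
within the region radius (default 6 A) count as free volume (h^3 each)
unless they lie within vdW radius + probe radius (default 1.4 A) of an
occluding atom. Occluders default to protein atoms (standard residue
names); ligand inclusion is a switch, since which atoms the original
volumetrics counted is not stated. Radii are the Bondi set (H 1.20,
C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Fe 1.40 A); unknown elements
fall back to 1.70 A with a warning. Anchoring the grid to the center
atom (not the lab frame) makes the measurement translation invariant,
which the tests assert; the analytic sphere and sphere-minus-occluder
cases bound the discretization error (under 5% at h = 0.5 A for a 6 A
region, converging as h decreases). Parity with any particular external
volumetrics program is a non-goal; the analytic cases are the test
surface.

## The synthetic trajectory generator

The production MD trajectories behind the original landscapes are not
publicly deposited, so the package ships a generator whose output has
the same *statistical* structure, with ground-truth labels:

- a hidden two-state Markov chain per frame, states `kinked` and `open`,
  initial state drawn from the stationary distribution (no burn-in
  parameter);
- state-conditional Gaussian emissions for d1 and d2;
- a state-conditional two-component von Mises mixture for chi, centered
  at -60 and 180 degrees (Best-Fisher rejection sampling);
- an exact geometric embedding: the two distance pairs are placed along
  fixed axes in spatially separated blocks, and the torsion quad is
  placed by internal coordinates (bonds 1.53 A, angles 111 degrees), so
  re-measuring the coordinates reproduces the emitted observables to
  1e-6. The toy system is geometrically faithful, **not** physically
  faithful: no force field, no membrane, no water, no excluded volume.

Preset parameters anchor each model system's basins to the published
landscape coordinates (kinked minimum near (2.0, 2.2) A for the
substrate system; an open subpopulation near (4.1, 5.6) A for the
product system; secondary d2 of 4.3 A and 4.9 A for the apoprotein and
CoA systems) and calibrate the substrate torsion mixture so the
actionable mass is 0.18 in the kinked state and 0.035 in the open state,
mirroring the published 18.1%/3.5% contrast. These are emulation
targets, not claims about the original trajectories. State-switching
rates are chosen for test power (occupancies 0.9 / 0.3 / 0.6 / 0.55
kinked for substrate / product / apoprotein / CoA), since the study
reports no autocorrelation times. Where per-state standard deviations
are not derivable from the text, 0.15 A is used for tight (kinked-like)
components and 0.3-0.4 A for genuinely open components, consistent with
the published basins' extents of a few tenths of an angstrom.

The `waterbox` preset has no protein, so it carries a trans-dominated
torsion and only *placeholder* solvent-scale distances (8 +/- 1 A);
every trajectory object carries d1/d2 series for interface uniformity,
but no landscape claim attaches to them, and basin-recovery tests
exclude this preset.

What passing tests show — and what they do not: recovery tests
demonstrate that the estimators identify basins, occupancies and
conditional contrasts from data *with the generator's statistical
structure* (Gaussian basins, von Mises torsions, Markov switching). Real
MD data have non-Gaussian basins, slow degrees of freedom and
state-dependent torsion-distance coupling beyond what the generator
emulates; the tests validate the estimators, not the biology.

## Statistical checks and numerical choices

- **Occupancy recovery** is tested against the Markov-chain standard
  error, sqrt(pi (1-pi) (1+lambda) / ((1-lambda) n)) with lambda the
  chain's second eigenvalue — the iid binomial SE understates the
  estimator's variance under autocorrelated states.
- **Conditional-fraction recovery** is tested against the model-implied
  truth P(actionable | bonded), computed analytically by mixing the
  per-state von Mises window masses with the per-state Gaussian
  bond probabilities at stationarity. This differs from the raw
  per-state values whenever the bond criterion imperfectly separates
  the states (e.g. the unbonded class contains kinked-state frames
  whose d2 fluctuated above the cutoff).
- Recovery runs use 5 replicates of 10,000 frames per model system —
  enough for three-standard-error checks on fractions of a few percent
  while keeping the whole suite in seconds.
- Bin assignment adds a 1e-9 guard before `floor()` so values stored at
  bin edges (e.g. 2.1 after decimal rounding) land in the bin they
  start, as the half-open convention requires.
- PDB coordinates round-trip at the format's fixed precision (1e-3 A);
  DCD at single precision (~1e-4 A at protein-scale magnitudes).
- Distances use the exact published atoms, including hydrogens (HE1,
  HE22), so topologies must carry explicit polar hydrogens for those
  roles. No minimum-image correction is applied; inputs are assumed
  whole.

## Crystal-geometry validation

The deposited crystal structure is not shipped with the package.
`synthetic_crystal_structure()` builds a SYNTHETIC stand-in (also at
`inst/extdata/synthetic_4zyo_standin.pdb`) that embeds only the two
published scalar facts — a 6.8 A metal-metal distance and a
-111.1 degree C8-C9-C10-C11 torsion — in a rigidly rotated frame. Tests
against it validate the PDB parsing, atom resolution and measurement
kernels on known geometry; they are a consistency check, not a
re-measurement of the experimental coordinates.

## Known limitations

- The landscape is raw binned population inversion: no reweighting
  (WHAM/MBAR), no kernel density estimation, no error bars on dG.
- Hydrogen bonds are distance-only; no donor-acceptor angle criterion.
- The pocket measurement implements the described sphere-region
  grid count, not any particular external program's full feature set.
- The generator emits conditionally independent observables given the
  state; real trajectories correlate chi with the distances *within*
  states as well.
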