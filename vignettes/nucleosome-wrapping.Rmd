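---
title: "Nucleosome wrapping energies from a rigid-base DNA model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome wrapping energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`nucwrap` treats a linear double-stranded DNA fragment of $n$ base pairs as
a chain of rigid bodies: the two bases of every pair, and the two backbone
phosphate groups of every junction between pairs. The configuration vector

$$ w = (y_1, \eta_1, y_2, \eta_2, \dots, \eta_{n-1}, y_n) \in \mathbb{R}^N,
\qquad N = 24n - 18, $$

collects the six intra base-pair coordinates $y_a$ of every pair and an
18-dimensional junction block $\eta_a$ = (Crick phosphate 6, inter
base-pair 6, Watson phosphate 6). Every 6-block is three rotational
coordinates (scaled Cayley/Gibbs vectors, scale factor 10 by default,
declared in the parameter-set metadata) followed by three translations in
Angstrom. A 147-bp nucleosomal fragment has $N = 3510$ coordinates.

Given a sequence $\mathcal{S}$ over the extended alphabet
$\{A, T, C, G, \mathrm{MpN}, \mathrm{HpK}\}$ — where MpN and HpK denote CpG
steps whose cytosines are symmetrically 5-methylated or
5-hydroxymethylated — and a parameter set $\mathcal{P}$ of per-dimer-step
30-dimensional stiffness blocks and weighted means, the package assembles

* the banded, symmetric positive-definite stiffness matrix
  $K(\mathcal{S}, \mathcal{P})$ by overlapping addition of the step blocks
  (adjacent blocks share the six intra coordinates of the common base
  pair; optional terminal corrections act on the first and last $y$), and
* the ground state $\mu(\mathcal{S}, \mathcal{P})$, solved from
  $K\mu = \sigma$ with the identically assembled weighted mean $\sigma$,

so that

$$ U(w) = \tfrac12\,(w - \mu)\cdot K\,(w - \mu) $$

is the elastic energy in units of $kT$, and
$\rho(w) = Z^{-1} e^{-U(w)}$ with
$Z = (2\pi)^{N/2}\det(K)^{-1/2}$ is the Gaussian equilibrium density.
All determinant work goes through the sparse Cholesky factorisation
(half-bandwidth 29; CHOLMOD via the Matrix package). Two algebraically
equivalent routes to the log density are implemented and tested against
each other to $10^{-9}$:

$$ \ln\rho(w) = -U(w) + \tfrac12\ln\det K - \tfrac{N}{2}\ln 2\pi
            = -U(w) - H + \tfrac{N}{2}, $$

where $H = \tfrac{N}{2}(1 + \ln 2\pi) - \tfrac12 \ln\det K$ is the
differential entropy.

Parameter sets are inputs, not outputs: estimating them from molecular
dynamics is outside this package's scope. The portable JSON container
(`save_parameter_set()` / `load_parameter_set()`) records the alphabet,
block dimension, coordinate ordering, rotation encoding and scale, and
units, and stores float arrays as 17-significant-digit strings so round
trips are bit-exact. Loading validates block symmetry and the
reverse-complement consistency
$B_{\mathrm{rc}(d)} = E\,B_d\,E$, $\sigma_{\mathrm{rc}(d)} = E\,\sigma_d$
under the declared involution (tilt-like and shift-like coordinates flip
sign, Watson and Crick phosphates swap, the block order reverses). At the
model level this implies $\mu(\mathrm{rc}(\mathcal{S})) = E_N\,\mu(\mathcal{S})$
and $K(\mathrm{rc}(\mathcal{S})) = E_N K(\mathcal{S}) E_N^{\!\top}$, which the
test suite asserts numerically.

## Wrapping energy

The nucleosomal configuration is modelled as the minimiser of the elastic
energy under soft constraints pinning the histone-bound phosphates:

$$ w_{\mathrm{opt}} = \arg\min_w \; U(w) + \sum_{i=1}^{28}
   c_i \,\lVert p_i(w) - \bar p_i \rVert^2 , $$

where $p_i(w)$ are the Cartesian positions of the 28 bound phosphates
(14 per strand, one per helical turn of contact), $\bar p_i$ their
reference positions (averaged over an aligned structure ensemble), and
$c_i > 0$ elastic coefficients in kT/A^2. The reported *wrapping energy*
is $U(w_{\mathrm{opt}})$ alone; the penalty sum is reported separately.
`log_density(w_opt)` gives the nucleosomal-configuration log probability
density, the package's second headline quantity.

### Reconstruction and derivatives

Absolute frames are reconstructed sequentially: inter coordinates place
successive base-pair frames by mid-frame (half-rotation) composition —
required for the reverse-complement symmetry to hold exactly — intra
coordinates split each pair into its two base frames, and each junction's
phosphates are placed relative to their 3'-side base frame (Watson
phosphate on base pair $a+1$, Crick on $a$; the convention is declared in
the metadata). The gradient of the objective is exact: a perturbation of
an inter coordinate at junction $a$ rotates all downstream material
rigidly about the origin of base pair $a+1$ and adds the mid-frame
translation kick, while intra and phosphate coordinates act locally. The
resulting phosphate-position Jacobian is assembled in compiled code and
verified against central finite differences to $10^{-6}$ relative.

### Optimisation

The minimiser is a damped Newton iteration with the exact gradient and the
Gauss–Newton Hessian $K + 2J^\top C J$ (positive semidefinite penalty
part, exact wherever residuals vanish; the exact second-order penalty term
is deliberately omitted for robustness). Each step solves the Newton
system through the Woodbury identity: one sparse Cholesky solve on
$K + \lambda I$ plus a dense $3m \times 3m$ core for $m$ constraints.
Armijo backtracking guarantees monotone descent; $\lambda$ grows tenfold
on rejected steps and decays on clean full steps. Convergence is declared
at gradient infinity-norm $\le 10^{-6}$ kT/unit (configurable); 500
iterations maximum.

Because the frame reconstruction anchors base pair 1, a naive
internal-coordinate minimisation would pin the molecule's absolute pose
and charge elastic energy for what should be free rigid-body placement
(on the 147-bp fixture this inflates the optimum by hundreds of kT). The
minimiser therefore augments the Newton system with the six rigid
placement degrees of freedom of the anchor (translations, rotations about
the constrained-phosphate centroid; their penalty columns are analytic
and the elastic energy is exactly invariant along them) and additionally
applies the closed-form weighted-Kabsch alignment of the current
phosphates onto the references after every accepted step. The alignment
is an exact block-descent move, so monotonicity is preserved; the joint
Newton system removes the slow zigzag a pure alternating scheme exhibits.
`align = FALSE` recovers the fixed-anchor problem (used when comparing
against generic fixed-parametrisation optimisers).

The default initial configuration is an ideal superhelix fitted to the
constraint references by least squares (axis from the smallest-variance
direction, radius, angular and axial rates from linear fits; the helical
twist register is chosen by a coarse scan of initial residuals), with
intra and phosphate coordinates taken from the ground state. With fewer
than six constraints the ground state itself is the start. User-supplied
starting configurations are accepted.

### Penalty coefficients and diagnostics

The default global coefficient is $c = 10$ kT/A^2
(`default_penalty_coefficient()`), calibrated once on the synthetic
fixture so optimum residuals fall in 0.1–2 A — the order of the
positional spread of bound phosphates across experimental structures; at
$c = 1$ residuals reach ~10 A, at $c = 50$ they drop below 0.05 A.
`residual_report()` flags residuals outside user-provided ranges, and
`check_self_overlap()` reports the minimum distance between phosphates
more than 40 junctions apart (different superhelical gyres) against a
clash threshold. Terminal base pairs carry no constraints, so a few
junctions at each end relax away from the superhelix; this mirrors the
end-unwrapping the method is known to produce and is not corrected.

### Constraint derivation from structure ensembles

`identify_bound_indices()` reproduces the bound-index construction from
aligned structure ensembles: per-index mean radial distance to the
nucleosome axis, strict local minima of the mean profile, an inner-side
(below profile midrange) filter, clustering by helical turn, and one
representative per cluster — the index closest to the nucleosome centre —
with the per-index standard-deviation profile returned alongside. The
default axis is a cylinder fit (`fit_symmetry_axis()`): the raw principal
axis of a ~1.65-turn superhelical cloud is measurably tilted, which
distorts the radial profile. `build_constraints()` then averages the
ensemble positions at the selected indices.

## Sequence and region layers

CpG counting, symmetric modification (one record per CpG step, both
strands), reverse complementation (a modified step at junction $j$ maps
to $n-j$), random sequences with a target CpG count range (uniform bases,
then randomised CpG insertion/removal with recounting after every edit),
dinucleotide counting, the Altschul–Erickson dinucleotide-preserving
shuffle (random last-exit edges accepted only when they form an
arborescence into the terminal base, then uniformly permuted edge lists;
the test suite checks uniformity against brute-force enumeration), and
tetramer flanking-context counting around CpG steps. The extended-FASTA
dialect writes a modified step as `MN` (methyl) or `HK` (hydroxymethyl);
ambiguity codes are rejected because the model alphabet has none.

Genomic intervals follow BED semantics (0-based, half-open) end to end;
`classify_regions()` computes the four-way split A = CGI∩NMI,
B = NMI∖CGI, C = CGI∖NMI, D = universe∖(CGI∪NMI) with per-bp interval
arithmetic (GenomicRanges), `central_window()` extracts the centred
147-bp representative per region, `scan_windows()` enumerates 1-bp-shift
windows, `attach_scores()` averages occupancy-style tracks per window
(flagging items under 50% coverage), and `group_by_cpg_count()` uses the
inclusive bins [0,4], [5,14], [15,24], [25,34] with an explicit overflow
bucket. Because no single convention is obviously right for assigning a
scan window to a region, `assign_windows_to_regions()` implements both a
central-bp rule (default) and a full-containment rule. The "respect NMI"
methylation policy (`methylate_by_region_class()`) methylates classes C
and D and leaves NMI classes unmodified; both modified and unmodified
runs are supported for every class.

## Synthetic fixtures: what they do and do not show

Every pipeline stage can run without downloads:

* `synthetic_parameter_set()` builds random symmetric positive-definite
  step blocks that satisfy the reverse-complement involution exactly,
  around a B-DNA-like mean (~34 deg twist, 3.4 A rise, phosphates ~9 A
  off axis). The MpN/HpK blocks are stiffened copies of the CG block
  (+15%/+18%) with raised roll and lowered twist in the mean — the
  qualitative signature of cytosine modification reported across the
  experimental and simulation literature. This gives fixtures the
  expected direction of modification effects; it is *not* a trained
  parameter set, and absolute energies under it are not comparable to
  trained-model values (random stiffness blocks lack the soft, collective
  bending modes of real DNA, so synthetic wrapping energies run several
  times higher).
* `ideal_superhelix_constraints()` places 28 contacts (14 per strand,
  alternating, ~10.2 junctions apart on a strand) on the standard
  nucleosome superhelix (radius 41.9 A, pitch 25.9 A, 1.65 left-handed
  turns).
* `synthetic_structure_ensemble()` generates aligned phosphate tracks
  with a near-periodic radial modulation realised as a phase-warped
  cosine whose strict minima sit exactly on integer junction indices
  (8 + ~10.2k on Watson, 5 + ~10.2k on Crick, 14 wells per strand), plus
  isotropic Gaussian jitter. Anchoring the wells to integer indices is
  what makes "recover the planted indices exactly" a well-posed check: a
  fixed-period cosine puts some minima halfway between two indices, where
  the discrete argmin is undecidable under noise.

Passing tests on these fixtures demonstrates the correctness of the
machinery — assembly, derivatives, optimisation, recovery logic — not the
biophysical accuracy of any prediction; the latter is inherited entirely
from the trained parameter set and constraint file a user supplies.

## Numerical choices

* Rotations: Gibbs vectors $g = \tan(\theta/2)\,k$, scale 10; decoding
  fails loudly within a quarter degree of $\theta = \pi$ (never reached
  in practice: per-junction rotations are ~0.6 rad).
* Log-determinants: sparse Cholesky; dense determinants appear only as
  test oracles ($N \le 80$).
* Monte-Carlo normalisation checks use importance sampling from an
  isotropic Gaussian sized by a dense eigendecomposition of the toy
  stiffness — independent of the Cholesky path under test, and with
  bounded weight variance (a uniform box at the same sample size would
  be noisier than the 2% gate).
* Degenerate inputs: empty constraint sets short-circuit to the ground
  state; collinear point sets make `superpose()` fail rather than return
  an arbitrary rotation; flat radial profiles (range below $10^{-6}$
  relative) are rejected instead of yielding noise-driven minima;
  sequences with ambiguity codes are rejected at parse time.
* The scan workflow (`cmd_scan`) checkpoints one row per window and skips
  completed windows on rerun, since genome-scale scans are long-running
  by nature.

Problem sizes in the shipped tests and the acceptance script are chosen
to exercise every code path at desk scale: toy fragments of 6–20 bp for
oracle and derivative checks, 100-structure ensembles, and a 24-run
147-bp ensemble study (two sequences per CpG bin, three modification
states) at tolerance $10^{-5}$; a single 147-bp minimisation takes a few
seconds on one core.

## Reproducing published benchmarks

`reproduce_published_benchmarks()` runs the full workflow on externally
supplied inputs: a trained parameter set converted to the portable
container, the matching bound-phosphate constraint file, and a FASTA of
benchmark sequences. Neither the trained parameters nor the constraint
file are shipped — they are distributed by their authors — so the
corresponding acceptance test is expected to fail until converted copies
are placed under `inst/external/`. With synthetic inputs the package
makes no claim about absolute wrapping energies of specific biological
sequences.

## Known limitations

* Histone tails, ions, ligands, and end-anchoring of the terminal ~5 bp
  are not modelled; end unwrapping is accepted behaviour.
* The penalty Hessian is Gauss–Newton only; near-optimal convergence is
  linear rather than quadratic (typically 60–100 iterations at 147 bp).
* Steric self-overlap is diagnosed post hoc, not constrained during
  optimisation.
* The probability density is a one-point proxy for the probability of
  reaching the wrapped configuration; comparisons across sequences assume
  equal domain volumes.
* Hemi-methylation and ambiguity codes are unsupported (the parameter
  alphabet has neither).
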