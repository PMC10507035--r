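---
title: "Selecting structure ensembles against polarized VSFG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting structure ensembles against polarized VSFG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vibrational sum-frequency generation (VSFG) spectroscopy of the amide-I band
is interface-specific: only protein molecules sitting at an interface emit,
and the lineshapes and relative intensities of the four recorded
polarization combinations (SSP, PPP, SPS achiral; PSP chiral) encode both
secondary structure and orientation. For an intrinsically disordered protein
such as alpha-synuclein bound to an anionic lipid monolayer, no single rigid
model structure explains such data. `viscaselect` implements the
frame-selection strategy: a large library of candidate conformations (for
instance the frames of out-of-equilibrium MD trajectories) is scored
spectroscopically, and the subset that best reproduces the measured spectra
— as an ensemble — is retained and characterized structurally.

## The spectroscopic model

Each peptide bond contributes one amide-I chromophore. For the bond between
residues $i$ and $i{+}1$, the transition dipole sits at
$\mathbf{r}_i = \mathbf{C} + d_\mathrm{off}\,\widehat{\mathbf{CO}}$ and
points at an angle $\theta_\mathrm{dip}$ from the C=O bond toward the amide
N, inside the O–C–N plane. The local Raman tensor is axially symmetric about
the dipole with principal values $(1, \rho, \rho)$. The one-exciton
Hamiltonian is

$$H_{ii} = \omega_i,\qquad
  H_{i,i\pm1} = J_\mathrm{NN},\qquad
  H_{ij} = A\,\frac{\hat e_i\!\cdot\!\hat e_j -
  3(\hat e_i\!\cdot\!\hat n)(\hat e_j\!\cdot\!\hat n)}{r_{ij}^3}
  \ \ (|i-j|>1),$$

i.e. through-bond nearest-neighbor coupling plus transition dipole coupling
(TDC) for all other pairs. Diagonalizing $H$ gives delocalized eigenmodes
$q$ with collective transition dipoles $\mathbf{M}_q = \sum_i c_{qi}\hat
e_i$ and Raman tensors $\mathbf{A}_q = \sum_i c_{qi}\alpha_i$. The
hyperpolarizability spectrum

$$\beta_{abc}(\omega) = \sum_q
  \frac{A_{q,ab}\,M_{q,c}}{\omega_q - \omega - i\,\Gamma/2}$$

is averaged over rotations about the interface normal $z$ (the monolayer is
azimuthally isotropic) to produce the lab-frame susceptibility
$\chi^{(2)}_{IJK}(\omega)$, from which the four polarized intensities follow:
$I_\mathrm{SSP}\propto|\chi_{yyz}|^2$, $I_\mathrm{SPS}\propto|\chi_{yzy}|^2$,
$I_\mathrm{PPP}\propto|w_1\chi_{xxz}+w_2\chi_{xzx}+w_3\chi_{zxx}+w_4\chi_{zzz}|^2$,
and $I_\mathrm{PSP}\propto|\chi_{xyz}$-type chiral terms$|^2$.

A useful exactness property: the azimuthal average of a rank-3 tensor is a
trigonometric polynomial of degree three in the rotation angle, so the
uniform $n$-point average is *exact* for every $n_\phi \ge 4$. The package
defaults to $n_\phi = 36$ and treats $n_\phi = 0$ as an analytic sentinel
evaluated with the minimal 4-point rule; the two agree to machine precision,
which the test suite asserts.

### Parameter defaults and why

| parameter | default | meaning |
|---|---|---|
| `omega0` | 1690 cm⁻¹ | uncoupled local amide-I′ frequency |
| `A` | 580 cm⁻¹·Å³ | TDC prefactor; gives non-neighbor couplings of ~1–10 cm⁻¹ |
| `theta_dip` | 20° | dipole tilt from C=O toward N |
| `d_off` | 0.868 Å | dipole anchor offset along C=O |
| `J_nn` | −8.5 cm⁻¹ | nearest-neighbor (through-bond) coupling |
| `gamma` | 12 cm⁻¹ | Lorentzian FWHM of a single-mode $|\chi|^2$ peak |
| `rho` | 0.25 | Raman tensor anisotropy |

All of these are conventions of the standard amide-I exciton
parameterization and every one is exposed in `exciton_params()` and the run
configuration. Two deserve comment.

**The local frequency.** In a helical chain the negative nearest-neighbor
and TDC couplings red-shift the bright, in-phase exciton mode by up to
~50 cm⁻¹ below the local frequency. A local frequency of 1650 cm⁻¹ would
therefore place the calculated band *below* the 1600–1700 cm⁻¹ amide-I
scoring window, where it cannot be scored meaningfully. With
`omega0 = 1690` the coupled helical band sits near 1640 cm⁻¹, matching
where amide-I′ bands of membrane-bound proteins are observed. Because the
model applies one uniform local frequency (no electrostatic/H-bond
frequency map — deliberately out of scope), absolute band positions are
model-relative: selection compares calculated spectra with experimental
spectra through lineshapes and inter-polarization ratios, not through
absolute frequencies of individual conformers.

**The linewidth.** The selection outcome is robust against the homogeneous
width up to an FWHM of 12 cm⁻¹, and that upper value is the default; smaller
values sharpen exciton substructure without changing the qualitative
ranking.

## Scoring and the std-matched cutoff

For each frame the four calculated spectra are compared with the
experimental ones on the common grid inside the scoring window
(1600–1700 cm⁻¹ by default, excluding the lipid ester carbonyl region that
the model does not simulate). A single non-negative scale
$s = \max\!\big(0, \sum I_\mathrm{exp} I_\mathrm{calc} \big/ \sum
I_\mathrm{calc}^2\big)$, joint across all polarization combinations so that
their intensity ratios are preserved, is fitted per frame; the score is the
residual sum of squares (RSS) of the scaled spectra over all scored points
and polarization combinations. Because residuals are absolute, stronger
polarization combinations dominate the score — including the chiral PSP
channel, whose near-zero experimental intensity penalizes frames with
spurious chiral responses.

Frames are ranked by ascending RSS (ties broken by frame index) and the
ensemble grows from the top of the ranking until the *pooled standard
deviation of the calculated spectra inside the ensemble* first reaches the
*pooled experimental standard deviation* — the point at which the ensemble
explains as much spectral spread as the measurement itself exhibits across
replicates. Pooling is the mean of per-point ($n{-}1$) standard deviations
over the scored window and polarization combinations, applied identically
to scaled calculated intensities and to experimental replicates. The RSS of
the last included frame is the reported threshold, and membership is
exactly the set of frames at or below it. This first-crossing rule is
deterministic, and nested: a larger experimental spread can only enlarge
the ensemble.

Degenerate cases are defined, not left to chance: a zero experimental
spread selects the set of rank-1-tied frames; if even the full library's
spread stays below the experimental one, the whole library is returned with
`crossed = FALSE`.

## Structural characterization

Selected ensembles are summarized per residue by

* **helicity** — the fraction of members in which the residue is assigned
  `H` by a simplified (3-state) Kabsch–Sander secondary-structure
  assignment: hydrogen bonds from the electrostatic energy
  $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol with a bond below −0.5, helices from pairs of consecutive
  n-turns, strands from bridges, and the full states reduced as
  {H,G,I}→H, {E,B}→E, else C. Amide hydrogens absent from the input are
  placed 1.01 Å from N opposite the preceding carbonyl, the classic DSSP
  construction. The implementation is validated against an independent
  reference implementation on helix, coil and sheet fixtures (≥95%
  per-residue agreement is asserted);
* **minimum lipid distance** — per frame, the minimum Euclidean distance
  from any atom of the residue (all atoms, not only backbone) to any lipid
  atom, averaged over members;

each with its standard error of the mean over members, plus segment
averages over the alpha-synuclein regions (N-terminal 1–60, NAC 61–95,
C-terminal 96–140).

## What the synthetic generator emulates

The package ships generators rather than stored fixtures: ideal poly-alanine
helices from canonical internal coordinates, seeded random coils from a
broad PPII/extended dihedral region, a hydrogen-bonded antiparallel
two-strand sheet, rigid reorientation utilities, a planar pseudo-lipid slab,
and noisy replicate "experimental" datasets formed from known frame
mixtures.

The flagship scenario (`fixture_library()`) emulates the study geometry: a
140-residue protein whose first 50 residues form a helix lying on the slab
(the lipid-anchored N-terminal segment), continued by a second helical arm
that either stays flat (tilt 83–97°) or protrudes upright (tilt 0–20°),
plus fully disordered coil frames above the slab. Design choices, made once
and kept:

* **Dihedral disorder of 10° (s.d.) per residue.** Frames within a class
  must differ spectrally — the selection cutoff is driven by ensemble
  spread — and surface-bound alpha-synuclein is a broken, imperfect helix,
  not a rigid rod.
* **Roll-locked helices (±10°).** Amphipathic helices bind a membrane with
  a fixed face, which fixes the rotation of the helix about its own axis.
  Physically this makes the small out-of-plane dipole components of
  flat-lying helices coherent across frames; without it the flat class is
  an unstable near-null emitter, since a perfectly horizontal ideal helix
  has vanishing achiral response after azimuthal averaging.
* **Replicate noise of 0.2% of the dataset peak, 30 replicates.**
  Replicate-averaged VSFG datasets accumulated over many acquisitions are
  high-signal-to-noise; the informative quantity for the cutoff is the
  *replicate* standard deviation, which must sit below the inter-class
  spectral separation for any selection method to discriminate classes.
* **Rejection of self-intersecting backbones.** The builders carry no
  sterics, so frames whose non-neighboring carbonyl carbons approach below
  1.5 Å are redrawn.

What the generator does **not** emulate: real lipid chemistry (the slab is
a geometric stand-in for distance and orientation analyses only), solvent,
electrostatic frequency shifts, surface-induced conformational bias of
coils, or exchange dynamics between conformations. Passing the recovery
tests therefore demonstrates that the scoring and selection machinery
discriminates orientation/structure classes under controlled conditions —
not that the exciton parameterization is quantitative for any particular
real protein.

## Chirality: what "silent" means here

Ideal helices are chiral-VSFG silent in this model: their PSP intensity is
below $10^{-3}$ of the strongest achiral combination (measured: ~$10^{-7}$),
while an antiparallel two-strand sheet produces a PSP response orders of
magnitude larger. Individual random-coil *conformers*, by contrast, are
strongly chiral objects; coil silence is an ensemble effect, in which the
coherent chiral amplitudes of independent conformers cancel. Because the
geometric coil generator is conformationally near-isotropic, its
ensemble-averaged *achiral* response also shrinks, so an intensity ratio is
not the right statistic; the package's tests instead assert that the
per-unit coherent chiral amplitude of a 1000-conformer coil ensemble falls
far below both the sheet reference and the single-conformer level. A small
residual bias (~2% of the sheet's per-unit amplitude) remains — the
L-backbone dihedral region is itself chiral — and is documented rather than
suppressed.

## Numerical choices and degenerate inputs

* Azimuthal averaging is exact for $n_\phi\ge4$ (see above); rotations and
  eigen-decompositions use dense linear algebra (`eigen(symmetric = TRUE)`),
  adequate for the ≤139-unit Hamiltonians of a 140-residue chain.
* Chain breaks (C–N distance > 2.5 Å) create no amide unit and produce a
  warning; chromophore pairs closer than 0.5 Å are a geometry error.
  Proline units are retained with identical parameters and flagged.
  Missing backbone atoms abort unit extraction with the residue named;
  in DSSP they demote the residue to coil with a warning.
* All randomized generators are pure functions of their seed; the RNG state
  of the caller is saved and restored around every seeded block.
* Frame ranking skips (optionally) frames whose spectral calculation fails
  and reports the count; ties in RSS are broken by the global frame index.

## Problem sizes used in the shipped checks

The test-suite scenarios use a 200-frame library of 140-residue proteins
over a 900-atom slab (the flagship recovery), 1000 25-residue coil
conformers (chiral cancellation), $10^4$ random rotations (isotropy null),
and a 37×36-point orientation scan of a 30-residue helix at 5°/10° steps.
These sizes keep the full suite within a few minutes on one CPU while
leaving each statistical assertion a comfortable margin; all scale linearly
for larger studies, and the pipeline accepts trajectory strides for
down-sampling real data.

## Known limitations

* No electrostatic or hydrogen-bond frequency map: per-unit frequency
  shifts can be supplied externally (`delta_omega`), but are not computed.
* Fresnel/local-field factors default to unity weights; quantitative
  inter-polarization ratios for a specific optical geometry require the
  user to supply the complex weights for their beam angles.
* No two-exciton states, anharmonicity, isotope labeling, heterodyne
  phases, or non-resonant backgrounds beyond an optional complex constant.
* Hard-threshold selection as published — no Bayesian or maximum-entropy
  reweighting of the library.
* XTC trajectories are not read; use DCD or multi-model PDB streams.
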