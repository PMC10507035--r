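Package: viscaselect
Title: Frame Selection Against Polarized Vibrational Sum-Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates polarized amide-I vibrational sum-frequency generation
    (VSFG) spectra from protein structure frames with a one-exciton Hamiltonian
    (transition dipole coupling, Lorentzian lineshapes, azimuthal interface
    averaging), scores every frame of a trajectory library against experimental
    SSP/PPP/SPS/PSP spectra by residual sum of squares, and selects the
    best-matching conformational ensemble with a cutoff at which the spectral
    spread inside the ensemble equals the experimental standard deviation.
    Selected ensembles are characterized structurally: per-residue helicity via
    a simplified Kabsch-Sander secondary-structure assignment, per-residue
    minimum distance to lipid atoms, and segment summaries. Includes synthetic
    fixture generators (ideal helices, random coils, oriented frames,
    pseudo-lipid slabs, noisy replicate spectra) and a scriptable pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
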