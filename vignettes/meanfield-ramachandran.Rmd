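---
title: "A steric and Lennard-Jones mean field for residue-specific Ramachandran distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steric and Lennard-Jones mean field for residue-specific Ramachandran distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`ramafield` asks how much of the residue-specific conformational
preference of alanine, valine, leucine and isoleucine in the unfolded
state can be explained by exactly two ingredients: short-range repulsion
between the side chain and the backbone, and a mean attractive
backbone–water interaction. Everything else is deliberately excluded —
no electrostatics or partial charges, no atom types, no solvent degrees
of freedom, no dihedral potential terms, no dynamics. The output
distributions therefore characterize the *minima* of a free-energy
landscape; they carry no kinetic or diffusive information.

The unit of computation is a residue **mimetic**: the residue plus the
preceding carbonyl (C′, O) and the following amide (N, H). The caps are
retained because peptide-group atoms of the adjacent residues contribute
to the sterics of a central residue, especially for longer side chains;
they are treated as electrostatically neutral ends. Assumptions baked
into the builder:

* idealized, fixed internal coordinates (standard Engh–Huber-type bond
  lengths and angles) — vibrational degrees of freedom are frozen, with
  the N–Cα–C′ angle exposed as a parameter (default 110°, with 105° and
  115° as variant geometries) precisely because it modulates the
  backbone–side-chain distances;
* planar trans peptide bonds (ω = 180°), never modified by any torsion
  operation;
* L-chirality at Cα, preserved exactly by the rotation operators;
* only standard heavy-atom side-chain torsions are scanned (χ₁ for
  valine; χ₁, χ₂ for leucine and isoleucine); methyl rotations are held
  fixed, and alanine has no scanned torsion at all.

For every (φ, ψ) bin the nested product of side-chain configurations is
enumerated on a full 360° grid per χ, and two quantities are averaged
over eligible atom pairs (≥ 4 covalent bonds apart, hydrogens included):
the number of hard-sphere overlaps (r < R_s, strict) and the total 12-6
Lennard-Jones energy. Lennard-Jones averaging is restricted to
*admissible* configurations, those whose every backbone–side-chain pair
is farther than λ·R_s; the average itself still runs over **all**
eligible pairs, so backbone–backbone repulsion survives and keeps the
right half-plane of Ramachandran space expensive. Cap atoms count as
backbone for the admissibility mask, since they are peptide-group atoms.
The water term is the Boltzmann inversion of a Gaussian-mixture
Ramachandran density for alanine and is reused unchanged for all four
residues, encoding the assumption that backbone hydration is
residue-independent for apolar side chains.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `lambda` | — | sweep {0} ∪ {0.70 … 1.00 by 0.05} | the single hyperparameter; scales the exclusion radius λ·R_s. λ = 0 excludes nothing; λ = 1 excludes every hard-sphere clash. |
| `backbone_step`, `chi_step` | degrees | 2 (reference), coarser for routine runs | grid resolutions; populations and couplings change by < 0.01 between 2° and 1° for smooth densities (tested), so 6–15° grids are adequate for summaries. |
| `backbone_angle` | degrees | 110 | the N–Cα–C′ angle; 105/115 variants probe the frozen vibrational degree of freedom. |
| `penalty` | kJ/mol | 500,000 | energy of bins with no admissible configuration; large enough that the Boltzmann weight underflows to exactly zero. |
| `temperature` | K | 298 | sets RT ≈ 2.479 kJ/mol for both directions of the Boltzmann conversion. |
| contact radii R_s | Å | reduced ("outer limit") canonical hard-sphere set | see design choices below; configurable. |
| LJ ε, r_min/2 | kJ/mol, Å | element-level CHARMM-style values | the nitrogen entry is pinned by the reference pair energies (≈ 4.2·10⁴ kJ/mol at 1.5 Å, ≈ 5.4·10⁶ at 1.0 Å); other elements use representative values since atom types are deliberately absent. |

## What the shipped inputs emulate — and what they do not

Three shipped configuration files are stand-ins for external data and are
labelled as such in their headers:

* `gaussian_ala_synthetic.yaml` — a three-component approximation
  (dominant pPII basin, β basin, minor αR basin) with the qualitative
  structure of the published empirical alanine model of
  Schweitzer-Stenner and co-workers, whose fitted parameters are not
  redistributed here. Population and coupling *values* therefore differ
  from what the real model would give, while trends in λ and between
  residues are preserved.
* `mesostates.yaml` — rectangle boundaries approximating the conventions
  of the GxG / unfolded-state literature. All reports carry the boundary
  file used.
* `reference_couplings.yaml` — literature-typical experimental couplings;
  only the leucine ³J(HN,Hα) value (6.78 Hz) is taken directly from the
  comparison literature for this method.

Likewise the builder's idealized geometry is a stand-in for any
externally distributed mimetic coordinates; `read_mimetic()` accepts such
PDB files (CONECT records required) so they can be substituted without
touching the code. Consequently, passing tests demonstrate the
correctness of the machinery and the robustness of the qualitative,
residue-specific picture (alanine λ-insensitive and pPII-dominated;
valine's β mass monotone in λ; leucine and isoleucine without clash-free
backbone bins), not quantitative agreement with any particular published
table.

## Numerical choices

* **Bins** are half-open with centers at −180° + Δ/2 + kΔ (for Δ = 2°:
  −179°, −177°, …, 179°); torsions are evaluated at bin centers, and
  mesostate membership is by bin center with half-open rectangle edges,
  so shared boundaries partition unambiguously.
* **Strict inequalities** throughout: r < R_s counts as an overlap; a
  backbone–side-chain pair at exactly λ·R_s makes a configuration
  inadmissible.
* **χ sweep phase**: each sweep starts at the built structure's current
  torsion value (all χ = 180° from the builder). Averages over a full
  360° sweep are start-invariant at commensurate steps, and summation
  order (outermost-first vs innermost-first) provably does not matter;
  both are tested.
* **Boltzmann inversion** floors nothing silently: a zero-probability bin
  is an error, and the reference p₀ is always the distribution's own
  minimum, recorded in the grid metadata. The reverse conversion
  subtracts the minimum energy before exponentiating, so penalty bins
  underflow to zero instead of overflowing anything.
* **Scan engine**: instead of rebuilding coordinates per configuration,
  eligible pairs are classified by which χ torsions move them relative
  to each other (fixed / χ₁-only / χ₂-only / both), rigid-rotation
  positions for a whole sweep are generated at once, and the
  both-angles block reduces to one small matrix product per backbone/cap
  atom. The decomposition is exact — unit tests require equality with a
  brute-force rebuild oracle at 10⁻¹⁰ relative tolerance — and makes
  degree-scale grids tractable in pure R. Admissibility for any number
  of λ values comes from a single pass by tracking min(d²/R_s²) per
  configuration.
* **Degenerate inputs**: missing element pairs in the radii or LJ tables
  are rejected by name; disconnected bond graphs, overlapping mesostate
  rectangles, non-positive Gaussian widths and mismatched grid shapes
  are all rejected at construction.

## Design choices that were genuinely open

* **Contact radius set.** The canonical hard-sphere analysis offers two
  radius sets ("normally allowed" and the reduced "outer limit"). Both
  leave alanine with clash-free β/pPII bins and leucine/isoleucine with
  none; only the reduced set also gives valine clash-free bins in parts
  of its β region, matching the expected picture, so the reduced set
  ships as the default and the other is documented in the config header.
* **Element-level LJ parameters.** With atom types excluded by design,
  one parameter pair per element must stand for mixed chemistry. The
  nitrogen values are fixed by the reference pair energies; carbon,
  oxygen and hydrogen use the carbonyl-C, carbonyl-O and aliphatic-H
  values as the chemistry most represented in the mimetics.
* **Torsion conventions.** Standard backbone conventions (trans = 180°,
  the sign convention under which left-handed helices have positive φ);
  χ angles over the standard heavy-atom paths with PDB v3 branch naming,
  validated against measured improper dihedrals of real protein
  structures, including the isoleucine Cβ stereocenter.
* **Scan resolutions.** The test suite runs oracle comparisons at
  30–90° steps, qualitative landscape checks at 6° and λ-response checks
  at 15°/30°; the acceptance script uses 6° backbone grids for
  alanine/valine and 10° for leucine/isoleucine with the full λ ladder.
  These sizes were chosen so that the quadrature error is far below the
  0.01 population resolution of interest (verified by the refinement
  test) while a complete run stays in the minutes range on one CPU.

## Known limitations

* Populations and couplings inherit every bias of the synthetic water
  model and the idealized geometry; quantitative comparison with
  experimental tables requires supplying the real external inputs via
  the config files.
* Peaks of the derived distributions are much narrower than
  experimentally derived ones — the model has no diffusive broadening,
  so coupling averages weight narrow basins too strongly.
* The admissibility rule makes the λ response discontinuous: small λ
  changes can admit or remove whole configuration families at once
  (clearly visible for isoleucine). The λ ladder, not any single value,
  is the meaningful object.
* Only ALA/VAL/LEU/ILE topologies ship; the engine supports at most two
  nested χ torsions, and polar or charged side chains would need the
  interactions the model deliberately omits.
* The mean field is strictly local to one residue: no nearest-neighbor
  coupling, no sequence context.
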