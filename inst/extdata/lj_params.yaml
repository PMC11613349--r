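# Element-level 12-6 Lennard-Jones parameters (no atom types: every atom of
# an element shares one parameter set).  epsilon in kJ/mol (well depth),
# rmin_half in Angstrom (half the pair-minimum distance, CHARMM convention:
# E(r_min) = -epsilon with r_min = rmin_half_i + rmin_half_j).  Pair
# parameters follow Lorentz-Berthelot combination: arithmetic mean of radii,
# geometric mean of well depths.
#
# Defaults are CHARMM-type values for the representative chemistry of the
# mimetics: amide nitrogen (0.20 kcal/mol, 1.85 A), carbonyl carbon
# (0.11, 2.00), carbonyl oxygen (0.12, 1.70), aliphatic hydrogen
# (0.022, 1.32), converted at 4.184 kJ/kcal.  The nitrogen entry reproduces
# the reference pair energies 4.2e4 kJ/mol (N-N, 1.5 A) and 5.4e6 kJ/mol
# (N-N, 1.0 A).
combination_rule: lorentz-berthelot
elements:
  C: {epsilon: 0.46024, rmin_half: 2.000}
  "N": {epsilon: 0.83680, rmin_half: 1.850}
  O: {epsilon: 0.50208, rmin_half: 1.700}
  H: {epsilon: 0.09205, rmin_half: 1.320}
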