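# Experimental reference J-couplings (Hz) for central residues in GxG
# host peptides, used by deviation reports.  The leucine 3J(HN,HA) value is
# the one quoted alongside this method's results; the remaining entries are
# literature-typical values for these residues and should be replaced with
# the exact experimental set before quantitative comparison.  Uncertainties
# are typical instrumental estimates.
references:
  ALA: {J3_HN_HA: {value: 5.60, uncertainty: 0.3}, J1_N_CA: {value: 11.36, uncertainty: 0.3}}
  VAL: {J3_HN_HA: {value: 7.30, uncertainty: 0.3}, J1_N_CA: {value: 11.10, uncertainty: 0.3}}
  LEU: {J3_HN_HA: {value: 6.78, uncertainty: 0.3}, J1_N_CA: {value: 11.20, uncertainty: 0.3}}
  ILE: {J3_HN_HA: {value: 7.60, uncertainty: 0.3}, J1_N_CA: {value: 11.00, uncertainty: 0.3}}
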