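# Karplus relations J(theta) = A cos^2(theta + offset) + B cos(theta +
# offset) + C, coefficients in Hz, offset in degrees.  3J(HN,HA) depends on
# phi (Wang-Bax parametrization, theta = phi - 60); 1J(N,CA) depends on psi
# (Wirmer-Schwalbe parametrization).  Override to use other
# parametrizations.
couplings:
  J3_HN_HA: {A: 7.09, B: -1.42, C: 1.55, offset: -60, angle: phi}
  J1_N_CA:  {A: 1.70, B: -0.98, C: 9.51, offset: 0,   angle: psi}
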