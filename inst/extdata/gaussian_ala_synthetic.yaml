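# Gaussian-mixture Ramachandran model for the backbone-water free-energy
# term: a weighted sum of 2D Gaussians in (phi, psi), each defined by a
# peak center, widths and an optional phi-psi correlation, evaluated with
# periodic wrapping.
#
# SYNTHETIC STAND-IN.  The published empirical model for central alanine in
# GAG (fitted elsewhere to amide I' band profiles and NMR J-couplings) is
# an external input whose parameters are not redistributed here.  This file
# encodes a three-component approximation with the qualitative structure of
# that model -- a dominant pPII basin, a beta basin in the transition
# region, and a minor right-handed helical basin -- and is intended to be
# replaced by the real parameter set when available.  Weights sum to 1;
# centers/widths in degrees.
components:
  - {name: pPII,   weight: 0.72, phi0: -70,  psi0: 150, sigma_phi: 14, sigma_psi: 18, rho: 0}
  - {name: beta,   weight: 0.22, phi0: -115, psi0: 150, sigma_phi: 16, sigma_psi: 16, rho: 0}
  - {name: alphaR, weight: 0.06, phi0: -60,  psi0: -40, sigma_phi: 12, sigma_psi: 12, rho: 0}
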