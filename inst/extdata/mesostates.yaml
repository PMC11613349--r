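# Mesostate rectangles in Ramachandran space, [phi_min, phi_max, psi_min,
# psi_max] in degrees with half-open membership [min, max).  Rectangles must
# not overlap; bins outside every rectangle are reported as "other".
#
# The boundaries approximate the conventions used in the GxG / unfolded-
# state literature: pPII adjacent to the beta strand basins with the
# antiparallel-beta / transition / pPII split along phi, parallel-beta at
# lower psi, and the right-handed helical basin below.  Reports name the
# boundary file used; replace this file to use a different convention.
mesostates:
  pPII:   [-90, -50, 110, 180]
  bt:     [-125, -90, 110, 180]
  ab:     [-180, -125, 110, 180]
  pb:     [-180, -90, 50, 110]
  aR:     [-100, -30, -70, 10]
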