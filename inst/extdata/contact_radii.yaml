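# Minimum approach distances R_s (Angstrom) between non-bonded atom pairs,
# below which two atoms count as sterically overlapping.  Defaults are the
# canonical hard-sphere contact limits of Ramachandran and co-workers in
# their reduced ("outer limit") form, which reproduces the expected
# clash-free regions for alanine and valine; the larger "normally allowed"
# set (C-C 3.20, C-N 2.90, C-O 2.80, C-H 2.40, N-N/N-O/O-O 2.70,
# N-H/O-H 2.40, H-H 2.00) can be substituted by overriding this file.
units: angstrom
pairs:
  C-C: 3.00
  C-N: 2.80
  C-O: 2.70
  C-H: 2.20
  N-N: 2.60
  N-O: 2.60
  N-H: 2.20
  O-O: 2.60
  O-H: 2.20
  H-H: 1.90
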