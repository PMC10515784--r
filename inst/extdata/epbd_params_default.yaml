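# Default EPBD model parameters.
#
# Morse well depths/widths are the classic homogeneous Peyrard-Bishop-Dauxois
# constants for A.T and G.C pairs (melting-experiment-derived values in wide
# use for this model family). The dinucleotide stacking table is an
# illustrative, reverse-complement-symmetric set in the physical range around
# the homogeneous value 0.025 eV/A^2; replace it with a melting-calibrated
# table for production work. All values are plain inputs: every computation in
# the package holds for any valid parameter set.
#
# Units: depths in eV, widths in 1/Angstrom, stacking k in eV/Angstrom^2,
# b in 1/Angstrom, rho dimensionless, kB in eV/K, bounds in Angstrom.
morse_depth:
  AT: 0.05
  GC: 0.075
morse_width:
  AT: 4.2
  GC: 6.9
stacking:
  rho: 2.0
  b: 0.35
  k:
    AA: 0.021
    AC: 0.024
    AG: 0.0245
    AT: 0.0215
    CA: 0.026
    CC: 0.028
    CG: 0.029
    CT: 0.0245
    GA: 0.025
    GC: 0.027
    GG: 0.028
    GT: 0.024
    TA: 0.020
    TC: 0.025
    TG: 0.026
    TT: 0.021
kB: 8.617333262e-5
bounds:
  y_min: -2.0
  y_max: 20.0
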