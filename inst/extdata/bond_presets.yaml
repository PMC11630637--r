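# Catch-slip bond kinetic presets for alpha5beta1-integrin / fibronectin.
#
# Koff(f) = Ka*exp(f/Fa) + Kb*exp(-f/Fb); units: rates 1/s, forces pN,
# kint pN/nm, rho_max bonds/um^2.
#
# The wild-type parameters give a unimodal (catch) lifetime curve with a
# zero-force occupancy Kon/(Kon+Koff(0)) of ~0.2, a zero-force lifetime of
# ~0.4 s and a lifetime maximum of ~5.7 s at ~17.7 pN, in the range reported
# for alpha5beta1-fibronectin single-molecule catch bonds. The synergy-site
# mutant R1374/9A is modelled as a rescaled catch bond: association is
# RGD-driven and kept unchanged, while both dissociation prefactors are
# scaled up (x13.475) so the zero-force equilibrium bond concentration is
# 11-fold lower than wild-type, matching the measured 11-fold affinity loss.
wildtype:
  Kon: 0.5
  Ka: 0.02
  Fa: 10.0
  Kb: 2.0
  Fb: 5.0
  kint: 0.5
  rho_max: 100.0
mutant_R1374_9A:
  Kon: 0.5
  Ka: 0.2695049504950495
  Fa: 10.0
  Kb: 26.95049504950495
  Fb: 5.0
  kint: 0.5
  rho_max: 100.0
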