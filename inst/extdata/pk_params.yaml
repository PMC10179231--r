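# Named pharmacokinetic parameter sets for the three-compartment
# effect-site model. Units: v1 in L, rate constants in 1/min.
#
# shafer_fentanyl: a representative adult fentanyl parameterization in the
# Shafer three-compartment family with a first-order effect compartment.
# These constants are configuration defaults, not fitted values: the engine
# accepts any valid parameter block, and analyses should state which block
# they used. ref_weight_kg enables the optional linear weight scaling of v1
# (off unless a weight is passed).
shafer_fentanyl:
  v1: 6.09
  k10: 0.0827
  k12: 0.4726
  k21: 0.2186
  k13: 0.2250
  k31: 0.0136
  ke0: 0.147
  ref_weight_kg: 70

# one_compartment_demo: degenerate configuration used in documentation
# examples; k12 = k13 = 0 reduces the model to mono-exponential kinetics.
one_compartment_demo:
  v1: 10
  k10: 0.1
  k12: 0
  k21: 0.05
  k13: 0
  k31: 0.02
  ke0: 0.5
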