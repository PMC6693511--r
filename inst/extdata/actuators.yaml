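# Joint MTG parameters for the 9-DoF walking model.
# PLACEHOLDER strengths: not fitted to any subject; chosen so that the
# strength-scaled damping beta = eta*(tau_o_F + tau_o_E)/(w_F + w_E) lies in
# the 2.7-7.3 N m s/rad range with eta = 2.  Signs follow the CCW-positive
# joint coordinates: hip flexion +, knee flexion -, ankle dorsiflexion +.
eta: 2.0
ecc: 1.35
tau_act: 0.015       # s
tau_deact: 0.050     # s
variant: mean        # activation-dynamics reading: mean | switched
joints:
  hip:
    flexor:    { tau_o: 110.0, omega_max: 36.0, sign:  1, theta_opt:  0.40, width: 2.0 }
    extensor:  { tau_o: 160.0, omega_max: 38.0, sign: -1, theta_opt: -0.10, width: 2.0 }
  knee:
    flexor:    { tau_o:  90.0, omega_max: 36.0, sign: -1, theta_opt: -0.90, width: 2.0 }
    extensor:  { tau_o: 150.0, omega_max: 34.0, sign:  1, theta_opt: -0.20, width: 2.0 }
  ankle:
    flexor:    { tau_o:  45.0, omega_max: 35.0, sign:  1, theta_opt:  0.10, width: 2.0 }
    extensor:  { tau_o: 140.0, omega_max: 30.0, sign: -1, theta_opt: -0.20, width: 2.0 }
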