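# Default foot-ground contact geometries (ankle-frame parameters, cm).
# These are fitted roll-over parameters for a 30.5 cm (shoed) foot; both
# models have total length 30.5 cm.
ellipse:
  units: cm
  r_E: [4.30, -8.11]     # ankle -> ellipse centre
  theta_E: 0.0           # ellipse orientation relative to the ankle frame (rad)
  r_x: 15.25             # semi-major axis
  r_y: 4.03              # semi-minor axis
double_circle:
  units: cm
  r_H: [-6.19, -6.64]    # ankle -> heel-circle centre
  rad_H: 4.87
  r_F: [11.97, -6.56]    # ankle -> forefoot-circle centre
  rad_F: 7.46
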