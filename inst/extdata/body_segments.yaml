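# Segment inertial-parameter regression table for the planar 7-segment model.
# Mass fractions of total body mass, lengths and COM positions as fractions
# of stature or segment length, radii of gyration about the segment COM as a
# fraction of segment length.  Values follow the conventional gait-analysis
# regression tables (Winter-style); head, arms and torso are lumped into the
# floating-base HAT segment, an explicit assumption of the planar model.
segments:
  hat:
    # mass fraction is the remainder 1 - 2*(thigh + shank + foot)
    length_frac: 0.530      # hip to vertex, used only to place COM / inertia
    com_frac: 0.370         # COM height above the hip, fraction of HAT length
    rog_frac: 0.310
  thigh:
    mass_frac: 0.1000
    length_frac: 0.245
    com_frac: 0.433         # below the hip, fraction of thigh length
    rog_frac: 0.323
  shank:
    mass_frac: 0.0465
    length_frac: 0.246
    com_frac: 0.433
    rog_frac: 0.302
  foot:
    mass_frac: 0.0145
    length_frac: 0.152
    com_x_frac: 0.250       # forward of the ankle, fraction of foot length
    com_z_frac: 0.220       # below the ankle, fraction of foot length
    com_frac: 0.500
    rog_frac: 0.475
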