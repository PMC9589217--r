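# Template waveforms for the synthetic single-stance gait trial.
# Each entry lists control points over % stance [0, 100]; waveforms are
# natural cubic splines through these points. Angles in degrees, pelvis
# translations in mm (vertical offset is added to the model-derived pelvis
# height), GRF in body weight, COP in foot-local mm (heel negative X).
angles:
  pelvis_tx: {t: [0, 25, 50, 75, 100], v: [0, 190, 385, 580, 770]}
  pelvis_ty: {t: [0, 25, 50, 75, 100], v: [0, 8, 14, 8, -6]}
  pelvis_tz: {t: [0, 25, 50, 75, 100], v: [0, 14, 19, 14, 2]}
  pelvis_rx: {t: [0, 50, 100], v: [1.0, -1.5, 1.0]}
  pelvis_ry: {t: [0, 50, 100], v: [-2.0, 0.0, 2.5]}
  pelvis_rz: {t: [0, 50, 100], v: [1.5, 0.0, -1.5]}
  hip_flex:  {t: [0, 25, 50, 75, 100], v: [25, 14, 2, -8, -12]}
  hip_add:   {t: [0, 25, 50, 75, 100], v: [1.5, 5, 4, 2, -2]}
  hip_rot:   {t: [0, 50, 100], v: [-3, 0, 4]}
  knee_flex: {t: [0, 12, 25, 50, 75, 90, 100], v: [5, 14, 18, 8, 13, 30, 42]}
  ankle_flex: {t: [0, 10, 25, 50, 80, 100], v: [-4, 2, 5, 9, 12, -16]}
grf:
  vertical_bw: {t: [0, 5, 15, 25, 38, 50, 62, 74, 88, 97, 100],
                v: [0, 0.45, 0.95, 1.10, 0.95, 0.76, 0.93, 1.12, 0.78, 0.12, 0]}
  anterior_bw: {t: [0, 8, 15, 30, 50, 70, 85, 95, 100],
                v: [0, -0.12, -0.15, -0.04, 0.0, 0.10, 0.16, 0.06, 0]}
  lateral_bw:  {t: [0, 20, 50, 80, 100], v: [0, 0.045, 0.03, 0.05, 0]}
  cop_x_mm:    {t: [0, 25, 50, 75, 100], v: [-45, 30, 75, 120, 155]}
  cop_z_mm:    {t: [0, 50, 100], v: [-5, 2, 8]}
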