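# Anthropometric scaling fractions for the right lower limb.
# length_fraction / hip_offset_z_fraction: of subject height.
# mass_fraction: of subject mass. com_fraction: of segment length, measured
# from the proximal joint along the segment axis. gyration_fractions: radii of
# gyration about the segment X/Y/Z axes as fractions of segment length.
# com_offset_m: optional extra COM offset in meters (segment frame).
hip_offset_z_fraction: 0.05
segments:
  pelvis:
    length_fraction: 0.105
    mass_fraction: 0.142
    com_fraction: 0.40
    gyration_fractions: [0.31, 0.30, 0.27]
  thigh:
    length_fraction: 0.245
    mass_fraction: 0.100
    com_fraction: 0.433
    gyration_fractions: [0.323, 0.149, 0.323]
  shank:
    length_fraction: 0.246
    mass_fraction: 0.0465
    com_fraction: 0.433
    gyration_fractions: [0.302, 0.124, 0.302]
  foot:
    length_fraction: 0.152
    mass_fraction: 0.0145
    com_fraction: 0.0
    com_offset_m: [0.055, -0.039, 0.0]
    gyration_fractions: [0.149, 0.124, 0.257]
markers:
  RASI: {segment: pelvis, local: [ 90.0,  20.0,  120.0]}
  LASI: {segment: pelvis, local: [ 90.0,  20.0, -120.0]}
  SACR: {segment: pelvis, local: [-100.0, 40.0,    0.0]}
  THI1: {segment: thigh,  local: [ 60.0, -150.0,  40.0]}
  THI2: {segment: thigh,  local: [ 20.0, -250.0,  60.0]}
  THI3: {segment: thigh,  local: [ 50.0, -340.0,  10.0]}
  SHA1: {segment: shank,  local: [ 50.0, -100.0,  30.0]}
  SHA2: {segment: shank,  local: [ 10.0, -200.0,  45.0]}
  SHA3: {segment: shank,  local: [ 40.0, -300.0,  15.0]}
  HEE:  {segment: foot,   local: [-60.0,  -60.0,   0.0]}
  TOE:  {segment: foot,   local: [150.0,  -70.0,  10.0]}
  MT5:  {segment: foot,   local: [ 80.0,  -65.0,  45.0]}
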