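# Tibiofemoral ligament bundle parameter set.
# k1 (N mm^-2): quadratic toe-region stiffness; k2 (N mm^-1): linear-region
# stiffness; eps_l: reference strain constant (0.03).
# Attachments in mm, tibia frame at the full-extension reference pose:
# X anterior, Y superior, Z lateral (right knee; medial = -Z). ref_strain is
# the strain the bundle carries at the reference pose (slack-length calibration).
ligaments:
  - ligament: ACL
    bundle: anterior
    k1: 22.48
    k2: 83.15
    eps_l: 0.03
    elements:
      - {femur: [-12.0, 8.0, 9.0],  tibia: [14.0, -14.0, -3.0], ref_strain: 0.0}
      - {femur: [-10.0, 10.0, 8.0], tibia: [16.0, -14.0, 1.0],  ref_strain: 0.0}
  - ligament: ACL
    bundle: posterior
    k1: 26.27
    k2: 83.15
    elements:
      - {femur: [-14.0, 5.0, 10.0], tibia: [10.0, -14.0, -1.0], ref_strain: 0.0}
      - {femur: [-13.0, 3.0, 9.0],  tibia: [11.0, -14.0, 3.0],  ref_strain: 0.0}
  - ligament: PCL
    bundle: anterior
    k1: 31.26
    k2: 125.00
    elements:
      - {femur: [2.0, 4.0, -9.0],  tibia: [-24.0, -18.0, -1.0], ref_strain: 0.0}
      - {femur: [4.0, 6.0, -8.0],  tibia: [-23.0, -18.0, 2.0],  ref_strain: 0.0}
  - ligament: PCL
    bundle: posterior
    k1: 19.29
    k2: 60.00
    elements:
      - {femur: [0.0, 2.0, -10.0], tibia: [-26.0, -20.0, 0.0],  ref_strain: 0.0}
      - {femur: [-2.0, 1.0, -9.0], tibia: [-25.0, -21.0, 3.0],  ref_strain: 0.0}
  - ligament: MCL
    bundle: anterior
    k1: 10.00
    k2: 91.25
    elements:
      - {femur: [2.0, 12.0, -44.0], tibia: [4.0, -55.0, -38.0], ref_strain: 0.0}
  - ligament: MCL
    bundle: oblique
    k1: 5.00
    k2: 27.86
    elements:
      - {femur: [-6.0, 10.0, -44.0], tibia: [-12.0, -40.0, -36.0], ref_strain: 0.0}
  - ligament: MCL
    bundle: deep
    k1: 5.00
    k2: 21.07
    elements:
      - {femur: [0.0, 8.0, -42.0], tibia: [0.0, -18.0, -40.0], ref_strain: 0.0}
  - ligament: PMC
    bundle: main
    k1: 12.00
    k2: 52.59
    elements:
      - {femur: [-16.0, 6.0, -34.0], tibia: [-20.0, -22.0, -30.0], ref_strain: 0.0}
      - {femur: [-18.0, 5.0, -30.0], tibia: [-22.0, -22.0, -26.0], ref_strain: 0.0}
      - {femur: [-20.0, 4.0, -26.0], tibia: [-24.0, -22.0, -22.0], ref_strain: 0.0}
  - ligament: LCL
    bundle: main
    k1: 10.00
    k2: 72.22
    elements:
      - {femur: [0.0, 12.0, 44.0],  tibia: [-4.0, -48.0, 42.0], ref_strain: 0.0}
      - {femur: [-2.0, 11.0, 45.0], tibia: [-6.0, -48.0, 43.0], ref_strain: 0.0}
      - {femur: [2.0, 13.0, 43.0],  tibia: [-2.0, -48.0, 41.0], ref_strain: 0.0}
  - ligament: ALS
    bundle: main
    k1: 5.00
    k2: 19.00
    elements:
      - {femur: [4.0, 9.0, 42.0],  tibia: [14.0, -24.0, 34.0], ref_strain: 0.0}
      - {femur: [6.0, 8.0, 41.0],  tibia: [16.0, -24.0, 32.0], ref_strain: 0.0}
      - {femur: [2.0, 10.0, 43.0], tibia: [12.0, -24.0, 36.0], ref_strain: 0.0}
  - ligament: OPL
    bundle: main
    k1: 3.00
    k2: 21.42
    elements:
      - {femur: [-18.0, 6.0, 12.0],  tibia: [-24.0, -22.0, -12.0], ref_strain: 0.0}
      - {femur: [-19.0, 5.0, 8.0],   tibia: [-25.0, -22.0, -16.0], ref_strain: 0.0}
      - {femur: [-20.0, 4.0, 4.0],   tibia: [-26.0, -22.0, -20.0], ref_strain: 0.0}
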