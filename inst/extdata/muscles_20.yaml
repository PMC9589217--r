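# Twenty-muscle right-lower-limb set: literature-scale maximum isometric
# forces (N) and optimal fiber lengths (mm); editable. Path points are
# segment-local (mm): pelvis origin mid-hips, thigh origin hip center, shank
# origin knee center, foot origin ankle center; X anterior, Y superior,
# Z lateral (right leg). lts: tendon slack length (mm) or "auto" to calibrate
# from ref_lnorm, the normalized fiber length the unit assumes in the upright
# reference pose (biarticular units sit below optimal there).
# wrap: optional cylinder {segment, center, axis, radius} applied to the
# flagged consecutive path pair (wrap_pair, 1-based index of the first point).
# The three gluteus maximus units span the muscle's broad attachment: the
# upper unit runs lateral iliac crest to the iliotibial insertion and carries
# the model's hip-abduction capacity; the middle and lower units are the
# near-pure extensors.
muscles:
  - {name: gluteus_maximus_1, fmax: 1500, lopt: 100, lts: auto, ref_lnorm: 1.0,
     path: [{segment: pelvis, local: [-10, 70, 115]},
            {segment: thigh, local: [-10, -45, 35]}]}
  - {name: gluteus_maximus_2, fmax: 650, lopt: 120, lts: auto, ref_lnorm: 0.9,
     path: [{segment: pelvis, local: [-85, 30, 95]},
            {segment: thigh, local: [-15, -70, 10]}]}
  - {name: gluteus_maximus_3, fmax: 650, lopt: 144, lts: auto, ref_lnorm: 0.9,
     path: [{segment: pelvis, local: [-90, -30, 70]},
            {segment: thigh, local: [-30, -170, -7]}]}
  - {name: iliopsoas, fmax: 2400, lopt: 110, lts: auto,
     path: [{segment: pelvis, local: [40, 80, 77.5]},
            {segment: thigh, local: [35, -10, -10]},
            {segment: thigh, local: [-5, -55, -15]}]}
  - {name: pectineus, fmax: 400, lopt: 133, lts: auto,
     path: [{segment: pelvis, local: [30, -10, 30]},
            {segment: thigh, local: [-10, -150, -15]}]}
  - {name: rectus_femoris, fmax: 780, lopt: 84, lts: auto, ref_lnorm: 0.85,
     path: [{segment: pelvis, local: [45, -5, 80]},
            {segment: thigh, local: [50, -300, 10]},
            {segment: shank, local: [42, -42, 3]}],
     wrap: {segment: thigh, center: [0, -428.75, 0], axis: [0, 0, 1], radius: 25},
     wrap_pair: 2}
  - {name: vastus_medialis, fmax: 1290, lopt: 89, lts: auto,
     path: [{segment: thigh, local: [20, -200, -25]},
            {segment: shank, local: [40, -42, -8]}],
     wrap: {segment: thigh, center: [0, -428.75, 0], axis: [0, 0, 1], radius: 25},
     wrap_pair: 1}
  - {name: vastus_intermedius, fmax: 1230, lopt: 87, lts: auto,
     path: [{segment: thigh, local: [35, -180, 0]},
            {segment: shank, local: [42, -42, 0]}],
     wrap: {segment: thigh, center: [0, -428.75, 0], axis: [0, 0, 1], radius: 25},
     wrap_pair: 1}
  - {name: vastus_lateralis, fmax: 1870, lopt: 84, lts: auto,
     path: [{segment: thigh, local: [15, -190, 35]},
            {segment: shank, local: [40, -42, 10]}],
     wrap: {segment: thigh, center: [0, -428.75, 0], axis: [0, 0, 1], radius: 25},
     wrap_pair: 1}
  - {name: semimembranosus, fmax: 1030, lopt: 80, lts: auto, ref_lnorm: 0.85,
     path: [{segment: pelvis, local: [-70, -30, 75]},
            {segment: shank, local: [-25, -50, -10]}]}
  - {name: semitendinosus, fmax: 410, lopt: 195, lts: auto, ref_lnorm: 0.85,
     path: [{segment: pelvis, local: [-72, -32, 62]},
            {segment: thigh, local: [-20, -200, -35]},
            {segment: shank, local: [10, -80, -30]}]}
  - {name: biceps_femoris_long, fmax: 720, lopt: 109, lts: auto, ref_lnorm: 0.85,
     path: [{segment: pelvis, local: [-40, -28, 68]},
            {segment: shank, local: [-20, -45, 40]}]}
  - {name: biceps_femoris_short, fmax: 800, lopt: 173, lts: auto,
     path: [{segment: thigh, local: [-15, -250, 20]},
            {segment: shank, local: [-20, -45, 42]}]}
  - {name: gastrocnemius_medial, fmax: 1115, lopt: 51, lts: auto, ref_lnorm: 0.95,
     path: [{segment: thigh, local: [-25, -405, -25]},
            {segment: foot, local: [-65, -55, -5]}]}
  - {name: gastrocnemius_lateral, fmax: 490, lopt: 59, lts: auto, ref_lnorm: 0.95,
     path: [{segment: thigh, local: [-25, -405, 30]},
            {segment: foot, local: [-63, -55, 5]}]}
  - {name: soleus, fmax: 2840, lopt: 50, lts: auto,
     path: [{segment: shank, local: [-25, -100, 10]},
            {segment: foot, local: [-65, -55, 0]}]}
  - {name: tibialis_anterior, fmax: 600, lopt: 98, lts: auto,
     path: [{segment: shank, local: [30, -120, 15]},
            {segment: foot, local: [60, -55, -25]}]}
  - {name: tibialis_posterior, fmax: 1270, lopt: 31, lts: auto,
     path: [{segment: shank, local: [-20, -150, 5]},
            {segment: shank, local: [-15, -400, -30]},
            {segment: foot, local: [20, -60, -35]}]}
  - {name: extensor_hallucis_longus, fmax: 110, lopt: 111, lts: auto,
     path: [{segment: shank, local: [25, -200, 10]},
            {segment: shank, local: [35, -420, -10]},
            {segment: foot, local: [120, -60, -20]}]}
  - {name: extensor_digitorum_longus, fmax: 340, lopt: 102, lts: auto,
     path: [{segment: shank, local: [22, -180, 25]},
            {segment: shank, local: [33, -420, 5]},
            {segment: foot, local: [110, -60, 20]}]}
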