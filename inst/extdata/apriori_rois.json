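{
  "version": 1,
  "comment": "A-priori meta-analytic MNI coordinates for 5 mm sphere ROIs.",
  "rois": [
    {"name": "L_striatum", "domain": "value", "x": -12, "y": 12, "z": -6},
    {"name": "R_striatum", "domain": "value", "x": 12, "y": 10, "z": -6},
    {"name": "L_medial_frontal", "domain": "value", "x": -2, "y": 40, "z": -8},
    {"name": "R_medial_frontal", "domain": "value", "x": 2, "y": 46, "z": 8},
    {"name": "L_lateral_frontal", "domain": "mathematical", "x": -42, "y": 4, "z": 40},
    {"name": "R_lateral_frontal", "domain": "mathematical", "x": 46, "y": 10, "z": 28},
    {"name": "L_superior_parietal", "domain": "mathematical", "x": -26, "y": -60, "z": 46},
    {"name": "R_superior_parietal", "domain": "mathematical", "x": 30, "y": -62, "z": 44},
    {"name": "L_inferior_parietal", "domain": "mathematical", "x": -44, "y": -40, "z": 42},
    {"name": "R_inferior_parietal", "domain": "mathematical", "x": 38, "y": -46, "z": 42},
    {"name": "L_middle_temporal", "domain": "emotion", "x": -56, "y": -58, "z": 4},
    {"name": "R_middle_temporal", "domain": "emotion", "x": 56, "y": -44, "z": 4},
    {"name": "L_insula", "domain": "emotion", "x": -26, "y": 20, "z": -4},
    {"name": "R_insula", "domain": "emotion", "x": 42, "y": 10, "z": 12},
    {"name": "R_amygdala", "domain": "emotion", "x": 25, "y": -1, "z": -17},
    {"name": "L_anterior_cingulate", "domain": "emotion", "x": -6, "y": 36, "z": 22}
  ]
}
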