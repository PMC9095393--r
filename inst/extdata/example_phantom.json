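{
  "size": 96,
  "background": 0,
  "shapes": [
    {"kind": "ellipse", "center": [48, 48], "axes": [40, 34], "intensity": 0.4},
    {"kind": "ellipse", "center": [40, 36], "axes": [15, 11], "rotation": 20, "intensity": 0.25},
    {"kind": "rectangle", "center": [65, 48], "extent": [11, 21], "intensity": 0.2},
    {"kind": "ellipse", "center": [67, 30], "axes": [5, 5], "intensity": 0.35}
  ]
}
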