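# Default cortical region polygons for the right-hemisphere imaging window.
# Millimetre coordinates relative to bregma: x positive lateral (right),
# y positive rostral. SYNTHETIC approximation of the Paxinos-derived surface
# map (the source atlas publishes no machine-readable surface vertices);
# replace with your own layout for real data.
# Polygons are simple (non-self-intersecting) and mutually disjoint.
regions:
  M2:
    x_mm: [0.2, 1.2, 1.2, 0.2]
    y_mm: [0.9, 0.9, 2.1, 2.1]
  M1:
    x_mm: [1.3, 2.3, 2.3, 1.3]
    y_mm: [0.6, 0.6, 2.1, 2.1]
  S1FL:
    x_mm: [1.7, 2.9, 2.9, 1.7]
    y_mm: [-0.4, -0.4, 0.5, 0.5]
  S1HL:
    x_mm: [1.2, 2.2, 2.2, 1.2]
    y_mm: [-1.6, -1.6, -0.6, -0.6]
  S1BF:
    x_mm: [2.4, 3.7, 3.7, 2.4]
    y_mm: [-1.9, -1.9, -0.6, -0.6]
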