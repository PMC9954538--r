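# 55-channel driving-task layout on a 7 x 9 scalp grid.
# Row 0 is frontal, column 0 is the left hemisphere; coordinates are 0-based
# [row, col]. The grid size (7 x 9) and channel count (55: a 59-electrode
# 10-20 montage minus the ocular-artifact-prone FP1, FP2, AF3, AF4) are exact;
# individual cell placements are an editable approximation of the scalp
# layout.
name: ebdsdd-7x9
height: 7
width: 9
channels:
  F7:  [0, 0]
  F5:  [0, 1]
  F3:  [0, 2]
  F1:  [0, 3]
  Fz:  [0, 4]
  F2:  [0, 5]
  F4:  [0, 6]
  F6:  [0, 7]
  F8:  [0, 8]
  FT7: [1, 0]
  FC5: [1, 1]
  FC3: [1, 2]
  FC1: [1, 3]
  FCz: [1, 4]
  FC2: [1, 5]
  FC4: [1, 6]
  FC6: [1, 7]
  FT8: [1, 8]
  T7:  [2, 0]
  C5:  [2, 1]
  C3:  [2, 2]
  C1:  [2, 3]
  Cz:  [2, 4]
  C2:  [2, 5]
  C4:  [2, 6]
  C6:  [2, 7]
  T8:  [2, 8]
  TP7: [3, 0]
  CP5: [3, 1]
  CP3: [3, 2]
  CP1: [3, 3]
  CPz: [3, 4]
  CP2: [3, 5]
  CP4: [3, 6]
  CP6: [3, 7]
  TP8: [3, 8]
  P7:  [4, 0]
  P5:  [4, 1]
  P3:  [4, 2]
  P1:  [4, 3]
  Pz:  [4, 4]
  P2:  [4, 5]
  P4:  [4, 6]
  P6:  [4, 7]
  P8:  [4, 8]
  PO9: [5, 0]
  PO7: [5, 1]
  PO3: [5, 3]
  POz: [5, 4]
  PO4: [5, 5]
  PO8: [5, 7]
  PO10: [5, 8]
  O1:  [6, 3]
  Oz:  [6, 4]
  O2:  [6, 5]
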