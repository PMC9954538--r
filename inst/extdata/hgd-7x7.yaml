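# 44-channel motor-cortex layout on a 7 x 7 scalp grid: all central
# electrodes except Cz (the recording reference). Row 0 is frontal, column 0
# the left hemisphere; coordinates are 0-based [row, col]. Grid size and
# channel count are exact; cell placements are an editable approximation
# (intermediate 10-5 "h" rows sit between the full 10-20 rows and straddle
# the midline, so they skip the centre column).
name: hgd-7x7
height: 7
width: 7
channels:
  FFC5h: [0, 0]
  FFC3h: [0, 1]
  FFC1h: [0, 2]
  FFC2h: [0, 4]
  FFC4h: [0, 5]
  FFC6h: [0, 6]
  FC5:   [1, 0]
  FC3:   [1, 1]
  FC1:   [1, 2]
  FCz:   [1, 3]
  FC2:   [1, 4]
  FC4:   [1, 5]
  FC6:   [1, 6]
  FCC5h: [2, 0]
  FCC3h: [2, 1]
  FCC1h: [2, 2]
  FCC2h: [2, 4]
  FCC4h: [2, 5]
  FCC6h: [2, 6]
  C5:    [3, 0]
  C3:    [3, 1]
  C1:    [3, 2]
  C2:    [3, 4]
  C4:    [3, 5]
  C6:    [3, 6]
  CCP5h: [4, 0]
  CCP3h: [4, 1]
  CCP1h: [4, 2]
  CCP2h: [4, 4]
  CCP4h: [4, 5]
  CCP6h: [4, 6]
  CP5:   [5, 0]
  CP3:   [5, 1]
  CP1:   [5, 2]
  CPz:   [5, 3]
  CP2:   [5, 4]
  CP4:   [5, 5]
  CP6:   [5, 6]
  CPP5h: [6, 0]
  CPP3h: [6, 1]
  CPP1h: [6, 2]
  CPP2h: [6, 4]
  CPP4h: [6, 5]
  CPP6h: [6, 6]
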