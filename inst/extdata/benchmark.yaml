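# Benchmarked acquisition state: 300 kV FEG-TEM, rectangular direct detector
# at 4.603 A/px, 3.15 um parallel beam, 3x3 beam-image-shift montage,
# grouped dose-symmetric +/-60 deg in 3 deg steps.
camera:
  width_px: 5760
  height_px: 4092
  pixel_size_A: 4.603
beam:
  diameter_um: 3.15
  fringe_fraction_x: 0.04
pattern:
  m: 3
  "n": 3   # quoted: a bare n is YAML-1.1 boolean
  overlap_x_px: 1152   # 20% of x; printed piece coordinates 0 -> 4608
  overlap_y_px: 576    # 14.1% of y; printed piece coordinates 0 -> 3516
tilt:
  max_deg: 60
  increment_deg: 3
  group_size: 3
  style: dose-symmetric
spiral:
  A_final: 1.5
  period: 3
  turns: 50
  revolutions: 15
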