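# Uniform calibration cylinder: 20 cm diameter, 5.64 L fillable volume,
# 105 kBq/ml at the reference time.
reference_time: 0
background:
  name: cylinder
  shape: cylinder
  center: [0, 0, 0]
  dimensions:
    diameter: 200.0
    height: 179.52
  nominal_volume: 5640.0
  activity_concentration: 105.0
  material: water
compartments: []
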