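# Anthropomorphic head-and-neck phantom: water-filled head with a dense
# bone-resin skull shell, water-filled brain cavity, fillable glands at
# background concentration, and a ~22.8-ml tumor insert. Ground-truth
# concentrations: 26.2 kBq/ml background, 259 kBq/ml tumor. Solid resin
# compartments are impermeable and carry no activity. Measured volumes of
# the fillable chambers are the `nominal_volume` entries.
reference_time: 0
background:
  name: head
  shape: ellipsoid
  center: [0, 0, 0]
  dimensions:
    axes: [150.0, 190.0, 220.0]
  activity_concentration: 26.2
  material: water
compartments:
  - name: skull
    shape: ellipsoid
    center: [0, 0, 40.0]
    dimensions:
      axes: [130.0, 160.0, 150.0]
    activity_concentration: 0.0
    material: bone-resin
  - name: brain
    shape: ellipsoid
    center: [0, 0, 40.0]
    dimensions:
      axes: [114.0, 144.0, 134.0]
    activity_concentration: 26.2
    material: water
  - name: parotid_l
    shape: sphere
    center: [55.0, 10.0, -20.0]
    nominal_volume: 8.75
    activity_concentration: 26.2
    material: water
  - name: parotid_r
    shape: sphere
    center: [-55.0, 10.0, -20.0]
    nominal_volume: 8.39
    activity_concentration: 26.2
    material: water
  - name: lacrimal_l
    shape: sphere
    center: [28.0, 70.0, 45.0]
    nominal_volume: 1.42
    activity_concentration: 26.2
    material: water
  - name: lacrimal_r
    shape: sphere
    center: [-28.0, 70.0, 45.0]
    nominal_volume: 1.49
    activity_concentration: 26.2
    material: water
  - name: thyroid
    shape: ellipsoid
    center: [0, 45.0, -80.0]
    dimensions:
      axes: [40.0, 30.0, 22.5]
    nominal_volume: 14.12
    activity_concentration: 26.2
    material: water
  - name: tumor
    shape: sphere
    center: [0, 55.0, -45.0]
    nominal_volume: 22.8
    activity_concentration: 259.0
    material: water
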