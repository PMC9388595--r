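# Hot-sphere Jaszczak phantom: six fillable spheres (0.5-16 ml) on a ring,
# 9.9:1 insert-to-background concentration, background 25.9 kBq/ml at scan
# time. Sphere diameters are the nominal insert diameters in mm.
reference_time: 0
insert_to_background_ratio: 9.9
background:
  name: background
  shape: cylinder
  center: [0, 0, 0]
  dimensions:
    diameter: 216.0
    height: 186.0
  nominal_volume: 6814.0
  activity_concentration: 25.9
  material: water
compartments:
  - name: sphere_0.5ml
    shape: sphere
    center: [55.0, 0.0, 0.0]
    dimensions: {diameter: 9.9}
    nominal_volume: 0.5
    activity_concentration: 256.41
    material: water
  - name: sphere_1ml
    shape: sphere
    center: [27.5, 47.63, 0.0]
    dimensions: {diameter: 12.4}
    nominal_volume: 1.0
    activity_concentration: 256.41
    material: water
  - name: sphere_2ml
    shape: sphere
    center: [-27.5, 47.63, 0.0]
    dimensions: {diameter: 15.4}
    nominal_volume: 2.0
    activity_concentration: 256.41
    material: water
  - name: sphere_4ml
    shape: sphere
    center: [-55.0, 0.0, 0.0]
    dimensions: {diameter: 19.8}
    nominal_volume: 4.0
    activity_concentration: 256.41
    material: water
  - name: sphere_8ml
    shape: sphere
    center: [-27.5, -47.63, 0.0]
    dimensions: {diameter: 24.8}
    nominal_volume: 8.0
    activity_concentration: 256.41
    material: water
  - name: sphere_16ml
    shape: sphere
    center: [27.5, -47.63, 0.0]
    dimensions: {diameter: 31.3}
    nominal_volume: 16.0
    activity_concentration: 256.41
    material: water
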