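schema: 1
label: artery_1mm_100us
geometry:
  domain_width: 80.0
  domain_height: 40.0
  saline_thickness: 0.5
  fat_thickness: 5.0
  myocardium_thickness: 2.7
  device_diameter: 3.98
  electrode_length: 2.56
  electrode_height: 0.2
  hole_width: 0.76
  artery_present: yes
  artery_diameter: 2.3
  stent_present: no
  stent_wall: 100.0
  electrode_artery_gap: 1.0
protocol:
  pulses: 10
  amplitude_V: 1000.0
  width_us: 100.0
  interval_us: 100.0
  latency_ms: 10.0
lumen_robin: yes
saline_flowing: yes
provenance:
  air_convection: h = 20 W/m2K, T = 21 C (ambient air)
  endocardial_convection: h = 1417 W/m2K, T = 37 C (chamber blood, 24.4 cm/s)
  lumen_convection: h = 63.19 W/m2K, T = 37 C (lumen blood, 0.5 m/s)
  blood_viscosity_kg_per_ms: 0.0021
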