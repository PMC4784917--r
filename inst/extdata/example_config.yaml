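# Typical MSB biosensing configuration: iron-oxide tracer with a 20 nm core
# and 50 nm hydrodynamic radius in water at room temperature, driven at 5 mT
# and 1 kHz.
particles:
  mean_core_radius_nm: 20
  mean_hydro_radius_nm: 50
  size_cv: 0.10
  Ms_kA_per_m: 250
environment:
  viscosity_mPa_s: 1.0
  temperature_K: 293
  density_kg_m3: 1000
field:
  amplitude_mT: 5
  frequency_Hz: 1000
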