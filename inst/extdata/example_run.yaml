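# Example run configuration. Units are carried in the key names.
seed: 1
wind_limit_m_s: 13
species:
  - isoprene
months: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]

# synthetic-climatology settings (ignored when `inputs:` points at NetCDF files)
uv_peak_mw_cm2: 3.0
wind_belt_amplitude_m_s: 9
trophic_fractions: [0.6, 0.3, 0.1]

# box-model scenario (soa-box command)
e_flux_molec_cm2_s: 4.1e+9
mbl_height_m: 600
poa_ug_m3: 0.4
temperature_c: 20
duration_h: 12
dt_s: 60

# regional comparison (flux command)
regions:
  - name: example-tropical-site
    lat: [-10, 10]
    lon: [60, 90]
    months: [1, 2, 3]
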