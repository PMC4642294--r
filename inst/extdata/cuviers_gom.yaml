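# Cuvier's beaked whale, Gulf of Mexico defaults
label: "Cuvier's beaked whale (GOM)"
source_level_mean: 225
source_level_sd: 3
peak_frequency_khz: 40.2
directivity_index_range: [24, 28]
detection_threshold: 121
absorption_db_km: 10.05
receiver_altitude_m: 10
animal_altitude_range_m: [175, 225]
monitoring_radius_km: 4
pitch_sd_range_deg: [5, 15]
beam_floor_db: 40
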