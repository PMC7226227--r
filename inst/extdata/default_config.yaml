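calibration:
  microns_per_pixel: 0.357
  tile_width_um: 300.0
  tile_height_um: 400.0
morphometry:
  max_vessel_or_mac_aggregate_um2: 800.0
  min_tumor_fragment_um2: 10.0
  min_stroma_um2: 400.0
  min_macrophage_um2: 5.0
  min_vessel_um2: 5.0
  vessel_mac_contact_min: 0.02
  large_mac_threshold_um2: 40.0
  large_mac_tumor_contact_min: 0.08
  large_mac_vessel_contact_min: 0.2
  small_mac_tumor_contact_min: 0.1
  small_mac_vessel_contact_min: 0.1
  ta_vessel_tumor_contact_min: 0.2
  ta_vessel_mac_contact_min: 0.2
  tmem_dilation_um: 50.0
  smoothing_radius_um: 0.75
scoring:
  top_k: 10
  min_tile_roi_overlap: 0.5
risk:
  low_cutoff: 6.0
  high_cutoff: 23.0
stains:
  vessel:
  - 70
  - 90
  - 200
  macrophage:
  - 120
  - 80
  - 30
  tumor:
  - 200
  - 60
  - 90
  counterstain:
  - 200
  - 230
  - 200
median_radius: 1
classifier: ''
verbosity: 0
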