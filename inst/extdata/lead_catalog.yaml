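# DBS lead catalog: vendor-nominal geometry (mm). These dimensions are the
# community-standard nominal values for each lead family; they can be
# overridden by supplying a custom catalog file to build_lead().
# Levels are counted from the distal tip (level 1 = bottom contact).
# Segmented levels carry 3 sectors of `segment_span_deg` degrees whose
# centres are 120 degrees apart (1-3-3-1 layout for the directional leads).
MDT3387:
  vendor: Medtronic
  type: standard
  shaft_radius_mm: 0.635
  contact_height_mm: 1.5
  contact_gap_mm: 1.5
  tip_length_mm: 1.5
  n_levels: 4
  segmented_levels: []
MDT3389:
  vendor: Medtronic
  type: standard
  shaft_radius_mm: 0.635
  contact_height_mm: 1.5
  contact_gap_mm: 0.5
  tip_length_mm: 1.5
  n_levels: 4
  segmented_levels: []
BSC2201:
  vendor: Boston Scientific
  type: standard
  shaft_radius_mm: 0.65
  contact_height_mm: 1.5
  contact_gap_mm: 0.5
  tip_length_mm: 1.1
  n_levels: 8
  segmented_levels: []
ABT6172:
  vendor: Abbott
  type: steerable
  shaft_radius_mm: 0.645
  contact_height_mm: 1.5
  contact_gap_mm: 0.5
  tip_length_mm: 1.0
  n_levels: 4
  segmented_levels: [2, 3]
  n_segments: 3
  segment_span_deg: 90
BSC2202:
  vendor: Boston Scientific
  type: steerable
  shaft_radius_mm: 0.65
  contact_height_mm: 1.5
  contact_gap_mm: 0.5
  tip_length_mm: 1.1
  n_levels: 4
  segmented_levels: [2, 3]
  n_segments: 3
  segment_span_deg: 90
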