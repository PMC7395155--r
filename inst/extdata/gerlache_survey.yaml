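# Gerlache Strait study inputs as printed in the source report:
# WorldView-3 image footprint and strata, FOI class counts from the
# principal observer, and the ship line-transect summary statistics.
image_area_total: 971
area_calmer: 635
area_rougher: 336
surface_threshold: 1
counts:
  definite: 18
  probable: 21
  unclassified: 146
ship:
  n_groups: 90
  n_individuals: 185
  n_humpback_individuals: 177
  esw: 3.1
  esw_cv: 0.07
  group_size_cv: 0.01
  effort_km: 90.7
  cv: 0.09
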