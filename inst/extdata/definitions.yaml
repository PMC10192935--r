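# Inclusion criteria of the five databases, one preset per source.
# count_basis FATALITIES counts killed only; CASUALTIES counts killed +
# injured; a null basis means no victim-count threshold (ASR). All presets
# exclude the perpetrator from victim counts.
SHR:
  count_basis: FATALITIES
  min_count: 4
  perp_excluded: true
  min_shooters: 1
  max_shooters: 1
ASR:
  count_basis: ~
  min_count: 0
  perp_excluded: true
  excluded_motives: [GANG, DRUG, FAMILY_IPV]
MJ:
  count_basis: FATALITIES
  min_count: 3
  perp_excluded: true
  min_shooters: 1
  max_shooters: 1
  shooter_must_be_known: true
  excluded_motives: [ROBBERY, GANG, FAMILY_IPV]
  allow_list: []
EVERYTOWN:
  count_basis: FATALITIES
  min_count: 4
  perp_excluded: true
GVA:
  count_basis: CASUALTIES
  min_count: 4
  perp_excluded: true
  min_shooters: 1
  max_shooters: 2
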