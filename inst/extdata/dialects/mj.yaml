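# Mother Jones mass-shootings database export dialect.
# Place is a single "City, State" column, split on read.
source: MJ
delim: ","
encoding: UTF-8
date_format: "%B %d, %Y"
state_style: full
victim_count_basis: EXCLUDES_PERP
victim_level: false
combined_location: true
list_sep: ";"
column_map:
  source_id: case_id
  date: date
  city: location
  shooter_names: shooter
  n_shooters: num_shooters
  killed: fatalities
  injured: injured
  perp_died: shooter_died
  motive: motive
  location_type: venue
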