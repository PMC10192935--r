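# Everytown for Gun Safety mass-shootings database export dialect.
source: EVERYTOWN
delim: ","
encoding: UTF-8
date_format: "%Y-%m-%d"
state_style: full
victim_count_basis: EXCLUDES_PERP
victim_level: false
combined_location: false
list_sep: ";"
column_map:
  source_id: incident_id
  date: incident_date
  state: state
  city: city
  shooter_names: shooter_names
  n_shooters: num_shooters
  killed: killed
  injured: wounded
  perp_died: shooter_outcome
  motive: circumstances
  location_type: setting
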