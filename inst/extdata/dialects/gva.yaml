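# Gun Violence Archive export dialect. No motive column: GVA includes
# incidents regardless of motive, so motive is UNKNOWN on read.
source: GVA
delim: ","
encoding: UTF-8
date_format: "%m/%d/%y"
state_style: full
victim_count_basis: EXCLUDES_PERP
victim_level: false
combined_location: false
list_sep: ";"
column_map:
  source_id: incident_id
  date: incident_date
  state: state
  city: city_or_county
  shooter_names: shooter_name
  n_shooters: n_shooters
  killed: n_killed
  injured: n_injured
  perp_died: shooter_died
  location_type: location_type
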