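# FBI Active Shooter Report tabular export dialect.
# The killed column counts the perpetrator when the perpetrator died;
# victim_count_basis triggers the exclusion adjustment on read.
source: ASR
delim: ","
encoding: UTF-8
date_format: "%m/%d/%Y"
state_style: usps
victim_count_basis: INCLUDES_PERP
victim_level: false
combined_location: false
list_sep: ";"
column_map:
  source_id: id
  date: incident_date
  state: state
  city: city
  shooter_names: shooter
  n_shooters: num_shooters
  killed: killed
  injured: wounded
  perp_died: shooter_deceased
  motive: circumstance
  location_type: location
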