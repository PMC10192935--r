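# FBI Supplementary Homicide Report export dialect.
# Victim-level: one row per homicide victim; rows are grouped into incidents
# by (agency, incident_num, date) before fatality counting (see subset_shr).
source: SHR
delim: ","
encoding: UTF-8
date_format: "%Y%m%d"
state_style: full
victim_count_basis: EXCLUDES_PERP
victim_level: true
combined_location: false
list_sep: ";"
column_map:
  agency: agency
  incident_num: incident_num
  date: date
  state: state
  city: city
  shooter_names: offender_name
  n_shooters: offender_count
  perp_died: offender_died
  motive: circumstance
  weapon: weapon
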