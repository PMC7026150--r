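{
  "schema": "facemasc/study_report",
  "schema_version": 1,
  "required_sections": ["metadata", "validation", "sibling_comparison"],
  "required_metadata": ["package", "version", "seed", "alpha", "config_hash"],
  "required_row_fields_fixtures": ["table", "variable", "t", "df", "p", "d"],
  "required_row_fields": ["variable", "statistic_name", "statistic", "p", "d"],
  "notes": "data-mode comparison rows additionally carry test choice (parametric/nonparametric via shapiro_p_*) and a direction annotation; density samples must integrate to 1 +/- 0.01 over their grid"
}
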