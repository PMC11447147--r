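{
  "format": "cohort-table",
  "encoding": "UTF-8",
  "missing_token": "NA",
  "delimiters": ["tab", "comma"],
  "columns": [
    {"name": "subject_id", "type": "string", "required": true, "unique": true},
    {"name": "status", "type": "string", "required": true, "levels": ["case", "control"]},
    {"name": "sex", "type": "string", "required": true, "levels": ["male", "female"]},
    {"name": "age_at_assessment", "type": "number", "required": false, "unit": "years"},
    {"name": "age_of_onset", "type": "number", "required": false, "unit": "years", "note": "cases only; onset <= 65 is early-onset, >= 66 late-onset"},
    {"name": "education", "type": "number", "required": false, "unit": "years"},
    {"name": "year_of_birth", "type": "integer", "required": false},
    {"name": "paternal_history", "type": "string", "required": false, "levels": ["yes", "no"], "note": "NA = unknown, distinct from no"},
    {"name": "maternal_history", "type": "string", "required": false, "levels": ["yes", "no"]},
    {"name": "father_birthplace", "type": "string", "required": false},
    {"name": "mother_birthplace", "type": "string", "required": false},
    {"name": "n_siblings", "type": "integer", "required": false},
    {"name": "siblings_with_dementia", "type": "integer", "required": false, "note": "must not exceed n_siblings"},
    {"name": "apoe", "type": "string", "required": false, "note": "unordered pair of e2/e3/e4, e.g. e3e4"},
    {"name": "csf_abeta42", "type": "number", "required": false, "unit": "pg/mL", "positive": true},
    {"name": "csf_ttau", "type": "number", "required": false, "unit": "pg/mL", "positive": true},
    {"name": "csf_ptau", "type": "number", "required": false, "unit": "pg/mL", "positive": true},
    {"name": "age_at_lp", "type": "number", "required": false, "unit": "years"}
  ]
}
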