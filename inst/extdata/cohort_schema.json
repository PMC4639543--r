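{
  "schema_version": "1.0",
  "format": "csv",
  "encoding": "UTF-8",
  "missing_value": "",
  "description": "Column dictionary for participant-level headache survey cohorts. One row per participant. Headache-block columns (features/lost_time/economics) must be empty when headache_last_year is FALSE and present when TRUE (monthly_income is the only field a headache sufferer may leave missing).",
  "columns": [
    {"name": "participant_id", "type": "string", "required": true, "description": "Opaque participant identifier, unique within a cohort"},
    {"name": "age", "type": "integer", "unit": "years", "required": true, "min": 18, "max": 65, "description": "Age at interview; survey eligibility is 18-65 years"},
    {"name": "sex", "type": "enum", "required": true, "values": ["male", "female"]},
    {"name": "habitation", "type": "enum", "required": true, "values": ["urban", "rural"]},
    {"name": "monthly_income", "type": "number", "unit": "INR/month", "required": false, "min": 0, "description": "Reported monthly household income; may be missing"},
    {"name": "headache_last_year", "type": "boolean", "required": true, "description": "Screening response: any headache in the preceding year"},
    {"name": "headache_days_per_month", "type": "number", "unit": "days/month", "block": "features", "min": 0, "max": 30},
    {"name": "attacks_per_month", "type": "number", "unit": "attacks/month", "block": "features", "min": 0},
    {"name": "mean_attack_duration_h", "type": "number", "unit": "hours", "block": "features", "min_exclusive": 0},
    {"name": "usual_intensity", "type": "integer", "block": "features", "values": [1, 2, 3], "labels": {"1": ["not bad", "mild"], "2": ["quite bad", "moderate"], "3": ["very bad", "severe"]}, "description": "3-point categorical intensity converted to a 1-3 numerical rating"},
    {"name": "pain_unilateral", "type": "boolean", "block": "features"},
    {"name": "pain_pulsating", "type": "boolean", "block": "features"},
    {"name": "pain_moderate_or_severe", "type": "boolean", "block": "features"},
    {"name": "pain_aggravated_by_activity", "type": "boolean", "block": "features"},
    {"name": "nausea_or_vomiting", "type": "boolean", "block": "features"},
    {"name": "photophobia", "type": "boolean", "block": "features"},
    {"name": "phonophobia", "type": "boolean", "block": "features"},
    {"name": "lifetime_attack_count_ge5", "type": "boolean", "block": "features"},
    {"name": "duration_4_to_72h", "type": "boolean", "block": "features"},
    {"name": "duration_30min_to_7d", "type": "boolean", "block": "features"},
    {"name": "acute_medication_days_per_month", "type": "number", "unit": "days/month", "block": "features", "min": 0, "max": 30},
    {"name": "acute_medication_class", "type": "enum", "block": "features", "values": ["simple_analgesic", "combination_or_specific", "none"]},
    {"name": "paid_days_lost_3m", "type": "number", "unit": "days/3 months", "block": "lost_time", "min": 0, "max": 92, "description": "HALT Q1+Q2: days lost from paid work in the preceding 3 months"},
    {"name": "household_days_lost_3m", "type": "number", "unit": "days/3 months", "block": "lost_time", "min": 0, "max": 92, "description": "HALT Q3+Q4: days lost from household work in the preceding 3 months"},
    {"name": "consulted_last_year", "type": "boolean", "block": "economics"},
    {"name": "consultation_level", "type": "enum", "block": "economics", "values": ["primary_care", "specialist", "other", "none"], "description": "Must be 'none' exactly when consulted_last_year is FALSE"},
    {"name": "expenditure_3m", "type": "number", "unit": "INR/3 months", "block": "economics", "min": 0, "description": "Actual spend on consultations and medication in the preceding 3 months"},
    {"name": "wtp", "type": "number", "unit": "INR", "block": "economics", "min": 0, "description": "Stated willingness to pay for effective treatment"}
  ]
}
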