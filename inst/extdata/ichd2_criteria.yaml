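# ICHD-II criteria registry used by the hierarchical diagnostic algorithm.
# Encoded as data (not code) so the rule encoding is auditable and swappable.
#
# Predicate grammar (evaluated per participant over HeadacheFeatures columns):
#   kind: flag   -- field equals value
#   kind: count  -- at least `min` / at most `max` of `fields` are TRUE
#                   (negate: true counts FALSE instead)
#   kind: any    -- at least one sub-predicate in `items` holds
#   kind: all    -- every sub-predicate in `items` holds
version: "ichd2-1.0"

# Chronic split: headache on >= 15 days/month is classified before any
# episodic rule set is consulted.
chronic_days_per_month: 15

# Acute-medication overuse day thresholds (days/month) by drug class
# (ICHD-II 8.2). The optional minimum overuse duration in months (ICHD-II
# requires > 3 months) is off by default: the survey did not record it.
overuse:
  thresholds:
    simple_analgesic: 15
    combination_or_specific: 10
  min_duration_months: null

# Episodic rule sets, evaluated strictly in this order; the first fully
# satisfied set wins, then probable variants (all but one criterion met).
order: [migraine, tth, probable_migraine, probable_tth]
probable_max_failed: 1

rule_sets:
  migraine:
    label: "Migraine (ICHD-II 1.1)"
    criteria:
      - id: attacks_ge5
        description: "At least 5 lifetime attacks"
        kind: flag
        field: lifetime_attack_count_ge5
        value: true
      - id: duration_4_72h
        description: "Attacks last 4-72 h"
        kind: flag
        field: duration_4_to_72h
        value: true
      - id: pain_features_ge2
        description: ">=2 of: unilateral, pulsating, moderate/severe, aggravated by routine activity"
        kind: count
        fields: [pain_unilateral, pain_pulsating, pain_moderate_or_severe, pain_aggravated_by_activity]
        min: 2
      - id: associated_symptoms
        description: "Nausea/vomiting, or both photophobia and phonophobia"
        kind: any
        items:
          - kind: flag
            field: nausea_or_vomiting
            value: true
          - kind: count
            fields: [photophobia, phonophobia]
            min: 2
  tth:
    label: "Tension-type headache (ICHD-II 2.x)"
    criteria:
      - id: episodes_ge10
        # The questionnaire records lifetime attack count only as a >=5
        # indicator; it stands proxy for the >=10 episode requirement.
        description: "At least 10 lifetime episodes (>=5 indicator as proxy)"
        kind: flag
        field: lifetime_attack_count_ge5
        value: true
      - id: duration_30min_7d
        description: "Episodes last 30 min - 7 d"
        kind: flag
        field: duration_30min_to_7d
        value: true
      - id: inverse_pain_features_ge2
        description: ">=2 of: bilateral, non-pulsating, not moderate/severe, not aggravated by activity"
        kind: count
        fields: [pain_unilateral, pain_pulsating, pain_moderate_or_severe, pain_aggravated_by_activity]
        negate: true
        min: 2
      - id: no_migrainous_symptoms
        description: "No nausea/vomiting and at most one of photophobia/phonophobia"
        kind: all
        items:
          - kind: flag
            field: nausea_or_vomiting
            value: false
          - kind: count
            fields: [photophobia, phonophobia]
            max: 1
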