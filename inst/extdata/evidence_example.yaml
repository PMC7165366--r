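# Synthetic worked example of a per-company evidence file: structured
# attributes coded by a human annotator from published commitments (the
# engine never parses free text). demo_foods is a fictitious manufacturer;
# the attribute patterns are the published worked scoring examples.
demo_foods:
  cs_overarching_commitment:
    commitment_level: national
    publicly_available: true
  pf_reformulation_commitment:
    commitment_level: national
    publicly_available: true
    specificity: vague
  pf_transfat_target:
    transfat_target: general
  nl_fop_labelling:
    fop_format: interpretive_some
  pp_marketing_age_policy:
    age_cutoff_years: 6
  pa_fiscal_policy_position:
    fiscal_position: strongly_opposed
  er_political_donations:
    donations_disclosure: national_public
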