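# Example domain-weight allocation per sector (out of 100). The study's
# exact allocations are not public; this documented example keeps the
# relative emphasis the tool places on formulation and promotion for
# manufacturers, promotion and accessibility for QSR and retailers. Real
# assessments supply their own file; weights not summing to exactly 100 are
# rejected at load time.
version: "1.0"
weights:
  manufacturer:
    corporate_strategy: 10
    product_formulation: 25
    nutrition_labelling: 20
    promotion_practices: 25
    product_accessibility: 10
    external_relationships: 10
  qsr:
    corporate_strategy: 10
    product_formulation: 20
    nutrition_labelling: 20
    promotion_practices: 25
    product_accessibility: 15
    external_relationships: 10
  retailer:
    corporate_strategy: 10
    product_formulation: 15
    nutrition_labelling: 20
    promotion_practices: 25
    product_accessibility: 20
    external_relationships: 10
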