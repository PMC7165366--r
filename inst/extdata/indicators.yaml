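# Example indicator rubric set: one worked indicator per domain (the
# published scoring-band examples) plus one extra formulation indicator
# demonstrating sector/portfolio applicability. The full study instrument
# carries many more indicators per domain; real assessments supply their own
# file in this schema. Every attribute referenced by a band predicate is
# declared under `attributes`; applicability predicates may reference roster
# fields (sector, scope, participating, listed) and the declared `flags`.
version: "1.0"

attributes:
  commitment_level:
    type: enum
    values: [national, global, weak, none]
  publicly_available:
    type: boolean
  specificity:
    type: enum
    values: [specific, vague, none]
  fop_format:
    type: enum
    values: [interpretive_all, interpretive_some, numeric_all, numeric_some,
             energy_only, none]
  age_cutoff_years:
    type: integer
    min: 0
    max: 21
  fiscal_position:
    type: enum
    values: [strong_support, weak_support, none, strongly_opposed]
  donations_disclosure:
    type: enum
    values: [national_public, global_disclosed, none]
  transfat_target:
    type: enum
    values: [specific_public, general, none]

flags:
  sells_food:
    type: boolean
  sells_beverages_only:
    type: boolean

indicators:
  - id: cs_overarching_commitment
    domain: corporate_strategy
    question: >
      Does the company have an overarching commitment to population
      nutrition and health articulated in strategic documents?
    status: example
    bands:
      - score: 10
        label: National-level commitment, publicly available
        when: {commitment_level: national, publicly_available: true}
      - score: 7.5
        label: Global-level commitment, publicly available
        when: {commitment_level: global, publicly_available: true}
      - score: 5
        label: Commitment not publicly available, or weak commitment
        any_of:
          - {commitment_level: [national, global], publicly_available: false}
          - {commitment_level: weak}
      - score: 0
        label: No clear commitment
        default: true

  - id: pf_reformulation_commitment
    domain: product_formulation
    question: >
      Does the company publish a comprehensive set of commitments or
      objectives on new product development and reformulation with respect
      to nutrients of concern and energy?
    status: example
    bands:
      - score: 10
        label: Specific national-level commitments, publicly available
        when: {commitment_level: national, publicly_available: true,
               specificity: specific}
      - score: 7.5
        label: Specific global commitments applicable in-country, publicly available
        when: {commitment_level: global, publicly_available: true,
               specificity: specific}
      - score: 5
        label: Specific national-level commitments, not publicly available
        when: {commitment_level: national, publicly_available: false,
               specificity: specific}
      - score: 2.5
        label: Public commitments that are vague and non-specific
        when: {commitment_level: [national, global], publicly_available: true,
               specificity: vague}
      - score: 0
        label: No commitments
        default: true

  - id: pf_transfat_target
    domain: product_formulation
    question: >
      Does the company set a target to eliminate industrially produced
      trans fats from its food products?
    status: example
    applicability:
      when: {sells_food: true}
    bands:
      - score: 10
        label: Specific public trans-fat elimination target
        when: {transfat_target: specific_public}
      - score: 5
        label: General statement without a target
        when: {transfat_target: general}
      - score: 0
        label: No target
        default: true

  - id: nl_fop_labelling
    domain: nutrition_labelling
    question: >
      Does the company commit to use a comprehensive front-of-pack
      labelling system (beyond a single energy icon)?
    status: example
    bands:
      - score: 10
        label: Interpretive symbols or logos across all product categories
        when: {fop_format: interpretive_all}
      - score: 7.5
        label: Interpretive symbols or logos (e.g. nationally endorsed
          healthier-choice logo) across some product categories
        when: {fop_format: interpretive_some}
      - score: 5
        label: Numeric key-nutrient information across all product categories
        when: {fop_format: numeric_all}
      - score: 2.5
        label: Numeric key-nutrient information across some product categories
        when: {fop_format: numeric_some}
      - score: 0
        label: No FOP labelling, or energy-only FOP labelling
        default: true

  - id: pp_marketing_age_policy
    domain: promotion_practices
    question: >
      To what age group(s) does the broadcast marketing policy apply?
    status: example
    bands:
      - score: 10
        label: 18 years and/or under
        when: {age_cutoff_years: {min: 18}}
      - score: 8
        label: 16 years and/or under
        when: {age_cutoff_years: {min: 16, max: 17}}
      - score: 6
        label: 14 years and/or under
        when: {age_cutoff_years: {min: 14, max: 15}}
      - score: 4
        label: 12 years and/or under
        when: {age_cutoff_years: {min: 12, max: 13}}
      - score: 2
        label: Under 10 years
        when: {age_cutoff_years: {min: 1, max: 11}}
      - score: 0
        label: No policy or no information
        default: true

  - id: pa_fiscal_policy_position
    domain: product_accessibility
    question: >
      Does the company's policy position support fiscal policies that make
      healthier foods relatively cheaper and non-core foods relatively more
      expensive?
    status: example
    bands:
      - score: 10
        label: Strong support (taxes on non-core foods broadly defined,
          subsidies for healthy foods)
        when: {fiscal_position: strong_support}
      - score: 5
        label: Weak support (narrowly defined taxes or subsidies)
        when: {fiscal_position: weak_support}
      - score: -10
        label: Strongly opposed (deficit points)
        when: {fiscal_position: strongly_opposed}
      - score: 0
        label: No details available
        default: true

  - id: er_political_donations
    domain: external_relationships
    question: >
      Does the company publish details of its political donations (where not
      prohibited by government policy)?
    status: example
    bands:
      - score: 10
        label: National-level information publicly available, or declared
          no activity
        when: {donations_disclosure: national_public}
      - score: 5
        label: Global policy disclosed as applying in-country
        when: {donations_disclosure: global_disclosed}
      - score: 0
        label: No disclosure
        default: true
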