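# Funding-statement templates used by the synthetic corpus generator.
# Placeholders: {entity} funder entity, {initials} author initials,
# {other} an unrelated (non-cola) funder. Screening cue rules are calibrated
# against these phrasings; both live in the repository so the screen is
# testable against known statements.
direct:
  - "This study was funded by {entity}."
  - "This work was supported by {entity}."
  - "Research relating to this article was supported by a grant from {entity}."
  - "Funding for data collection and analysis was provided by {entity}."
  - "The trial was financially supported by {entity}."
ci_only:
  - "{initials} has received speaking fees from {entity}."
  - "{initials} has consulted for {entity} on matters unrelated to this study."
  - "{initials} serves on an advisory board of {entity}."
  - "{initials} reports honoraria and travel reimbursement from {entity}."
indirect:
  - "This work was supported by a student grant from {entity}."
  - "The first author received a student travel award from {entity}."
  - "The analysis benefited from a donation to the authors' institution by {entity}."
indexing_error:
  - "This study was funded by {other}; the authors thank the {entity} community programme for access to facilities."
  - "This work was supported by {other}. {entity} had no role in study design or analysis."
other_funders:
  - "the National Diet Research Agency"
  - "the Public Science Fund"
  - "the Metabolic Research Council"
  - "the Beverage Epidemiology Consortium"
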