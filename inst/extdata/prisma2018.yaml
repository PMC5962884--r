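# Packaged flow specification: the synthetic corpus generated from this file
# realizes, stage by stage, the published screening and matching accounting
# that the pipeline is validated against.
n_total: 779
seed: 20180604
exclusion_plan:
  ci_only: 200
  indirect: 60
  other_cola: 30
  indexing_error: 28
subsidiary_plan: 72
cohort_plan:
  pre_window: 30
  post_window: 20
  consortium: 8
  non_pi: 0
roster_plan:
  planted_matches: 42
  matched_articles: 179
  matched_extra_authors: 338
  unmatched_articles: 152
  unmatched_authors: 527
  unmatched_corresponding: 131
  disclosure_size: 218
survey_plan:
  confirmed: 14
  denied: 29
  no_reply: 68
  invalid_address: 20
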