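# Example run configuration for run_pipeline() / pvsignal-pipeline.R.
seed: 20190306
simulate:
  n_reports: 20000
  duplicate_rate: 0.02
ic_method: approx
min_count: 3
subgroups:
  - a: pd1_pdl1_mono
    b: ctla4_mono
    query: thyroid_dysfunction
  - a: combination
    b: pd1_pdl1_mono
    query: endocrine_all
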