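Placeholder for the source study's deposited supplementary tables, which are
not redistributed with this package.

To run the replication tiers of the test suite, place here:

  s1_counts.csv       raw subject-by-taxon 16S counts (subject_id first column)
  s1_survey.csv       raw survey/demographic responses (subject_id first
                      column; includes age, ethnicity, ph, nugent,
                      good_health, ever_tss and the question columns)
  s3_discrete.csv     the filtered, discretized 60-variable table
  s3_discrete_meta.csv  its variable metadata sidecar
                      (see write_bn_dataset() for the format)
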