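Published per-variant blood-pressure association summaries for the MAP4
gene region (averaged and empirical marginal posterior probabilities at
prior inclusion probability 0.1), used as fixed inputs to exercise the
two-stage decision rule and ranking. DBP = diastolic, SBP = systolic.
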