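# the benchmark-comparison tests intentionally report every deviation from
# the published values; do not stop the run after the first few failures
options(testthat.progress.max_fails = 100)
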