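# Reference scenario configuration for the pahfate CLI.
# Values mirror scenario_paper_like(); override as needed.
noise_cv: 0.1
replicates: 2
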