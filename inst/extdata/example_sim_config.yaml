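# Example simulation config for `breakjoin simulate` / cmd_simulate().
# Locus fields omitted -> built-in defaults (20-kb Salpha window, 200-bp bins).
preset: aej
n_reads: 2000
seed: 7
read_length: 150
germline_fraction: 0.15
duplicate_rate: 0.2
error_rate: 0.001
# preset_overrides:
#   resection_mean: 600
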