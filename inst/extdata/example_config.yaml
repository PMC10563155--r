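# Example simulation configuration: a mock-bead arm of the two-condition
# pull-down design (bait-tagged vs untagged, 3 replicates each).
n_background: 150
n_interactors: 8
n_contaminants: 4
bait_enrichment: 4
acetylation_p: 0
peptides_per_protein: 5
seed: 20230901
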