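# Uniformly elevated somatic hypermutation (6% per residue), no binder
# category structure.
seed: 45
nAnimals: 10
nSequences: 2000
strain: HC27sim
shmRate: 0.06
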