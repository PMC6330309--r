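# Default cohort but with the light-chain-paired junction alphabet, so a
# contrast against an h2l2 cohort is a composition null.
seed: 44
nAnimals: 10
nSequences: 2000
strain: HC27sim
nClones: 50
cloneSizeLaw: geometric
cloneSizeParam: 0.08
junctionLengthRange: [9, 18]
junctionAlphabet:
  "A": 0.063
  "V": 0.063
  "I": 0.0336
  "L": 0.0588
  "M": 0.0168
  "F": 0.0588
  "Y": 0.105
  "W": 0.021
  "C": 0.015
  "G": 0.175
  "P": 0.06
  "R": 0.051
  "H": 0.017
  "K": 0.0255
  "D": 0.051
  "E": 0.0255
  "S": 0.064
  "T": 0.04
  "N": 0.032
  "Q": 0.024
cdr3MutRate: 0.03
shmRate: 0.02
shmRateByCategory:
  lambda_binding: 0.0145
  antigen_specific: 0.033
pLambdaGivenW: 0.23
pLambdaGivenR: 0.007
pCloneSpecific: 0.30
pAntigenSpecific: 0.215
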