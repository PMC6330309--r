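# Default heavy-chain-only cohort: 10 animals x 2,000 sequences, VH3/VH4
# usage bias, 80% arginine-variant J usage, lambda binding coupled to the
# FR4 motif residue, category-dependent V-region hypermutation.
seed: 42
nAnimals: 10
nSequences: 2000
strain: HC27sim
vWeights:
  "IGHV3-23*01": 0.30
  "IGHV3-30*01": 0.20
  "IGHV4-39*01": 0.20
  "IGHV4-34*01": 0.12
  "IGHV3-7*01": 0.10
  "IGHV1-69*01": 0.08
jWeights:
  "IGHJ4*01": 0.80
  "IGHJ1*01": 0.04
  "IGHJ2*01": 0.04
  "IGHJ3*01": 0.04
  "IGHJ5*01": 0.04
  "IGHJ6*01": 0.04
nClones: 50
cloneSizeLaw: geometric
cloneSizeParam: 0.08
junctionLengthRange: [9, 18]
cdr3MutRate: 0.03
shmRate: 0.02
shmRateByCategory:
  lambda_binding: 0.0145
  antigen_specific: 0.033
pLambdaGivenW: 0.23
pLambdaGivenR: 0.007
pCloneSpecific: 0.30
pAntigenSpecific: 0.215
elisa:
  backgroundMean: 100
  backgroundCv: 0.2
  nBackground: 16
  positiveRange: [40, 400]
  negativeRange: [0.2, 5]
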