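# Rare-pair benchmark geometry: 1000 cells x 2000 genes, five broad
# clusters (~18.8% each) plus one adjacent rare pair (3% each). The pair
# inherits broad cluster 1's DE program, shares a strong rare-specific
# program (40 genes) and each member carries 20 private marker genes
# (so the vast majority of each rare cluster's DE program is shared).
nCells: 1000
nGenes: 2000
proportions: [0.188, 0.188, 0.188, 0.188, 0.188, 0.03, 0.03]
deFrac: 0.10
lfcMean: 1.2
lfcSd: 0.3
nbDispersion: 0.5
rareParents: [1, 1]
rareSharedFrac: 0.02
rarePrivateGenes: 20
rareLfcMean: 2.0
rareLfcSd: 0.3
baselineMeanlog: -1.0
baselineSdlog: 1.5
libSdlog: 0.35
seed: 2
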