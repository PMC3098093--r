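# Default OPEN triplet pool configuration.
#
# List SIZES (26 / 21 / 23 triplets at finger positions 1 / 2 / 3) match
# the published inventory of OPEN finger pools. The triplet IDENTITIES are
# only partly public: pools exist for all 16 GNN triplets plus several TNN
# (and one ANN) triplets, but the full TNN/ANN memberships have not been
# enumerated in print. The TNN entries below are therefore PROVISIONAL
# PLACEHOLDERS (the alphabetically first TNN triplets) chosen to reproduce
# the published pool sizes, NOT the real reagent lists. Replace this file
# with your laboratory's actual pool inventory for real scanning work.
pos1:
  - GAA
  - GAC
  - GAG
  - GAT
  - GCA
  - GCC
  - GCG
  - GCT
  - GGA
  - GGC
  - GGG
  - GGT
  - GTA
  - GTC
  - GTG
  - GTT
  - TAA
  - TAC
  - TAG
  - TAT
  - TCA
  - TCC
  - TCG
  - TCT
  - TGA
  - TGC
pos2:
  - GAA
  - GAC
  - GAG
  - GAT
  - GCA
  - GCC
  - GCG
  - GCT
  - GGA
  - GGC
  - GGG
  - GGT
  - GTA
  - GTC
  - GTG
  - GTT
  - TAA
  - TAC
  - TAG
  - TAT
  - TCA
pos3:
  - GAA
  - GAC
  - GAG
  - GAT
  - GCA
  - GCC
  - GCG
  - GCT
  - GGA
  - GGC
  - GGG
  - GGT
  - GTA
  - GTC
  - GTG
  - GTT
  - TAA
  - TAC
  - TAG
  - TAT
  - TCA
  - TCC
  - TCG
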