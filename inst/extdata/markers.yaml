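# Default marker-gene table for rule-based auxotrophy prediction.
#
# Essential lists are the genes whose absence (any one) implies auxotrophy
# for that vitamin; `precursor_map` names the vitamer still usable when a
# single listed gene is the one lost (the rest of the pathway is retained).
# The thiamine set (thiC / thiG / thiE) covers the pyrimidine branch, the
# thiazole branch, and the coupling step respectively.  The B3/B7/B9 lists
# are conventional marker sets from the genome-prediction literature and are
# meant to be overridden by a study-specific table where available; B9 calls
# are flagged low-confidence downstream because rare folate auxotrophies are
# poorly captured by presence/absence of these genes.
vitamins:
  B1:
    essential: [thiC, thiE, thiG]
    precursor_map:
      thiC: HMP
      thiG: Thz-P
      thiE: thiamine
  B3:
    essential: [nadA, nadB, nadC]
    precursor_map:
      nadC: quinolinate
  B7:
    essential: [bioA, bioB, bioD, bioF]
    precursor_map:
      bioB: desthiobiotin
  B9:
    essential: [folE, folP, folK]
    precursor_map: {}
    low_confidence: true
# Cobalamin is handled as a three-state classification: `pathway` lists
# corrin-ring and assembly genes scored as fractional completeness against
# `completeness_threshold`; `dependence` names the two methionine-synthase
# isozymes whose presence pattern decides whether a non-producer actually
# needs B12 (metH only) or can do without it (metE present).
b12:
  pathway: [cobA, cobB, cobC, cobD, cobE, cobF, cobG, cobH, cobI, cobJ,
            cobK, cobL, cobM, cobN, cobO, cobP, cobQ, cobS, cobT, cobU]
  completeness_threshold: 0.8
  dependence:
    b12_independent: metE
    b12_dependent: metH
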