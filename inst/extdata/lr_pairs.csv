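ligand,receptor,pathway
IGF1,IGF1R,IGF
PTN,PTPRZ1,PTN
WNT3A,LRP6,WNT
WNT2B,LRP6,WNT
OSM,OSMR,OSM
HGF,MET,HGF
LIF,LIFR,LIF
CNTF,CNTFR,CNTF
NRG1,ERBB4,NRG
NGF,NTRK1,NGF
PDGFA,PDGFRA,PDGF
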