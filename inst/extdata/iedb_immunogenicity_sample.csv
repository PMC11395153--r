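peptide,length,score
LLDVTAAV,8,0.30
AAAAAAAAA,9,-0.12
KLDETGNSLK,10,0.18342
GILGFVFTK,9,0.02123
SVFAGVVGK,9,-0.25411
AAAWYLWEVK,10,0.41276
TPRLVGGDNL,10,0.0
NLVPMVATV,9,-0.01987
RAKFKQLL,8,0.09912
LLDVTAAV,8,0.30
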