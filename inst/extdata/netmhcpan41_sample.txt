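# NetMHCpan version 4.1

# Input is in PEPTIDE format

# Threshold for Strong binding peptides   0.500
# Threshold for Weak binding peptides   2.000

HLA-A*03:01 : Distance to training data  0.000 (using nearest neighbor HLA-A03:01)

---------------------------------------------------------------------------------------------------------------------
 Pos         MHC        Peptide      Core Of Gp Gl Ip Il        Icore       Identity  Score_EL %Rank_EL  BindLevel
---------------------------------------------------------------------------------------------------------------------
   1 HLA-A*03:01     KLDETGNSLK  KLDETGNSL  0  0  0  0  1   KLDETGNSLK  pep1           0.752370    0.300 <= SB
   2 HLA-A*03:01      LLDVTAAVK  LLDVTAAVK  0  0  0  0  0    LLDVTAAVK  pep2           0.401220    1.500 <= SB
   3 HLA-A*03:01      SVFAGVVGK  SVFAGVVGK  0  0  0  0  0    SVFAGVVGK  pep3           0.220150    1.800 <= WB
   4 HLA-A*03:01     AAAWYLWEVK  AAAWYLWEV  0  0  0  0  1   AAAWYLWEVK  pep4           0.020110    8.500
   5 HLA-A*03:01      GILGFVFTK  GILGFVFTK  0  0  0  0  0    GILGFVFTK  pep5           0.901230    0.080 <= SB
---------------------------------------------------------------------------------------------------------------------

Protein pep1. Allele HLA-A*03:01. Number of high binders 2. Number of weak binders 1. Number of peptides 5

HLA-B*07:02 : Distance to training data  0.000 (using nearest neighbor HLA-B07:02)

---------------------------------------------------------------------------------------------------------------------
 Pos         MHC        Peptide      Core Of Gp Gl Ip Il        Icore       Identity  Score_EL %Rank_EL  BindLevel
---------------------------------------------------------------------------------------------------------------------
   1 HLA-B*07:02     KLDETGNSLK  KLDETGNSL  0  0  0  0  1   KLDETGNSLK  pep1           0.050210    6.200
   2 HLA-B*07:02      LLDVTAAVK  LLDVTAAVK  0  0  0  0  0    LLDVTAAVK  pep2           0.110020    2.000 <= WB
   3 HLA-B*07:02      SVFAGVVGK  SVFAGVVGK  0  0  0  0  0    SVFAGVVGK  pep3           0.030450    7.900
   4 HLA-B*07:02     AAAWYLWEVK  AAAWYLWEV  0  0  0  0  1   AAAWYLWEVK  pep4           0.650870    0.450 <= SB
   5 HLA-B*07:02      GILGFVFTK  GILGFVFTK  0  0  0  0  0    GILGFVFTK  pep5           0.010080   12.000
---------------------------------------------------------------------------------------------------------------------

Protein pep1. Allele HLA-B*07:02. Number of high binders 1. Number of weak binders 1. Number of peptides 5
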