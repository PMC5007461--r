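ALB
A1BG
A2M
AFM
AGT
AHSG
AMBP
APOA1
APOA2
APOA4
APOB
APOC1
APOC2
APOC3
APOD
APOE
APOH
APOL1
APOM
APCS
B2M
C1QA
C1QB
C1QC
C1R
C1S
C2
C3
C4A
C4B
C4BPA
C4BPB
C5
C6
C7
C8A
C8B
C8G
C9
CFB
CFD
CFH
CFHR1
CFHR2
CFHR3
CFI
CFP
CLU
CP
CRP
F2
F5
F7
F9
F10
F11
F12
F13A1
F13B
FGA
FGB
FGG
FN1
GC
GSN
HP
HPR
HPX
HRG
IGHA1
IGHA2
IGHD
IGHG1
IGHG2
IGHG3
IGHG4
IGHM
IGJ
IGKC
IGLC1
ITIH1
ITIH2
ITIH3
ITIH4
KLKB1
KNG1
LBP
LPA
LRG1
ORM1
ORM2
PLG
PON1
PROC
PROS1
RBP4
SAA1
SAA2
SAA4
SERPINA1
SERPINA3
SERPINA4
SERPINA5
SERPINA6
SERPINA7
SERPINC1
SERPIND1
SERPINF1
SERPINF2
SERPING1
SHBG
TF
TTR
VTN
VWF
PLASMA_SYN_001
PLASMA_SYN_002
PLASMA_SYN_003
PLASMA_SYN_004
PLASMA_SYN_005
PLASMA_SYN_006
PLASMA_SYN_007
PLASMA_SYN_008
PLASMA_SYN_009
PLASMA_SYN_010
PLASMA_SYN_011
PLASMA_SYN_012
PLASMA_SYN_013
PLASMA_SYN_014
PLASMA_SYN_015
PLASMA_SYN_016
PLASMA_SYN_017
PLASMA_SYN_018
PLASMA_SYN_019
PLASMA_SYN_020
PLASMA_SYN_021
PLASMA_SYN_022
PLASMA_SYN_023
PLASMA_SYN_024
PLASMA_SYN_025
PLASMA_SYN_026
PLASMA_SYN_027
PLASMA_SYN_028
PLASMA_SYN_029
PLASMA_SYN_030
PLASMA_SYN_031
PLASMA_SYN_032
PLASMA_SYN_033
PLASMA_SYN_034
PLASMA_SYN_035
PLASMA_SYN_036
PLASMA_SYN_037
PLASMA_SYN_038
PLASMA_SYN_039
PLASMA_SYN_040
PLASMA_SYN_041
PLASMA_SYN_042
PLASMA_SYN_043
PLASMA_SYN_044
PLASMA_SYN_045
PLASMA_SYN_046
PLASMA_SYN_047
PLASMA_SYN_048
PLASMA_SYN_049
PLASMA_SYN_050
PLASMA_SYN_051
PLASMA_SYN_052
PLASMA_SYN_053
PLASMA_SYN_054
PLASMA_SYN_055
PLASMA_SYN_056
PLASMA_SYN_057
PLASMA_SYN_058
PLASMA_SYN_059
PLASMA_SYN_060
PLASMA_SYN_061
PLASMA_SYN_062
PLASMA_SYN_063
PLASMA_SYN_064
PLASMA_SYN_065
PLASMA_SYN_066
PLASMA_SYN_067
PLASMA_SYN_068
PLASMA_SYN_069
PLASMA_SYN_070
PLASMA_SYN_071
PLASMA_SYN_072
PLASMA_SYN_073
PLASMA_SYN_074
PLASMA_SYN_075
PLASMA_SYN_076
PLASMA_SYN_077
PLASMA_SYN_078
PLASMA_SYN_079
PLASMA_SYN_080
PLASMA_SYN_081
PLASMA_SYN_082
PLASMA_SYN_083
PLASMA_SYN_084
PLASMA_SYN_085
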