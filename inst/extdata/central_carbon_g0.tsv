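reaction_id	delta_g_kJ_mol
GLPK	-20
GLPD	-30
TPI	5.5
FBA	-20
FBPASE	-11
PGI	-2.5
ZWF_L	-25
EDD	-20
EDA	16
GAPD	7.5
PGK	-19
PGM	4.2
ENO	-4
PYK	-27
PPSA	-12
ADK	0
MGSA	-25
MGGSH	-35
GLOB	-15
HCHA	-50
GLDA	-35
ALDA	-50
LLDD	-55
DLD	-55
SERA	30
SERC	-10
SERB	-13
SDAA	-35
GLUDY	-33
THD	0
NDH	-80
QOX	-100
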