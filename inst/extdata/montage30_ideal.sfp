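FP1	-0.2938926261	 0.9045084972	 0.3090169944
FP2	 0.2938926261	 0.9045084972	 0.3090169944
F7	-0.7694208843	 0.5590169944	 0.3090169944
F3	-0.4330274292	 0.6454163629	 0.6292256862
Fz	 0.0000000000	 0.5877852523	 0.8090169944
F4	 0.4330274292	 0.6454163629	 0.6292256862
F8	 0.7694208843	 0.5590169944	 0.3090169944
FC5	-0.7564688004	 0.3427981057	 0.5569958821
FC1	-0.2839429504	 0.3506992531	 0.8924048604
FC2	 0.2839429504	 0.3506992531	 0.8924048604
FC6	 0.7564688004	 0.3427981057	 0.5569958821
C3	-0.5877852523	 0.0000000000	 0.8090169944
Cz	 0.0000000000	 0.0000000000	 1.0000000000
C4	 0.5877852523	 0.0000000000	 0.8090169944
CP5	-0.7564688004	-0.3427981057	 0.5569958821
CP1	-0.2839429504	-0.3506992531	 0.8924048604
CP2	 0.2839429504	-0.3506992531	 0.8924048604
CP6	 0.7564688004	-0.3427981057	 0.5569958821
P7	-0.7694208843	-0.5590169944	 0.3090169944
P3	-0.4330274292	-0.6454163629	 0.6292256862
Pz	 0.0000000000	-0.5877852523	 0.8090169944
P4	 0.4330274292	-0.6454163629	 0.6292256862
P8	 0.7694208843	-0.5590169944	 0.3090169944
PO7	-0.5590169944	-0.7694208843	 0.3090169944
PO3	-0.2942920171	-0.8309616198	 0.4721175649
POz	 0.0000000000	-0.8090169944	 0.5877852523
PO4	 0.2942920171	-0.8309616198	 0.4721175649
PO8	 0.5590169944	-0.7694208843	 0.3090169944
O1	-0.2938926261	-0.9045084972	 0.3090169944
O2	 0.2938926261	-0.9045084972	 0.3090169944
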