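profile	domain
AMP-binding	A
A-OX	A
Condensation	C
Condensation_LCL	C
Condensation_DCL	C
Condensation_Starter	C
Cglyc	C
PKS_AT	AT
Acyl_transf_1	AT
PKS_KS	KS
ketoacyl-synt	KS
A	A
C	C
AT	AT
KS	KS
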