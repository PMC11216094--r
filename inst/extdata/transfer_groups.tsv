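group_id	group_smiles	label
a	F	F
b	Cl	Cl
c	Br	Br
d	C	CH3
e	C(F)(F)F	CF3
f	C=C	CHCH2
g	C#C	CCH
h	C#N	CN
i	N=[N+]=[N-]	N3
j	N	NH2
k	NC(C)=O	NHAc
l	O	OH
m	OC	OCH3
n	OC(F)(F)F	OCF3
o	OC(C)=O	OCOCH3
p	OC(=O)C(F)(F)F	OCOCF3
q	OC(=O)c1ccccc1	OCOPh
r	OS(=O)(=O)C(F)(F)F	OTf
s	OS(=O)(=O)c1ccc(C)cc1	OTs
t	SC(F)(F)F	SCF3
u	C(F)(F)S(=O)(=O)c1ccccc1	CF2SO2Ph
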