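skeleton_id	template_smiles	description
1	O=C1O{X}({G})c2ccccc21	benziodoxolone-type: 2-carboxyphenyl tether, five-membered X-O ring
2	CC1(C)O{X}({G})c2ccccc21	3,3-dimethylbenziodoxole-type: gem-dimethyl alkoxide tether
3	FC(F)(F)C1(C(F)(F)F)O{X}({G})c2ccccc21	3,3-bis(trifluoromethyl)benziodoxole-type: gem-di-CF3 alkoxide tether
4	O=C1N{X}({G})c2ccccc21	benziodazolone-type: amide N-X tether
5	{X}1({G})c2ccccc2-c2ccccc21	dibenzohalole-type: biphenylene C,C-chelate around X
6	O=S1(=O)O{X}({G})c2ccccc21	benziodoxathiole 3,3-dioxide-type: sulfonate O-X tether (external test skeleton)
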