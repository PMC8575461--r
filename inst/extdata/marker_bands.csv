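position,sign,assignment,context
1647,+,L-state amide I,photocycle
1665,-,L-state amide I bleach,photocycle
1630,+,M-state amide I,photocycle
1643,-,M-state amide I bleach,photocycle
1220,-,retinal fingerprint C-C,photocycle
1198,-,retinal fingerprint C-C,photocycle
1529,-,retinal C=C stretch,photocycle
1087,+,cGMP P=O,turnover
1068,+,cGMP cyclic phosphate,turnover
1122,+,free GTP PO3 2-,uncaging
1132,+,protein-bound GTP PO3 2-,uncaging
923,-,GTP P-O-P,turnover
1527,-,NPE caging group NO2,uncaging
1347,-,NPE caging group NO2,uncaging
1686,+,NAP by-product keto C=O,uncaging
1267,+,NAP by-product,uncaging
1256,-,gamma-phosphate PO2-,uncaging
1207,-,gamma-PO2- enzyme-bound,uncaging
1244,-,phosphodiester cleavage,turnover
1155,-,phosphodiester cleavage,turnover
1117,-,substrate-binding P=O shift,binding
1070,+,substrate-binding P=O shift,binding
1172,+,cGMP/pyrophosphate formation,turnover
1175,+,cGMP/pyrophosphate formation,turnover
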