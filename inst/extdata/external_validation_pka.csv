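# External validation set: experimental and predicted basic pKa values for
# 40 nitrogen compounds (pharmaceutical ingredients and dyes) at 25 C in
# aqueous solution, compound ids 131-170. pka_pred is the six-descriptor
# QSAR model; chemaxon_pred is the commercial reference predictor.
# abs_error columns are |pka_exp - pred| at 2-decimal arithmetic, as
# printed in the source table.
compound_id,name,pka_exp,pka_pred,abs_error,chemaxon_pred,chemaxon_abs_error
131,Norephedrine,9.12,9.72,0.60,8.96,0.16
132,Procaine,9.05,8.59,0.46,8.96,0.09
133,Terbutaline,8.62,8.14,0.48,9.76,1.14
134,Quinine,8.60,8.69,0.09,8.55,0.05
135,Tetracaine,8.50,8.87,0.37,8.42,0.08
136,Astemizole,8.35,8.25,0.10,9.23,0.88
137,Nicotine,8.14,8.32,0.18,8.58,0.44
138,Clozapine,7.94,7.85,0.09,8.16,0.22
139,Ampicillin,7.25,7.60,0.35,7.23,0.02
140,Ketoconazole,6.22,6.25,0.03,6.26,0.04
141,Clotrimazole,5.89,6.17,0.28,6.42,0.53
142,Benzimidazole,5.50,5.47,0.03,5.79,0.29
143,Coumarin 7,5.10,5.26,0.16,4.21,0.89
144,Abacavir,5.04,5.35,0.31,6.87,1.83
145,Fuberidazole,4.80,5.21,0.41,3.93,0.87
146,Thiabendazole,4.60,5.00,0.40,4.08,0.52
147,Carbendazim,4.50,4.98,0.48,4.28,0.22
148,Omeprazole,4.40,4.71,0.31,4.77,0.37
149,Cerivastatin,4.38,4.79,0.41,5.58,1.20
150,Ethionamide,4.37,3.89,0.48,5.00,0.63
151,Olmesartan medoxomil,4.30,4.48,0.18,3.65,0.65
152,Lamivudine,4.24,4.01,0.23,2.00,2.24
153,Picoprazole,3.50,3.78,0.28,2.89,0.61
154,2-Amino-pentamethylbodipy,3.50,3.77,0.27,0.41,3.09
155,Diazepam,3.42,3.84,0.42,2.92,0.50
156,Prodan,3.40,3.14,0.26,4.94,1.54
157,Timoprazole,3.10,3.41,0.31,2.38,0.72
158,Benzocaine,2.45,2.39,0.06,2.78,0.33
159,Metronidazole,2.38,2.65,0.27,3.03,0.65
160,Acyclovir,2.20,2.62,0.42,2.94,0.74
161,Sulfacetamide,1.75,1.58,0.17,2.14,0.39
162,7-Dimethylazacoumarin,1.30,0.73,0.57,3.67,2.37
163,CHEMBL1689126,7.00,7.07,0.07,6.54,0.46
164,CHEMBL1689112,6.90,6.68,0.22,5.94,0.96
165,CHEMBL47529,5.50,5.48,0.02,4.96,0.54
166,CHEMBL1349378,4.64,4.90,0.26,4.49,0.15
167,CHEMBL432733,4.37,4.72,0.35,7.39,3.02
168,CHEMBL271703,4.20,4.26,0.06,3.46,0.74
169,CHEMBL191553,3.20,2.89,0.31,2.80,0.40
170,CHEMBL1405150,2.50,2.86,0.36,3.64,1.14
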